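#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric test of the overlap between a metabolite test
#' set and each pathway, against a background of measured metabolites:
#' p = P(X >= k) with N = |background|, K = |pathway intersect background|,
#' n = |test set|, k = |pathway intersect test set|.
#'
#' @param test_set character metabolite ids (must lie in `background`).
#' @param background character metabolite ids forming the universe.
#' @param db a [pathway_db()].
#' @return Tibble `pathway_id`, `k`, `K`, `n`, `N`, `p_hyper`.
#' @export
hypergeom_enrichment <- function(test_set, background, db) {
  if (length(test_set) == 0) abort("empty test set")
  test_set <- unique(test_set)
  background <- unique(background)
  if (!all(test_set %in% background)) {
    abort("`test_set` must be a subset of `background`")
  }
  N <- length(background)
  n <- length(test_set)
  purrr::imap(db$metabolite_sets, function(members, pid) {
    Kset <- intersect(members, background)
    K <- length(Kset)
    k <- length(intersect(Kset, test_set))
    tibble(pathway_id = pid, k = k, K = K, n = n, N = N,
           p_hyper = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) |>
    bind_rows()
}

#' Resampling pathway over-representation
#'
#' Draws `n_perm` metabolite sets of the same size as the test set,
#' uniformly without replacement from the background, and reports per
#' pathway the add-one permutation p value of observing at least the
#' observed overlap.
#'
#' @inheritParams hypergeom_enrichment
#' @param n_perm number of resamples (>= 100 recommended).
#' @param seed RNG seed.
#' @return Tibble `pathway_id`, `k`, `perm_p`.
#' @export
permutation_enrichment <- function(test_set, background, db, n_perm = 1000,
                                   seed = 1L) {
  test_set <- unique(test_set)
  background <- unique(background)
  if (length(background) < length(test_set)) {
    abort("background smaller than the test set")
  }
  if (!all(test_set %in% background)) {
    abort("`test_set` must be a subset of `background`")
  }
  pw_ids <- names(db$metabolite_sets)
  # pathway x background membership matrix: overlaps are one matrix product
  M <- purrr::map(db$metabolite_sets, ~ as.numeric(background %in% .x)) |>
    do.call(what = rbind)
  obs <- drop(M %*% as.numeric(background %in% test_set))
  exceed <- withr::with_seed(seed, {
    ex <- rep(0L, length(pw_ids))
    S <- matrix(0, length(background), n_perm)
    for (b in seq_len(n_perm)) {
      S[sample(length(background), length(test_set)), b] <- 1
    }
    null_k <- M %*% S
    rowSums(null_k >= obs)
  })
  tibble(pathway_id = pw_ids, k = as.integer(unname(obs)),
         perm_p = unname(add_one_p(exceed, n_perm)))
}

#' Combined pathway enrichment with the dual thresholds
#'
#' Convenience wrapper running [hypergeom_enrichment()] and
#' [permutation_enrichment()] and joining the results; a pathway is called
#' enriched when both p values pass their thresholds.
#'
#' @inheritParams permutation_enrichment
#' @param p_threshold threshold applied to both p values (default 0.05).
#' @return Tibble with both p values and a logical `enriched` column.
#' @export
enrich_pathways <- function(test_set, background, db, n_perm = 1000,
                            seed = 1L, p_threshold = 0.05) {
  hyper <- hypergeom_enrichment(test_set, background, db)
  perm <- permutation_enrichment(test_set, background, db, n_perm, seed)
  hyper |>
    left_join(perm |> select("pathway_id", "perm_p"), by = "pathway_id") |>
    mutate(enriched = .data$p_hyper < p_threshold &
             .data$perm_p < p_threshold)
}

#' Detect environment-condition-affected peaks
#'
#' Per tissue, t-tests of the condition macaques against all
#' standard-condition control macaques, with a permutation p value
#' (condition/control labels shuffled); a peak is classified as affected by
#' the environmental change when both p values are below `cutoff` and the
#' human samples change in the same direction relative to the control
#' macaques.
#'
#' @param mset a normalized [metabolome_set()].
#' @param condition `"condition1"` or `"condition2"`.
#' @param cutoff p threshold for both tests (default 0.01).
#' @param n_perm permutations per tissue.
#' @param seed RNG seed.
#' @param var_equal pooled-variance t instead of Welch.
#' @return Tibble `tissue`, `peak_id`, `direction`, `statistic`,
#'   `p_value`, `perm_p`.
#' @export
environment_effect_peaks <- function(mset, condition = c("condition1",
                                                         "condition2"),
                                     cutoff = 0.01, n_perm = 1000, seed = 1L,
                                     var_equal = FALSE) {
  condition <- match.arg(condition)
  smp <- mset$samples
  is_cond <- smp$species == "macaque" & smp$condition == condition &
    !smp$is_pooled
  is_ctrl <- smp$species == "macaque" & smp$condition == "standard" &
    !smp$is_pooled & smp$postmortem_delay < 2
  is_human <- smp$species == "human" & !smp$is_pooled
  if (!any(is_cond)) abort(sprintf("no %s samples present", condition))
  out <- list()
  withr::with_seed(seed, {
    for (t in unique(smp$tissue)) {
      jc <- which(is_cond & smp$tissue == t)
      jk <- which(is_ctrl & smp$tissue == t)
      jh <- which(is_human & smp$tissue == t)
      if (length(jc) < 2 || length(jk) < 2) next
      Y <- mset$intensities
      obs <- row_t_stat(Y, jc, jk, var_equal)
      p_obs <- 2 * pt(abs(obs$t), obs$df, lower.tail = FALSE)
      pool <- c(jc, jk)
      n_c <- length(jc)
      exceed <- rep(0L, nrow(Y))
      for (b in seq_len(n_perm)) {
        pj <- sample(pool)
        pb <- row_t_stat(Y, pj[seq_len(n_c)], pj[-seq_len(n_c)], var_equal)
        exceed <- exceed + (!is.na(pb$t) & !is.na(obs$t) &
                              abs(pb$t) >= abs(obs$t) - 1e-12)
      }
      perm_p <- add_one_p(exceed, n_perm)
      human_d <- rowMeans(Y[, jh, drop = FALSE], na.rm = TRUE) -
        rowMeans(Y[, jk, drop = FALSE], na.rm = TRUE)
      hit <- which(!is.na(p_obs) & p_obs < cutoff & perm_p < cutoff &
                     sign(human_d) == sign(obs$d) & obs$d != 0)
      if (length(hit) > 0) {
        out[[t]] <- tibble(
          tissue = t, peak_id = mset$peaks$peak_id[hit],
          direction = unname(ifelse(obs$d[hit] > 0, "up", "down")),
          statistic = unname(obs$t[hit]), p_value = unname(p_obs[hit]),
          perm_p = unname(perm_p[hit])
        )
      }
    }
  })
  if (length(out) == 0) {
    return(tibble(tissue = character(0), peak_id = character(0),
                  direction = character(0), statistic = numeric(0),
                  p_value = numeric(0), perm_p = numeric(0)))
  }
  bind_rows(out)
}

#' Overlap between environment-enriched pathways and human-specific change
#'
#' Counts the human-specific peaks whose annotated metabolite belongs to
#' any of the environment-enriched pathways, and compares the count with a
#' null in which equally many pathways are drawn at random from the pathway
#' universe.
#'
#' @param env_pathways character pathway ids enriched for
#'   environment-affected metabolites (non-empty).
#' @param human_assign `lineage_assignment` (or tibble) of human-specific
#'   peaks.
#' @param annotation peak -> metabolite mapping tibble (`peak_id`,
#'   `metabolite_id`).
#' @param db a [pathway_db()].
#' @param n_perm number of random pathway draws.
#' @param seed RNG seed.
#' @return A list: `count` (observed human-specific peaks in the enriched
#'   pathways) and `perm_p` (add-one permutation p).
#' @export
overlap_significance <- function(env_pathways, human_assign, annotation, db,
                                 n_perm = 1000, seed = 1L) {
  if (length(env_pathways) == 0) abort("empty enriched pathway set")
  all_pw <- names(db$metabolite_sets)
  if (length(all_pw) == 0) abort("empty pathway universe")
  tbl <- if (inherits(human_assign, "lineage_assignment")) {
    human_assign$assignments
  } else {
    as_tibble(human_assign)
  }
  human_peaks <- tbl |>
    filter(.data$lineage == "human") |>
    pull("peak_id") |>
    unique()
  ann <- annotation |> filter(.data$peak_id %in% human_peaks)
  count_in <- function(pws) {
    mets <- unique(unlist(db$metabolite_sets[pws]))
    length(unique(ann$peak_id[ann$metabolite_id %in% mets]))
  }
  obs <- count_in(env_pathways)
  if (length(human_peaks) == 0) {
    return(list(count = 0L, perm_p = 1))
  }
  exceed <- withr::with_seed(seed, {
    sum(purrr::map_int(seq_len(n_perm), function(b) {
      count_in(sample(all_pw, length(unique(env_pathways))))
    }) >= obs)
  })
  list(count = obs, perm_p = add_one_p(exceed, n_perm))
}
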