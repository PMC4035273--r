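#' Composite tissue categories
#'
#' In addition to the five sampled tissues, two composite neural categories
#' are defined by pooling samples in silico: cortex = PFC + V1 and
#' brain = PFC + V1 + CBC. The five original groups are unchanged. The
#' composite categories reuse the same samples, so the seven categories are
#' not independent.
#'
#' @param samples sample metadata tibble.
#' @return Tibble with columns `tissue_category`, `sample_id`, `tissue`
#'   (the sample's original tissue, the stratum for permutations).
#' @export
build_composite_tissues <- function(samples) {
  base <- samples |>
    select(sample_id = "sample_id", tissue = "tissue") |>
    mutate(tissue_category = .data$tissue)
  cortex <- base |>
    filter(.data$tissue %in% c("PFC", "V1")) |>
    mutate(tissue_category = "cortex")
  brain <- base |>
    filter(.data$tissue %in% c("PFC", "V1", "CBC")) |>
    mutate(tissue_category = "brain")
  bind_rows(base, cortex, brain) |>
    select("tissue_category", "sample_id", "tissue")
}

#' Gate peaks on the ANOVA species and species-tissue terms
#'
#' A peak passes the gate when, for either term, its parametric p is below
#' `cutoff` and its permutation q value (the FDR estimated at its own p
#' level) is below `fdr`.
#'
#' @param pf_species,pf_interaction [permutation_fdr()] results for the
#'   `species` and `tissue:species` terms (the interaction may be `NULL`).
#' @param cutoff,fdr significance cutoffs (defaults 0.01 and 0.05).
#' @return Character vector of gated peak ids.
#' @export
gate_peaks <- function(pf_species, pf_interaction = NULL, cutoff = 0.01,
                       fdr = 0.05) {
  pass <- function(pf) {
    if (is.null(pf)) return(character(0))
    pf$peak_id[!is.na(pf$p_value) & pf$p_value < cutoff &
                 !is.na(pf$fdr_q) & pf$fdr_q < fdr]
  }
  union(pass(pf_species), pass(pf_interaction))
}

# Per-family test of the focal species against the comparison species.
# method "pooled": one t test against all comparison samples pooled (the
# shadow of a sister-lineage shift is delta/2 and can reach significance).
# method "pairwise": intersection-union test — the focal species must
# differ from EACH comparison species with a consistent sign; the reported
# p is the maximum pairwise p (set to 1 on sign disagreement), which makes
# lineage assignment specific to the focal branch.
family_test <- function(Y, species_lab, focal_sp, comp_species,
                        var_equal = FALSE, method = "pairwise") {
  j1 <- which(species_lab == focal_sp)
  if (method == "pooled") {
    j2 <- which(species_lab %in% comp_species)
    r <- row_t_stat(Y, j1, j2, var_equal)
    p <- 2 * pt(abs(r$t), r$df, lower.tail = FALSE)
    return(list(p = p, t = r$t, d = r$d))
  }
  p_max <- rep(0, nrow(Y))
  t_bind <- rep(NA_real_, nrow(Y))
  sign_ok <- rep(TRUE, nrow(Y))
  first_sign <- NULL
  for (cs in comp_species) {
    j2 <- which(species_lab == cs)
    r <- row_t_stat(Y, j1, j2, var_equal)
    p <- 2 * pt(abs(r$t), r$df, lower.tail = FALSE)
    upd <- is.na(p_max) | (!is.na(p) & p >= p_max)
    t_bind[upd] <- r$t[upd]
    p_max <- pmax(p_max, p)
    if (is.null(first_sign)) {
      first_sign <- sign(r$d)
    } else {
      sign_ok <- sign_ok & sign(r$d) == first_sign
    }
  }
  p_max[!sign_ok] <- 1
  jp <- which(species_lab %in% comp_species)
  d <- row_group_stats(Y, j1)$mean - row_group_stats(Y, jp)$mean
  list(p = p_max, t = t_bind, d = d)
}

# Lean Welch/pooled t over rows; returns vectors only (hot permutation path).
row_t_stat <- function(Y, j1, j2, var_equal = FALSE) {
  g1 <- row_group_stats(Y, j1)
  g2 <- row_group_stats(Y, j2)
  d <- g1$mean - g2$mean
  if (var_equal) {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) / df
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    a <- g1$var / g1$n
    b <- g2$var / g2$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (g1$n - 1) + b^2 / (g2$n - 1))
  }
  t <- d / se
  bad <- g1$n < 2 | g2$n < 2
  t[bad] <- NA_real_
  list(t = t, df = df, d = d)
}

#' Classify species-specific peak concentration levels per tissue
#'
#' For every tissue category (five tissues plus cortex and brain) and every
#' lineage, peaks that passed the corresponding ANOVA gate (primate test
#' for primate lineages, all-species test for the mouse lineage) are tested
#' against the comparison species: the other primates for a primate, all
#' primates for the mouse. With the default `comparison = "pairwise"` the
#' focal species must differ from each comparison species with a
#' consistent sign (intersection-union test; the peak's p is the maximum
#' pairwise t-test p), which makes the assignment specific to the focal
#' branch; `comparison = "pooled"` is the single t test against all
#' comparison samples pooled. An assignment requires parametric p <
#' `cutoff` together with a permutation q value (the family's FDR
#' estimated at the peak's own p level, from species labels permuted
#' within the original tissue strata) below `fdr`. The direction is the
#' sign of the focal-minus-comparison mean difference. A peak may be
#' assigned to more than one lineage in a tissue.
#'
#' @param mset a normalized [metabolome_set()].
#' @param gate_primate,gate_mouse character vectors of gated peak ids (see
#'   [gate_peaks()]); `gate_mouse` defaults to `gate_primate` if omitted.
#' @param cutoff parametric p cutoff (default 0.01).
#' @param fdr permutation-FDR bound (default 0.05).
#' @param n_perm permutations per (tissue, lineage) family.
#' @param seed RNG seed.
#' @param var_equal use the pooled-variance t instead of Welch.
#' @param comparison `"pairwise"` (intersection-union against each
#'   comparison species) or `"pooled"` (one test against the pooled
#'   comparison samples).
#' @param lineages lineages to test (default all four).
#' @return A `lineage_assignment`: list with `assignments` (tibble
#'   `peak_id`, `tissue`, `lineage`, `direction`, `estimate`, `statistic`,
#'   `p_value`, `perm_p`) and `families` (tibble `tissue`, `lineage`,
#'   `n_tested`, `n_discoveries`, `mean_null_discoveries`, `fdr`).
#' @export
classify_species_specific <- function(mset, gate_primate, gate_mouse = NULL,
                                      cutoff = 0.01, fdr = 0.05,
                                      n_perm = 1000, seed = 1L,
                                      var_equal = FALSE,
                                      comparison = c("pairwise", "pooled"),
                                      lineages = names(lineage_species)) {
  comparison <- match.arg(comparison)
  if (mset$scale != "log2") abort("`mset` must be normalized first")
  gate_mouse <- gate_mouse %||% gate_primate
  smp <- mset$samples
  keep_ids <- analysis_samples(smp)
  cats <- build_composite_tissues(smp |> filter(.data$sample_id %in% keep_ids))
  assignments <- list()
  families <- list()
  withr::with_seed(seed, {
    for (cat in unique(cats$tissue_category)) {
      cat_samples <- cats |> filter(.data$tissue_category == cat)
      for (lin in lineages) {
        gate <- if (lin == "mouse_anc") gate_mouse else gate_primate
        if (length(gate) == 0) next
        rows <- match(intersect(gate, mset$peaks$peak_id),
                      mset$peaks$peak_id)
        focal_sp <- lineage_species[[lin]]
        comp_sp <- lineage_comparison[[lin]]
        meta <- smp[match(cat_samples$sample_id, smp$sample_id), ]
        in_test <- meta$species %in% c(focal_sp, comp_sp)
        test_ids <- cat_samples$sample_id[in_test]
        strata <- cat_samples$tissue[in_test]
        species_lab <- meta$species[in_test]
        jcols <- match(test_ids, smp$sample_id)
        Y <- mset$intensities[rows, jcols, drop = FALSE]
        if (sum(species_lab == focal_sp) < 2 ||
              any(table(species_lab[species_lab %in% comp_sp]) < 2)) next
        obs <- family_test(Y, species_lab, focal_sp, comp_sp, var_equal,
                           comparison)
        p_obs <- obs$p
        d_obs <- sum(p_obs < cutoff, na.rm = TRUE)

        exceed <- rep(0L, length(rows))
        d_null <- numeric(n_perm)
        null_counts <- rep(0L, length(rows))
        for (b in seq_len(n_perm)) {
          lab <- species_lab
          for (t in unique(strata)) {
            jt <- which(strata == t)
            lab[jt] <- species_lab[jt][sample(length(jt))]
          }
          pb <- family_test(Y, lab, focal_sp, comp_sp, var_equal, comparison)
          pp <- pb$p
          exceed <- exceed + (!is.na(pp) & !is.na(p_obs) &
                                pp <= p_obs + 1e-12)
          d_null[b] <- sum(pp < cutoff, na.rm = TRUE)
          null_counts <- null_counts + findInterval(p_obs, sort(pp))
        }
        fam_fdr <- if (d_obs == 0) 0 else min(1, mean(d_null) / d_obs)
        q <- perm_q_values(p_obs, null_counts, n_perm)
        families[[paste(cat, lin)]] <- tibble(
          tissue = cat, lineage = lin, n_tested = length(rows),
          n_discoveries = d_obs, mean_null_discoveries = mean(d_null),
          fdr = fam_fdr
        )
        sig <- which(!is.na(p_obs) & p_obs < cutoff & !is.na(q) & q < fdr)
        if (length(sig) > 0) {
          assignments[[paste(cat, lin)]] <- tibble(
            peak_id = mset$peaks$peak_id[rows[sig]],
            tissue = cat, lineage = lin,
            direction = unname(ifelse(obs$d[sig] > 0, "up", "down")),
            estimate = unname(obs$d[sig]), statistic = unname(obs$t[sig]),
            p_value = unname(p_obs[sig]),
            perm_p = unname(add_one_p(exceed[sig], n_perm)),
            fdr_q = unname(q[sig])
          )
        }
      }
    }
  })
  empty_assign <- tibble(
    peak_id = character(0), tissue = character(0), lineage = character(0),
    direction = character(0), estimate = numeric(0), statistic = numeric(0),
    p_value = numeric(0), perm_p = numeric(0), fdr_q = numeric(0)
  )
  structure(
    list(
      assignments = if (length(assignments)) bind_rows(assignments) else
        empty_assign,
      families = if (length(families)) bind_rows(families) else
        tibble(tissue = character(0), lineage = character(0),
               n_tested = integer(0), n_discoveries = integer(0),
               mean_null_discoveries = numeric(0), fdr = numeric(0)),
      params = list(cutoff = cutoff, fdr = fdr, n_perm = n_perm,
                    var_equal = var_equal, comparison = comparison)
    ),
    class = "lineage_assignment"
  )
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat("<lineage_assignment> ", nrow(x$assignments),
      " assignments across ", nrow(x$families), " (tissue, lineage) tests\n",
      sep = "")
  invisible(x)
}

#' @describeIn classify_species_specific per-assignment tibble.
#' @param x a `lineage_assignment`.
#' @param ... unused.
#' @method tidy lineage_assignment
#' @export
tidy.lineage_assignment <- function(x, ...) x$assignments

#' @describeIn classify_species_specific per-family summary tibble.
#' @method glance lineage_assignment
#' @export
glance.lineage_assignment <- function(x, ...) x$families

# Tissue groups within which same-direction repeats are not "unique".
multitissue_groups <- list(
  c("PFC", "V1"),
  c("cortex", "CBC"),
  c("brain", "kidney", "muscle")
)

#' Exclude multi-tissue species-specific changes
#'
#' For the per-tissue "unique" analysis, removes assignments whose
#' same-lineage, same-direction counterpart exists in another tissue of the
#' same group, for the three groups (i) PFC and V1; (ii) cortex and CBC;
#' (iii) brain, kidney and muscle. Assignments with opposite directions, or
#' without a counterpart in their group, are retained.
#'
#' @param assign a `lineage_assignment` (or its assignments tibble).
#' @return An object of the same type with the excluded rows removed.
#' @export
exclude_multitissue <- function(assign) {
  tbl <- if (inherits(assign, "lineage_assignment")) assign$assignments else
    as_tibble(assign)
  drop <- rep(FALSE, nrow(tbl))
  for (grp in multitissue_groups) {
    in_grp <- tbl$tissue %in% grp
    if (!any(in_grp)) next
    sub <- tbl[in_grp, ]
    multi <- sub |>
      distinct(.data$peak_id, .data$lineage, .data$direction, .data$tissue) |>
      count(.data$peak_id, .data$lineage, .data$direction) |>
      filter(n >= 2)
    if (nrow(multi) == 0) next
    key <- paste(tbl$peak_id, tbl$lineage, tbl$direction)
    bad <- paste(multi$peak_id, multi$lineage, multi$direction)
    drop <- drop | (in_grp & key %in% bad)
  }
  out <- tbl[!drop, , drop = FALSE]
  if (inherits(assign, "lineage_assignment")) {
    assign$assignments <- out
    assign
  } else {
    out
  }
}
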