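# Per-peak hierarchical ANOVA. Factors enter sequentially (Type I sums of
# squares) in the order given, mirroring a variance decomposition into
# tissue, species, species:tissue and the sample covariates. The F
# statistics for all peaks are obtained jointly from orthonormal bases of
# the nested design matrices, which makes the permutation machinery cheap:
# each permutation costs a few small QR decompositions and one skinny
# matrix product per basis.

# canonical sequential order (interaction after all main effects, as in
# base R model formulas): covariates are adjusted for before the
# species-tissue interaction term is assessed
default_anova_factors <- c("tissue", "species", "sex", "age", "rin",
                           "tissue:species")

# Model frame for the design; factors coerced, covariates kept numeric.
anova_model_frame <- function(samples, factors) {
  vars <- unique(unlist(strsplit(factors, ":", fixed = TRUE)))
  missing <- setdiff(vars, names(samples))
  if (length(missing) > 0) {
    abort(paste("sample metadata lacks:", paste(missing, collapse = ", ")))
  }
  df <- samples[, vars, drop = FALSE]
  for (v in vars) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]])
    }
  }
  for (v in vars) {
    if (is.factor(df[[v]]) && nlevels(droplevels(df[[v]])) < 2) {
      abort(sprintf("factor '%s' has fewer than 2 levels", v))
    }
  }
  df
}

# Sequential-F engine on complete data: returns per-term F/p plus residual
# bookkeeping. Y is peaks x samples (no NAs among `rows`).
seq_anova_fit <- function(Y, frame, factors) {
  n <- nrow(frame)
  fits <- matrix(0, nrow(Y), length(factors))
  dfs <- integer(length(factors))
  prev_fit <- {
    q0 <- matrix(1 / sqrt(n), n, 1)
    (Y %*% q0)^2 |> rowSums()
  }
  prev_rank <- 1L
  for (k in seq_along(factors)) {
    fml <- stats::as.formula(
      paste("~", paste(factors[seq_len(k)], collapse = " + ")))
    X <- stats::model.matrix(fml, frame)
    qr_x <- qr(X)
    r <- qr_x$rank
    Q <- qr.Q(qr_x)[, seq_len(r), drop = FALSE]
    fit_k <- rowSums((Y %*% Q)^2)
    fits[, k] <- fit_k - prev_fit
    dfs[k] <- r - prev_rank
    prev_fit <- fit_k
    prev_rank <- r
  }
  rss <- pmax(rowSums(Y^2) - prev_fit, 0)
  df_res <- n - prev_rank
  Fm <- sweep(fits, 2, pmax(dfs, 1), "/") / (rss / df_res)
  Fm[, dfs == 0] <- NA_real_
  Pm <- matrix(NA_real_, nrow(Fm), ncol(Fm))
  for (k in seq_along(factors)) {
    if (dfs[k] > 0) {
      Pm[, k] <- pf(Fm[, k], dfs[k], df_res, lower.tail = FALSE)
    }
  }
  # constant peaks: no residual and no model variance -> undefined
  zero_var <- rowSums(fits) + rss <= 1e-12
  Fm[zero_var, ] <- NA_real_
  Pm[zero_var, ] <- NA_real_
  list(f = Fm, p = Pm, df = dfs, rss = rss, df_res = df_res)
}

# Focal-term-only fit used in the permutation loop: just the three nested
# bases (up to the previous term, up to the focal term, full model) are
# needed for the focal F, which roughly triples permutation throughput.
seq_anova_term_fit <- function(Y, frame, factors, k) {
  n <- nrow(frame)
  basis <- function(upto) {
    if (upto == 0) return(list(q = matrix(1 / sqrt(n), n, 1), rank = 1L))
    fml <- stats::as.formula(
      paste("~", paste(factors[seq_len(upto)], collapse = " + ")))
    qr_x <- qr(stats::model.matrix(fml, frame))
    list(q = qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE],
         rank = qr_x$rank)
  }
  b_prev <- basis(k - 1)
  b_k <- basis(k)
  b_full <- if (k == length(factors)) b_k else basis(length(factors))
  fit_prev <- rowSums((Y %*% b_prev$q)^2)
  fit_k <- rowSums((Y %*% b_k$q)^2)
  fit_full <- if (k == length(factors)) fit_k else
    rowSums((Y %*% b_full$q)^2)
  df_k <- b_k$rank - b_prev$rank
  df_res <- n - b_full$rank
  rss <- pmax(rowSums(Y^2) - fit_full, 0)
  f <- ((fit_k - fit_prev) / max(df_k, 1)) / (rss / df_res)
  if (df_k == 0) f[] <- NA_real_
  p <- pf(f, df_k, df_res, lower.tail = FALSE)
  zero_var <- fit_full - fit_prev + rss <= 1e-12
  f[zero_var] <- NA_real_
  p[zero_var] <- NA_real_
  list(f = f, p = p)
}

# NA-tolerant wrapper: complete rows take the joint path; rows with missing
# values are refit individually on their observed samples.
seq_anova <- function(Y, frame, factors) {
  complete <- which(rowSums(is.na(Y)) == 0)
  Fm <- matrix(NA_real_, nrow(Y), length(factors),
               dimnames = list(rownames(Y), factors))
  Pm <- Fm
  if (length(complete) > 0) {
    fit <- seq_anova_fit(Y[complete, , drop = FALSE], frame, factors)
    Fm[complete, ] <- fit$f
    Pm[complete, ] <- fit$p
  }
  partial <- setdiff(seq_len(nrow(Y)), complete)
  for (i in partial) {
    obs <- which(!is.na(Y[i, ]))
    if (length(obs) < length(factors) + 2) next
    sub_frame <- droplevels(frame[obs, , drop = FALSE])
    ok <- tryCatch({
      fit <- seq_anova_fit(Y[i, obs, drop = FALSE], sub_frame, factors)
      Fm[i, ] <- fit$f
      Pm[i, ] <- fit$p
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
  }
  list(f = Fm, p = Pm)
}

#' Per-peak ANOVA decomposition
#'
#' Fits, for every peak, a linear model with sequential (Type I) terms for
#' tissue, species, their interaction and the sample covariates, and
#' returns per-term F statistics and parametric p values. The test runs in
#' two modes: on all four species, or on the primate samples only (the
#' "primate test", the gate for primate-specific classification).
#'
#' Constant peaks get missing p values. Only standard individual samples
#' (see [analysis_samples()]) are used.
#'
#' @param mset a normalized [metabolome_set()].
#' @param mode `"all"` (four species) or `"primates"`.
#' @param factors sequential model terms (default
#'   `tissue, species, tissue:species, sex, age, rin`, intersected with the
#'   available metadata columns).
#' @return An `anova_result`: tibble `peak_id`, `term`, `statistic`,
#'   `p_value` with the mode and factors as attributes.
#' @export
anova_decompose <- function(mset, mode = c("all", "primates"),
                            factors = NULL) {
  mode <- match.arg(mode)
  sel <- anova_sample_index(mset$samples, mode)
  frame_cols <- names(mset$samples)
  if (is.null(factors)) {
    factors <- default_anova_factors[
      purrr::map_lgl(default_anova_factors, function(f) {
        all(strsplit(f, ":", fixed = TRUE)[[1]] %in% frame_cols)
      })
    ]
  }
  frame <- anova_model_frame(mset$samples[sel, , drop = FALSE], factors)
  Y <- mset$intensities[, sel, drop = FALSE]
  fit <- seq_anova(Y, frame, factors)
  res <- tibble(
    peak_id = rep(mset$peaks$peak_id, times = length(factors)),
    term = rep(factors, each = nrow(Y)),
    statistic = as.vector(fit$f),
    p_value = as.vector(fit$p)
  )
  structure(res, mode = mode, factors = factors,
            class = c("anova_result", class(res)))
}

anova_sample_index <- function(samples, mode) {
  ids <- analysis_samples(samples)
  sel <- samples$sample_id %in% ids
  if (mode == "primates") sel <- sel & samples$species != "mouse"
  which(sel)
}

# Permute the focal variable respecting the design: species labels are
# shuffled within tissue, tissue labels within species, covariates freely.
permute_frame <- function(frame, term) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  focal <- if ("species" %in% vars) "species" else vars[1]
  out <- frame
  if (focal == "species" && "tissue" %in% names(frame)) {
    for (t in levels(factor(frame$tissue))) {
      j <- which(frame$tissue == t)
      out$species[j] <- frame$species[sample(j)]
    }
  } else if (focal == "tissue" && "species" %in% names(frame)) {
    for (s in levels(factor(frame$species))) {
      j <- which(frame$species == s)
      out$tissue[j] <- frame$tissue[sample(j)]
    }
  } else {
    out[[focal]] <- frame[[focal]][sample(nrow(frame))]
  }
  out
}

# All distinct label assignments for exhaustive enumeration (small n only).
enumerate_label_permutations <- function(labels) {
  n <- length(labels)
  perms <- permutations_of(seq_len(n))
  arrangements <- unique(do.call(rbind, lapply(perms, function(p) labels[p])))
  arrangements
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Permutation p values and permutation FDR for an ANOVA term
#'
#' Re-fits the sequential ANOVA under label permutations that respect the
#' design (species within tissue for the species and interaction terms;
#' tissue within species for the tissue term; covariates freely) and
#' returns, per peak, the add-one permutation p value
#' `(1 + #permuted F >= observed F) / (n_perm + 1)` and the permutation
#' q value: the FDR estimated at the peak's own p level as the mean
#' permuted discovery count divided by the observed discovery count at
#' that level, clipped to \[0, 1\] and monotonized. The family FDR at the
#' nominal `cutoff` is reported as an attribute.
#'
#' With `exhaustive = TRUE`, all distinct label arrangements are
#' enumerated instead of sampled (feasible for a handful of samples) and
#' the permutation p is the exact enumeration fraction.
#'
#' @param mset a normalized [metabolome_set()].
#' @param term the focal model term (e.g. `"species"`).
#' @param mode `"all"` or `"primates"`, as in [anova_decompose()].
#' @param cutoff nominal significance level used in the FDR bookkeeping.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed.
#' @param factors sequential model terms, as in [anova_decompose()].
#' @param exhaustive enumerate all distinct label assignments (only with a
#'   single-factor design and a small sample count).
#' @return A `permutation_fdr` result: tibble `peak_id`, `statistic`,
#'   `p_value` (parametric), `perm_p`, `fdr_q` (per-peak permutation q),
#'   with attributes `fdr` (at `cutoff`), `n_discoveries`,
#'   `mean_null_discoveries`, `cutoff`, `term`.
#' @export
permutation_fdr <- function(mset, term = "species", mode = c("all", "primates"),
                            cutoff = 0.01, n_perm = 1000, seed = 1L,
                            factors = NULL, exhaustive = FALSE) {
  mode <- match.arg(mode)
  sel <- anova_sample_index(mset$samples, mode)
  if (is.null(factors)) {
    factors <- default_anova_factors[
      purrr::map_lgl(default_anova_factors, function(f) {
        all(strsplit(f, ":", fixed = TRUE)[[1]] %in% names(mset$samples))
      })
    ]
  }
  if (!term %in% factors) abort("`term` must be one of the model factors")
  frame <- anova_model_frame(mset$samples[sel, , drop = FALSE], factors)
  Y <- mset$intensities[, sel, drop = FALSE]
  k <- match(term, factors)

  obs <- seq_anova(Y, frame, factors)
  f_obs <- obs$f[, k]
  p_obs <- obs$p[, k]
  complete <- rowSums(is.na(Y)) == 0

  if (exhaustive) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    focal <- if ("species" %in% vars) "species" else vars[1]
    labs <- enumerate_label_permutations(as.character(frame[[focal]]))
    n_arr <- nrow(labs)
    exceed <- rep(0L, nrow(Y))
    d_null <- numeric(n_arr)
    null_counts <- rep(0L, nrow(Y))
    for (b in seq_len(n_arr)) {
      fr <- frame
      fr[[focal]] <- factor(labs[b, ], levels = levels(factor(frame[[focal]])))
      fit <- seq_anova(Y, fr, factors)
      exceed <- exceed + (fit$f[, k] >= f_obs - 1e-12)
      pb <- fit$p[, k]
      d_null[b] <- sum(pb < cutoff, na.rm = TRUE)
      null_counts <- null_counts + findInterval(p_obs, sort(pb))
    }
    perm_p <- exceed / n_arr # includes the identity arrangement
    d_obs <- sum(p_obs < cutoff, na.rm = TRUE)
    fdr <- if (d_obs == 0) 0 else min(1, mean(d_null) / d_obs)
    q <- perm_q_values(p_obs, null_counts, n_arr)
    return(permutation_fdr_result(mset$peaks$peak_id, f_obs, p_obs, perm_p,
                                  q, fdr, d_obs, mean(d_null), cutoff, term,
                                  flag_no_discoveries = d_obs == 0))
  }

  if (n_perm < 100) warn("fewer than 100 permutations is unreliable")
  exceed <- rep(0L, nrow(Y))
  d_null <- numeric(n_perm)
  null_counts <- rep(0L, sum(complete))
  withr::with_seed(seed, {
    Yc <- Y[complete, , drop = FALSE]
    for (b in seq_len(n_perm)) {
      fr <- permute_frame(frame, term)
      fit <- seq_anova_term_fit(Yc, fr, factors, k)
      exceed[complete] <- exceed[complete] +
        (fit$f >= f_obs[complete] - 1e-12)
      pb <- fit$p
      d_null[b] <- sum(pb < cutoff, na.rm = TRUE)
      null_counts <- null_counts + findInterval(p_obs[complete], sort(pb))
    }
  })
  perm_p <- ifelse(complete, add_one_p(exceed, n_perm), NA_real_)
  d_obs <- sum(p_obs[complete] < cutoff, na.rm = TRUE)
  fdr <- if (d_obs == 0) 0 else min(1, mean(d_null) / d_obs)
  q <- rep(NA_real_, nrow(Y))
  q[complete] <- perm_q_values(p_obs[complete], null_counts, n_perm)
  permutation_fdr_result(mset$peaks$peak_id, f_obs, p_obs, perm_p, q, fdr,
                         d_obs, mean(d_null), cutoff, term,
                         flag_no_discoveries = d_obs == 0)
}

permutation_fdr_result <- function(peak_id, f, p, perm_p, q, fdr, d_obs,
                                   mean_null, cutoff, term,
                                   flag_no_discoveries = FALSE) {
  res <- tibble(peak_id = peak_id, statistic = unname(f),
                p_value = unname(p), perm_p = unname(perm_p),
                fdr_q = unname(q))
  structure(res, fdr = fdr, n_discoveries = d_obs,
            mean_null_discoveries = mean_null, cutoff = cutoff, term = term,
            no_discoveries = flag_no_discoveries,
            class = c("permutation_fdr", class(res)))
}

#' @method glance permutation_fdr
#' @export
glance.permutation_fdr <- function(x, ...) {
  tibble(
    term = attr(x, "term"), cutoff = attr(x, "cutoff"),
    n_discoveries = attr(x, "n_discoveries"),
    mean_null_discoveries = attr(x, "mean_null_discoveries"),
    fdr = attr(x, "fdr")
  )
}
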