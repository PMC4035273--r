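# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Minimal sample sheet: `spec` is a named list species -> number of
# individual samples, replicated over `tissues`; pooled samples appended
# per tissue when n_pooled > 0.
make_samples <- function(spec, tissues = "muscle", n_pooled = 0) {
  rows <- list()
  for (sp in names(spec)) {
    for (t in tissues) {
      n <- spec[[sp]]
      if (n == 0) next
      rows[[paste(sp, t)]] <- tibble::tibble(
        sample_id = sprintf("%s_%02d.%s", sp, seq_len(n), t),
        species = sp, tissue = t,
        individual_id = sprintf("%s_%02d", sp, seq_len(n)),
        sex = rep_len(c("M", "F"), n), age = 10, rin = 8,
        condition = "standard", postmortem_delay = 0.2, is_pooled = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (n_pooled > 0) {
    pooled <- tidyr::crossing(tissue = tissues, rep = seq_len(n_pooled))
    pooled <- dplyr::mutate(
      pooled,
      sample_id = sprintf("pooled_%s_%02d", tissue, rep),
      species = "mixed", individual_id = NA_character_, sex = NA_character_,
      age = NA_real_, rin = NA_real_, condition = "standard",
      postmortem_delay = 0, is_pooled = TRUE
    )
    pooled$rep <- NULL
    out <- dplyr::bind_rows(out, pooled)
  }
  out$run_order <- seq_len(nrow(out))
  out
}

make_mset <- function(X, samples, dataset = "posLC", rt = 2,
                      scale = "intensity", peaks_extra = NULL) {
  n <- nrow(X)
  rownames(X) <- NULL
  peaks <- tibble::tibble(
    peak_id = sprintf("pk%03d", seq_len(n)),
    dataset = dataset,
    mz = ifelse(dataset == "GC", NA_real_, 200),
    mass = ifelse(dataset == "GC", 200, NA_real_),
    rt = rep_len(rt, n)
  )
  if (!is.null(peaks_extra)) {
    for (nm in names(peaks_extra)) peaks[[nm]] <- peaks_extra[[nm]]
  }
  rownames(X) <- peaks$peak_id
  colnames(X) <- samples$sample_id
  metabolome_set(X, peaks, samples, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small default-free simulation used by several files: no QC extras, no
# censoring, so the statistical paths run on clean dense matrices.
quiet_sim_config <- function(...) {
  sim_config(
    detection_limit = 0, n_pooled_per_tissue = 0, n_postmortem = 0,
    pm_effect_fraction = 0, n_condition = c(condition1 = 0, condition2 = 0),
    cond_effect_fraction = c(condition1 = 0, condition2 = 0),
    n_extra_controls = 0, ...
  )
}

null_accel <- function() {
  z <- c(PFC = 0, V1 = 0, CBC = 0, kidney = 0, muscle = 0)
  list(human = z, chimp = z, macaque_anc = z, mouse_anc = z)
}

# LC fixture: 6 clean peaks plus one violator of each criterion; pooled
# samples carry the run order used by the consistency criterion.
lc_fixture <- function() {
  samples <- make_samples(list(human = 4, chimpanzee = 4), "muscle",
                          n_pooled = 3)
  n_samp <- nrow(samples)
  good_row <- function() {
    x <- rep(20000, n_samp)
    x[samples$is_pooled] <- 5000
    x
  }
  X <- t(sapply(seq_len(10), function(i) good_row()))
  rt <- rep(2, 10)
  pooled_idx <- which(samples$is_pooled)
  rt[7] <- 0.5                                 # criterion 1
  X[8, pooled_idx] <- c(500, 5000, 5000)        # criterion 2 (2/3 < 80%)
  X[9, pooled_idx] <- c(8000, 1000, 4000)       # criterion 3 (|log2 8| > 1)
  X[10, !samples$is_pooled] <- 8000             # criterion 4 (< 10,000 AU)
  make_mset(X, samples, dataset = "posLC", rt = rt)
}

# GC fixture: clean peaks plus one violator per criterion and an
# overlapping same-mass pair clear of the internal standards.
gc_fixture <- function() {
  samples <- make_samples(list(macaque = 4), "kidney")
  X <- matrix(5000, 9, nrow(samples))
  mass <- c(200, 210, 220, 150, 230, 240, 400, 400, 250)
  rt <- c(2, 2.5, 3, 5.5, 3.5, 6, 6.8, 7.2, 7.6)
  spread <- c(rep(0.2, 8), 1.5)
  distinct <- c(TRUE, TRUE, FALSE, rep(TRUE, 6))
  X[6, ] <- c(3000, 3000, 1000, 1000) # boundary: 50% at exactly 3,000 AU
  X[5, ] <- 1000                      # criterion 4 (below level everywhere)
  make_mset(X, samples, dataset = "GC", rt = rt,
            peaks_extra = list(mass = mass, rt_spread = spread,
                               distinct_background = distinct))
}

# Independent rank-mean quantile normalization (no ties expected in the
# fixtures that use it).
ref_quantile_normalize <- function(M) {
  ranks <- apply(M, 2, rank, ties.method = "average")
  means <- rowMeans(apply(M, 2, sort))
  out <- M
  for (j in seq_len(ncol(M))) out[, j] <- means[ranks[, j]]
  out
}

# Brute-force complete linkage: merge the pair of clusters with the
# smallest maximal inter-point distance; record heights.
ref_complete_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Exact upper-tail hypergeometric by subset enumeration (N <= 12).
ref_hypergeom_enum <- function(N, K, n, k_obs) {
  universe <- seq_len(N)
  in_pathway <- universe <= K
  subsets <- utils::combn(N, n)
  hits <- apply(subsets, 2, function(s) sum(in_pathway[s]) >= k_obs)
  mean(hits)
}
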