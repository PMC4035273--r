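# Multistep peak filtering for the LC-MS and GC-MS datasets. Criteria are
# evaluated in their listed order and each removed peak is attributed to the
# first criterion it fails, so the report's removal counts plus the retained
# count always equal the input count.

filter_report <- function(criteria, fails, removed_samples = character(0)) {
  counts <- purrr::map_int(criteria, function(cr) sum(fails == cr, na.rm = TRUE))
  tibble(criterion = criteria, removed = counts) |>
    structure(retained = sum(is.na(fails)),
              removed_samples = removed_samples,
              class = c("filter_report", "tbl_df", "tbl", "data.frame"))
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> retained", attr(x, "retained"), "peaks\n")
  NextMethod()
}

#' Filter an LC-MS peak table
#'
#' Applies the four LC filtering criteria, in order:
#' 1. retention time >= 0.6 min;
#' 2. present (intensity >= 1,000 AU) in >= 80% of pooled samples;
#' 3. consistent levels in the two earliest pooled samples, operationalized
#'    as |log2 ratio| <= `max_pooled_log_ratio` with both values detected;
#' 4. intensity >= 10,000 AU in >= 50% of samples of at least one
#'    (species, tissue) cell (individual samples only).
#'
#' Outlier samples should be removed before criterion 4; pass them via
#' `exclude_samples` (they are dropped from the returned table and ignored
#' by the criteria).
#'
#' @param mset a [metabolome_set()] on the intensity scale with pooled
#'   samples present; only `posLC`/`negLC` peaks may be supplied.
#' @param thresholds named list overriding `min_rt`, `pooled_presence`
#'   (fraction), `pooled_min_intensity`, `max_pooled_log_ratio`,
#'   `min_intensity`, `min_sample_fraction`.
#' @param exclude_samples sample ids (e.g. PCA outliers) to drop first.
#' @return A list: `mset` (retained peaks, outliers dropped) and `report`
#'   (a `filter_report` tibble of per-criterion removal counts).
#' @export
filter_lcms_peaks <- function(mset, thresholds = list(),
                              exclude_samples = character(0)) {
  th <- utils::modifyList(list(
    min_rt = 0.6, pooled_presence = 0.8, pooled_min_intensity = 1000,
    max_pooled_log_ratio = 1, min_intensity = 10000,
    min_sample_fraction = 0.5
  ), thresholds)
  if (!all(mset$peaks$dataset %in% c("posLC", "negLC"))) {
    abort("`filter_lcms_peaks()` expects posLC/negLC peaks only")
  }
  if (length(exclude_samples) > 0) {
    mset <- subset_mset(
      mset, samples = setdiff(mset$samples$sample_id, exclude_samples))
  }
  pooled <- mset$samples$is_pooled
  if (!any(pooled)) {
    abort("criterion 2 needs pooled samples, but none are present")
  }
  X <- mset$intensities
  n_peaks <- nrow(X)
  fails <- rep(NA_character_, n_peaks)

  c1 <- mset$peaks$rt >= th$min_rt
  fails[!c1] <- "rt"

  P <- X[, pooled, drop = FALSE]
  c2 <- rowMeans(P >= th$pooled_min_intensity) >= th$pooled_presence
  fails[is.na(fails) & !c2] <- "pooled_presence"

  ord <- order(mset$samples$run_order[pooled] %||% seq_len(sum(pooled)))
  first_two <- P[, ord[1:2], drop = FALSE]
  ratio <- log2(first_two[, 1] / first_two[, 2])
  c3 <- is.finite(ratio) & abs(ratio) <= th$max_pooled_log_ratio
  fails[is.na(fails) & !c3] <- "pooled_consistency"

  c4 <- cell_presence(X, mset$samples, th$min_intensity,
                      th$min_sample_fraction)
  fails[is.na(fails) & !c4] <- "species_tissue_level"

  keep <- is.na(fails)
  list(
    mset = subset_mset(mset, peaks = keep),
    report = filter_report(
      c("rt", "pooled_presence", "pooled_consistency", "species_tissue_level"),
      fails, removed_samples = exclude_samples)
  )
}

# TRUE where a peak reaches min_intensity in >= min_fraction of the
# individual samples of at least one (species, tissue) cell.
cell_presence <- function(X, samples, min_intensity, min_fraction) {
  ind <- !samples$is_pooled
  cells <- split(which(ind), paste(samples$species[ind], samples$tissue[ind]))
  ok <- rep(FALSE, nrow(X))
  for (j in cells) {
    ok <- ok | rowMeans(X[, j, drop = FALSE] >= min_intensity) >= min_fraction
  }
  ok
}

#' Filter a GC-MS peak table
#'
#' Applies the five GC filtering criteria, in order:
#' 1. distinct-from-background (an upstream call carried as the logical
#'    `distinct_background` peak-meta column; missing column = all pass);
#' 2. per-sample retention times within a 2-min window around the peak's
#'    median RT, carried as the `rt_spread` column (max |RT - median|, min)
#'    and checked against `rt_window / 2`;
#' 3. RT farther than 0.75 min from every internal standard, or, when the
#'    peak shares an internal standard's (nominal) mass, farther than
#'    1.5 min from that standard;
#' 4. intensity >= 3,000 AU in >= 50% of samples of at least one
#'    (species, tissue) cell;
#' 5. peaks sharing a mass with RTs within 0.5 min of each other are
#'    overlapping: every member of such a group is removed.
#'
#' @param mset a [metabolome_set()] of GC peaks on the intensity scale.
#' @param internal_standards tibble or data.frame with columns `mass`, `rt`.
#' @param thresholds named list overriding `rt_window`, `is_distance`,
#'   `is_same_mass_distance`, `min_intensity`, `min_sample_fraction`,
#'   `overlap_rt`.
#' @param exclude_samples sample ids to drop before criterion 4.
#' @return A list: `mset` and `report`, as in [filter_lcms_peaks()].
#' @export
filter_gcms_peaks <- function(mset, internal_standards, thresholds = list(),
                              exclude_samples = character(0)) {
  if (missing(internal_standards) || is.null(internal_standards)) {
    abort("`internal_standards` (mass, rt) are required for criterion 3")
  }
  th <- utils::modifyList(list(
    rt_window = 2, is_distance = 0.75, is_same_mass_distance = 1.5,
    min_intensity = 3000, min_sample_fraction = 0.5, overlap_rt = 0.5
  ), thresholds)
  if (!all(mset$peaks$dataset == "GC")) {
    abort("`filter_gcms_peaks()` expects GC peaks only")
  }
  if (length(exclude_samples) > 0) {
    mset <- subset_mset(
      mset, samples = setdiff(mset$samples$sample_id, exclude_samples))
  }
  is_tbl <- as_tibble(internal_standards)
  pk <- mset$peaks
  n_peaks <- nrow(pk)
  fails <- rep(NA_character_, n_peaks)

  c1 <- pk$distinct_background %||% rep(TRUE, n_peaks)
  c1[is.na(c1)] <- TRUE
  fails[!c1] <- "background"

  spread <- pk$rt_spread %||% rep(0, n_peaks)
  spread[is.na(spread)] <- 0
  c2 <- spread <= th$rt_window / 2
  fails[is.na(fails) & !c2] <- "rt_consistency"

  c3 <- rep(TRUE, n_peaks)
  for (k in seq_len(nrow(is_tbl))) {
    d <- abs(pk$rt - is_tbl$rt[k])
    same_mass <- !is.na(pk$mass) & round(pk$mass) == round(is_tbl$mass[k])
    lim <- ifelse(same_mass, th$is_same_mass_distance, th$is_distance)
    c3 <- c3 & d > lim
  }
  fails[is.na(fails) & !c3] <- "internal_standard"

  c4 <- cell_presence(mset$intensities, mset$samples, th$min_intensity,
                      th$min_sample_fraction)
  fails[is.na(fails) & !c4] <- "species_tissue_level"

  # criterion 5 among survivors of 1-4: same mass, RT gap <= overlap_rt
  surv <- which(is.na(fails))
  if (length(surv) > 1) {
    overlapping <- rep(FALSE, length(surv))
    mass_groups <- split(seq_along(surv), pk$mass[surv])
    for (g in mass_groups) {
      if (length(g) < 2) next
      rts <- pk$rt[surv[g]]
      o <- order(rts)
      gaps <- diff(rts[o]) <= th$overlap_rt
      hit <- rep(FALSE, length(g))
      hit[o[c(gaps, FALSE)]] <- hit[o[c(gaps, FALSE)]] | TRUE
      hit[o[c(FALSE, gaps)]] <- hit[o[c(FALSE, gaps)]] | TRUE
      overlapping[g] <- hit
    }
    fails[surv[overlapping]] <- "overlapping"
  }

  keep <- is.na(fails)
  list(
    mset = subset_mset(mset, peaks = keep),
    report = filter_report(
      c("background", "rt_consistency", "internal_standard",
        "species_tissue_level", "overlapping"),
      fails, removed_samples = exclude_samples)
  )
}

#' Detect outlier samples on the first two principal components
#'
#' PCA of the log2 intensity matrix (zeros treated as missing; peaks with
#' any missing value are excluded from the PCA). A sample is an outlier if
#' its score on PC1 or PC2 lies more than `k` robust standard deviations
#' (MAD) from the median score.
#'
#' @param mset a [metabolome_set()]; at least 4 samples.
#' @param k robust-SD threshold (default 5, deliberately conservative).
#' @return Character vector of outlier sample ids.
#' @export
detect_outlier_samples <- function(mset, k = 5) {
  X <- mset$intensities
  if (ncol(X) < 4) abort("outlier detection needs at least 4 samples")
  L <- log2(X)
  L[!is.finite(L)] <- NA
  # samples with no usable data (e.g. pooled columns of a GC table) are
  # not assessable and are dropped from the PCA
  usable <- colSums(!is.na(L)) > 0
  L <- L[, usable, drop = FALSE]
  if (ncol(L) < 4) abort("outlier detection needs at least 4 samples")
  complete <- which(rowSums(is.na(L)) == 0)
  if (length(complete) < 2) abort("too few complete peaks for PCA")
  pc <- prcomp(t(L[complete, , drop = FALSE]), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  out <- rep(FALSE, ncol(L))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    dev <- abs(s - median(s))
    scale <- mad(s)
    if (scale <= 0) next
    out <- out | dev > k * scale
  }
  colnames(L)[out]
}
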