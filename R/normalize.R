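#' Log2-transform and within-tissue quantile normalization
#'
#' Intensities are log2-transformed (zeros, i.e. "not detected", become
#' `NA` and stay missing) and quantile-normalized separately within each
#' tissue's sample group, so differences between tissues are preserved
#' while sample-to-sample distributional differences within a tissue are
#' removed. Missing values are excluded from the reference distribution
#' (the underlying engine is [limma::normalizeQuantiles()]).
#'
#' A tissue group with a single sample is log2-transformed only, with a
#' warning.
#'
#' @param mset a filtered [metabolome_set()] on the intensity scale.
#' @return The [metabolome_set()] on the log2 scale.
#' @export
normalize_peaks <- function(mset) {
  if (mset$scale != "intensity") abort("`mset` is already on the log2 scale")
  L <- log2(mset$intensities)
  L[!is.finite(L)] <- NA
  for (t in unique(mset$samples$tissue)) {
    j <- which(mset$samples$tissue == t)
    if (length(j) == 1) {
      warn(sprintf("tissue '%s' has a single sample; log2 transform only", t))
      next
    }
    L[, j] <- limma::normalizeQuantiles(L[, j, drop = FALSE], ties = TRUE)
  }
  metabolome_set(L, mset$peaks, mset$samples, scale = "log2")
}

#' Flag peaks affected by postmortem delay
#'
#' Per tissue, computes each peak's mean normalized difference between the
#' delayed-dissection macaque samples and the standard-condition macaque
#' controls, and flags the peaks in the top and bottom `q` tails of that
#' difference distribution. The tails are taken rank-based:
#' `floor(q * n_peaks)` peaks on each side, so the flagged set is exactly
#' what a sort of the differences produces. Flagged peaks are excluded from
#' the respective tissue downstream.
#'
#' @param mset a normalized [metabolome_set()].
#' @param q tail fraction per side (default 0.05, i.e. ~10% flagged).
#' @param min_delay_hours samples at or above this postmortem delay count as
#'   delayed (default 2 h; the study's delayed animals are at 4-6 h).
#' @return Tibble with columns `tissue`, `peak_id`, `difference`.
#' @export
flag_postmortem_peaks <- function(mset, q = 0.05, min_delay_hours = 2) {
  if (mset$scale != "log2") abort("`mset` must be normalized first")
  smp <- mset$samples
  mac <- smp$species == "macaque" & !smp$is_pooled &
    smp$condition == "standard"
  delayed <- mac & smp$postmortem_delay >= min_delay_hours
  control <- mac & smp$postmortem_delay < min_delay_hours
  if (!any(delayed)) {
    warn("no postmortem-delayed samples; nothing flagged")
    return(tibble(tissue = character(0), peak_id = character(0),
                  difference = numeric(0)))
  }
  out <- list()
  for (t in unique(smp$tissue)) {
    jd <- which(delayed & smp$tissue == t)
    jc <- which(control & smp$tissue == t)
    if (length(jd) == 0 || length(jc) == 0) next
    d <- rowMeans(mset$intensities[, jd, drop = FALSE], na.rm = TRUE) -
      rowMeans(mset$intensities[, jc, drop = FALSE], na.rm = TRUE)
    k <- floor(q * sum(is.finite(d)))
    if (k == 0) next
    o <- order(d, na.last = NA)
    flagged <- c(head(o, k), utils::tail(o, k))
    out[[t]] <- tibble(tissue = t, peak_id = mset$peaks$peak_id[flagged],
                       difference = unname(d[flagged]))
  }
  if (length(out) == 0) {
    return(tibble(tissue = character(0), peak_id = character(0),
                  difference = numeric(0)))
  }
  bind_rows(out)
}
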