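#' Peaks-by-samples metabolome container
#'
#' Bundles a peaks x samples intensity matrix with its peak and sample
#' metadata. Intensities are arbitrary units (AU) where 0 means "not
#' detected"; after [normalize_peaks()] values are log2 with zeros carried
#' as `NA`.
#'
#' @param intensities numeric matrix, peaks in rows, samples in columns.
#'   Row names are peak ids, column names sample ids.
#' @param peaks tibble of per-peak metadata with at least `peak_id`; LC peaks
#'   carry `mz` (Da) and `rt` (min), GC peaks `mass` (nominal) and `rt`;
#'   `dataset` is one of `"posLC"`, `"negLC"`, `"GC"`.
#' @param samples tibble of per-sample metadata with at least `sample_id`,
#'   `species`, `tissue`; the full record has `individual_id`, `sex`, `age`,
#'   `rin`, `condition` (`"standard"`, `"condition1"`, `"condition2"`),
#'   `postmortem_delay` (hours) and `is_pooled`.
#' @param scale `"intensity"` (AU, zeros = not detected) or `"log2"`.
#'
#' @return An object of class `metabolome_set`.
#' @export
metabolome_set <- function(intensities, peaks, samples,
                           scale = c("intensity", "log2")) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  peaks <- as_tibble(peaks)
  samples <- as_tibble(samples)
  if (!"peak_id" %in% names(peaks)) abort("`peaks` needs a `peak_id` column")
  if (!all(c("sample_id", "species", "tissue") %in% names(samples))) {
    abort("`samples` needs `sample_id`, `species`, `tissue` columns")
  }
  if (anyDuplicated(peaks$peak_id)) abort("peak ids must be unique")
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique")
  if (nrow(intensities) != nrow(peaks)) {
    abort("intensity rows and peak metadata rows differ")
  }
  if (ncol(intensities) != nrow(samples)) {
    abort("intensity columns and sample metadata rows differ")
  }
  if (is.null(rownames(intensities))) rownames(intensities) <- peaks$peak_id
  if (is.null(colnames(intensities))) colnames(intensities) <- samples$sample_id
  if (!identical(rownames(intensities), as.character(peaks$peak_id))) {
    abort("intensity row names must match `peaks$peak_id` in order")
  }
  if (!identical(colnames(intensities), as.character(samples$sample_id))) {
    abort("intensity column names must match `samples$sample_id` in order")
  }
  if (scale == "intensity" && any(intensities < 0, na.rm = TRUE)) {
    abort("raw intensities must be non-negative")
  }
  structure(
    list(intensities = intensities, peaks = peaks, samples = samples,
         scale = scale),
    class = "metabolome_set"
  )
}

#' @export
print.metabolome_set <- function(x, ...) {
  cat("<metabolome_set> ", nrow(x$intensities), " peaks x ",
      ncol(x$intensities), " samples (", x$scale, " scale)\n", sep = "")
  cat("  datasets: ",
      paste(unique(x$peaks$dataset %||% "unspecified"), collapse = ", "),
      "\n", sep = "")
  cat("  species:  ", paste(unique(x$samples$species), collapse = ", "),
      "\n  tissues:  ", paste(unique(x$samples$tissue), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolome_set <- function(x) dim(x$intensities)

#' Subset a metabolome set by peaks and/or samples
#'
#' @param mset a [metabolome_set()].
#' @param peaks character peak ids or logical/integer row selector.
#' @param samples character sample ids or logical/integer column selector.
#' @return A `metabolome_set` restricted to the selection.
#' @export
subset_mset <- function(mset, peaks = NULL, samples = NULL) {
  i <- seq_len(nrow(mset$intensities))
  j <- seq_len(ncol(mset$intensities))
  if (!is.null(peaks)) {
    i <- if (is.character(peaks)) match(peaks, mset$peaks$peak_id) else which(
      if (is.logical(peaks)) peaks else seq_along(i) %in% peaks
    )
    if (anyNA(i)) abort("unknown peak id in selection")
  }
  if (!is.null(samples)) {
    j <- if (is.character(samples)) match(samples, mset$samples$sample_id) else
      which(if (is.logical(samples)) samples else seq_along(j) %in% samples)
    if (anyNA(j)) abort("unknown sample id in selection")
  }
  metabolome_set(mset$intensities[i, j, drop = FALSE],
                 mset$peaks[i, , drop = FALSE],
                 mset$samples[j, , drop = FALSE],
                 scale = mset$scale)
}

#' @describeIn metabolome_set long-format view: one row per
#'   (peak, sample) with intensity and joined metadata.
#' @param x a `metabolome_set`.
#' @param ... unused.
#' @method tidy metabolome_set
#' @export
tidy.metabolome_set <- function(x, ...) {
  long <- as_tibble(x$intensities, rownames = "peak_id") |>
    tidyr::pivot_longer(-"peak_id", names_to = "sample_id",
                        values_to = "intensity")
  long |>
    left_join(x$peaks, by = "peak_id") |>
    left_join(x$samples, by = "sample_id")
}

#' Standard analysis samples
#'
#' The comparative analyses use individual (non-pooled) samples from
#' standard-condition animals without postmortem delay. Pooled QC samples,
#' environment-condition macaques and delayed-dissection macaques are
#' carried in the table for the filtering/QC stages but excluded here.
#'
#' @param samples sample metadata tibble.
#' @param max_postmortem_hours samples at or above this delay are excluded
#'   (default 2 h; the delayed animals are at 4-6 h, the rest under 15 min).
#' @return Character vector of sample ids.
#' @export
analysis_samples <- function(samples, max_postmortem_hours = 2) {
  keep <- rep(TRUE, nrow(samples))
  if ("is_pooled" %in% names(samples)) keep <- keep & !samples$is_pooled
  if ("condition" %in% names(samples)) {
    keep <- keep & samples$condition == "standard"
  }
  if ("postmortem_delay" %in% names(samples)) {
    keep <- keep & (is.na(samples$postmortem_delay) |
                      samples$postmortem_delay < max_postmortem_hours)
  }
  samples$sample_id[keep]
}
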