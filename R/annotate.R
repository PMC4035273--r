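# Adduct mass shifts (Da) relative to the neutral monoisotopic mass. The
# values are the standard proton/ammonium/sodium/formate constants; tests
# cross-check them against an independent computation from atomic masses.
adduct_shifts_positive <- c(
  "[M+H]" = 1.007276,
  "[M+NH4]" = 18.033826,
  "[M+Na]" = 22.989221
)
adduct_shifts_negative <- c(
  "[M-H]" = -1.007276,
  "[M+FA-H]" = 44.998203
)

adduct_shift <- function(adduct) {
  all_shifts <- c(adduct_shifts_positive, adduct_shifts_negative)
  unname(all_shifts[adduct])
}

#' Accurate-mass adduct annotation of LC peaks
#'
#' For each peak, each candidate metabolite and each mode-appropriate
#' adduct ([M+H], [M+NH4], [M+Na] in positive mode; [M-H], [M+FA-H] in
#' negative mode), a match is reported when the relative deviation between
#' the observed m/z and the adduct m/z of the metabolite's neutral mass is
#' within `tol_ppm` parts per million. All matches are reported with their
#' signed ppm error.
#'
#' @param mset a [metabolome_set()] whose peaks carry `mz`.
#' @param mass_db tibble with `metabolite_id` and neutral monoisotopic
#'   `mass` (Da).
#' @param mode `"positive"` or `"negative"` ionization.
#' @param tol_ppm mass tolerance in ppm (default 5).
#' @return Tibble `peak_id`, `metabolite_id`, `adduct`, `ppm_error`.
#' @export
annotate_peaks <- function(mset, mass_db, mode = c("positive", "negative"),
                           tol_ppm = 5) {
  mode <- match.arg(mode)
  shifts <- if (mode == "positive") adduct_shifts_positive else
    adduct_shifts_negative
  pk <- mset$peaks
  if (!"mz" %in% names(pk)) abort("peaks need an `mz` column")
  keep <- which(!is.na(pk$mz))
  if (any(mass_db$mass <= 0)) abort("metabolite masses must be positive")
  out <- list()
  for (a in names(shifts)) {
    target <- mass_db$mass + shifts[[a]]
    # outer comparison peak x metabolite, reported sparsely
    for (i in keep) {
      ppm <- (pk$mz[i] - target) / target * 1e6
      hit <- which(abs(ppm) <= tol_ppm)
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- tibble(
          peak_id = pk$peak_id[i],
          metabolite_id = mass_db$metabolite_id[hit],
          adduct = a,
          ppm_error = ppm[hit]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(peak_id = character(0), metabolite_id = character(0),
                  adduct = character(0), ppm_error = numeric(0)))
  }
  bind_rows(out) |> arrange(.data$peak_id, .data$metabolite_id, .data$adduct)
}
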