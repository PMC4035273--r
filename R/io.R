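# Readers/writers for the package's plain-text interchange formats:
# tab-delimited matrices (first column = feature id, header = sample ids),
# tab-delimited metadata, GMT pathway files, two-column link TSVs, and a
# JSON dump of the synthetic-truth ledger.

#' Write / read a metabolome set as tab-delimited files
#'
#' Writes `<stem>_intensities.tsv` (first column `peak_id`, one column per
#' sample), `<stem>_peaks.tsv` and `<stem>_samples.tsv`.
#'
#' @param mset a [metabolome_set()].
#' @param stem path stem for the three files.
#' @return `write_metabolome()` the stem, invisibly; `read_metabolome()`
#'   the reconstructed [metabolome_set()].
#' @export
write_metabolome <- function(mset, stem) {
  mat <- as_tibble(mset$intensities, rownames = "peak_id")
  readr::write_tsv(mat, paste0(stem, "_intensities.tsv"))
  readr::write_tsv(mset$peaks, paste0(stem, "_peaks.tsv"))
  readr::write_tsv(mset$samples, paste0(stem, "_samples.tsv"))
  invisible(stem)
}

#' @rdname write_metabolome
#' @param scale scale of the stored values (see [metabolome_set()]).
#' @export
read_metabolome <- function(stem, scale = "intensity") {
  mat <- readr::read_tsv(paste0(stem, "_intensities.tsv"),
                         show_col_types = FALSE)
  peaks <- readr::read_tsv(paste0(stem, "_peaks.tsv"), show_col_types = FALSE)
  samples <- readr::read_tsv(paste0(stem, "_samples.tsv"),
                             show_col_types = FALSE)
  X <- as.matrix(mat[, -1, drop = FALSE])
  rownames(X) <- mat[[1]]
  metabolome_set(X, peaks, samples, scale = scale)
}

#' Write / read pathway sets in GMT format
#'
#' One pathway per line: name, description, then the member ids,
#' tab-separated. Enzyme sets are stored in a companion GMT
#' (`<path>.enzymes.gmt`) and direct links in `<path>.links.tsv` when
#' present.
#'
#' @param db a [pathway_db()].
#' @param path output GMT path for the metabolite sets.
#' @return `write_pathway_gmt()` the path, invisibly; `read_pathway_gmt()`
#'   a [pathway_db()].
#' @export
write_pathway_gmt <- function(db, path) {
  lines <- purrr::imap_chr(db$metabolite_sets, function(members, pid) {
    paste(c(pid, db$pathway_names[[pid]] %||% pid, members),
          collapse = "\t")
  })
  writeLines(lines, path)
  if (any(lengths(db$enzyme_sets) > 0)) {
    ez <- purrr::imap_chr(db$enzyme_sets, function(members, pid) {
      paste(c(pid, "enzymes", members), collapse = "\t")
    })
    writeLines(ez, paste0(path, ".enzymes.gmt"))
  }
  if (nrow(db$links) > 0) {
    readr::write_tsv(db$links, paste0(path, ".links.tsv"))
  }
  invisible(path)
}

#' @rdname write_pathway_gmt
#' @export
read_pathway_gmt <- function(path) {
  parse_gmt <- function(p) {
    lines <- readLines(p)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- purrr::map(parts, ~ .x[-(1:2)])
    names(sets) <- purrr::map_chr(parts, 1)
    attr(sets, "descriptions") <- setNames(purrr::map_chr(parts, 2),
                                           names(sets))
    sets
  }
  sets <- parse_gmt(path)
  descriptions <- attr(sets, "descriptions")
  attr(sets, "descriptions") <- NULL
  ez_path <- paste0(path, ".enzymes.gmt")
  links_path <- paste0(path, ".links.tsv")
  enzymes <- if (file.exists(ez_path)) {
    ez <- parse_gmt(ez_path)
    attr(ez, "descriptions") <- NULL
    ez
  } else {
    NULL
  }
  links <- if (file.exists(links_path)) {
    readr::read_tsv(links_path, show_col_types = FALSE)
  } else {
    NULL
  }
  pathway_db(sets, enzymes, links, names = descriptions)
}

#' Write the synthetic-truth ledger as JSON
#'
#' @param truth a `synthetic_truth` from [simulate_metabolome()].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(
      peak_effects = truth$peak_effects,
      pm_peaks = truth$pm_peaks,
      condition_peaks = truth$condition_peaks
    ),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write an expression table as TSV
#'
#' Gene x sample matrix with a leading `gene` column and a trailing
#' `exon_length` metadata column file.
#'
#' @param expr an `expression_set`.
#' @param stem path stem (`<stem>_expression.tsv`, `<stem>_genes.tsv`,
#'   `<stem>_samples.tsv`).
#' @return The stem, invisibly.
#' @export
write_expression <- function(expr, stem) {
  mat <- as_tibble(expr$values, rownames = "gene")
  readr::write_tsv(mat, paste0(stem, "_expression.tsv"))
  readr::write_tsv(expr$genes, paste0(stem, "_genes.tsv"))
  readr::write_tsv(expr$samples, paste0(stem, "_samples.tsv"))
  invisible(stem)
}
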