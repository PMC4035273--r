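#' Pathway database container
#'
#' Holds pathway -> metabolite sets, pathway -> enzyme sets, and direct
#' enzyme-metabolite reaction links.
#'
#' @param metabolite_sets named list: pathway id -> character vector of
#'   metabolite ids (no empty pathways).
#' @param enzyme_sets named list: pathway id -> character vector of enzyme
#'   (gene) ids; may be empty for a pathway.
#' @param links tibble with columns `enzyme_id`, `metabolite_id` of direct
#'   reaction links.
#' @param names optional named character of human-readable pathway names.
#' @return A `pathway_db` object.
#' @export
pathway_db <- function(metabolite_sets, enzyme_sets = NULL, links = NULL,
                       names = NULL) {
  if (length(metabolite_sets) == 0) abort("no pathways supplied")
  if (any(lengths(metabolite_sets) == 0)) abort("empty pathway in database")
  ids <- base::names(metabolite_sets)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("pathways must have unique names")
  }
  if (is.null(enzyme_sets)) {
    enzyme_sets <- setNames(vector("list", length(ids)), ids)
    enzyme_sets[] <- list(character(0))
  }
  if (is.null(links)) {
    links <- tibble(enzyme_id = character(0), metabolite_id = character(0))
  }
  structure(
    list(metabolite_sets = metabolite_sets,
         enzyme_sets = enzyme_sets[ids],
         links = as_tibble(links),
         pathway_names = names %||% setNames(ids, ids)),
    class = "pathway_db"
  )
}

#' @export
print.pathway_db <- function(x, ...) {
  cat("<pathway_db> ", length(x$metabolite_sets), " pathways, ",
      length(unique(unlist(x$metabolite_sets))), " metabolites, ",
      length(unique(unlist(x$enzyme_sets))), " enzymes, ",
      nrow(x$links), " direct links\n", sep = "")
  invisible(x)
}

#' @describeIn pathway_db one row per (pathway, metabolite) membership.
#' @param x a `pathway_db`.
#' @param ... unused.
#' @method tidy pathway_db
#' @export
tidy.pathway_db <- function(x, ...) {
  tibble(
    pathway_id = rep(base::names(x$metabolite_sets),
                     lengths(x$metabolite_sets)),
    metabolite_id = unlist(x$metabolite_sets, use.names = FALSE)
  )
}

pathway_universe <- function(db) sort(unique(unlist(db$metabolite_sets)))
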