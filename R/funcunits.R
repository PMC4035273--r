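#' Group metabolites and their enriched pathways into functional units
#'
#' Metabolites belonging to two or more over-represented pathways are
#' incrementally merged into functional units when their pathway sets are
#' sufficiently shared: with the default `"jaccard"` similarity, when
#' |A intersect B| / |A union B| exceeds `threshold` (two-thirds); the
#' `"min-fraction"` mode uses |A intersect B| / min(|A|, |B|) instead.
#' Merging is deterministic: at each step the highest-similarity eligible
#' pair is merged (ties broken by the lexicographically smallest sorted
#' member ids), a merged unit's pathway set being the union of its
#' members' sets, until no pair exceeds the threshold.
#'
#' @param metab_pathways named list: metabolite id -> character vector of
#'   its over-represented pathway ids.
#' @param similarity `"jaccard"` or `"min-fraction"`.
#' @param threshold similarity must strictly exceed this (default 2/3).
#' @return Tibble `unit`, `metabolites` (list-column), `pathways`
#'   (list-column, the union of members' sets), `n_metabolites`.
#' @examples
#' group_functional_units(list(a = c("P1", "P2"), b = c("P1", "P2"),
#'                             c = c("P3", "P4", "P5")))
#' @export
group_functional_units <- function(metab_pathways,
                                   similarity = c("jaccard", "min-fraction"),
                                   threshold = 2 / 3) {
  similarity <- match.arg(similarity)
  if (length(metab_pathways) == 0) {
    return(tibble(unit = character(0), metabolites = list(),
                  pathways = list(), n_metabolites = integer(0)))
  }
  eligible <- metab_pathways[lengths(metab_pathways) >= 2]
  if (length(eligible) == 0) {
    return(tibble(unit = character(0), metabolites = list(),
                  pathways = list(), n_metabolites = integer(0)))
  }
  eligible <- eligible[order(names(eligible))]
  units <- purrr::imap(eligible, function(pw, id) {
    list(members = id, pathways = sort(unique(pw)))
  })
  sim_fun <- function(a, b) {
    i <- length(intersect(a, b))
    if (similarity == "jaccard") i / length(union(a, b)) else
      i / min(length(a), length(b))
  }
  repeat {
    n_u <- length(units)
    if (n_u < 2) break
    best <- NULL
    best_sim <- threshold
    for (i in seq_len(n_u - 1)) {
      for (j in seq(i + 1, n_u)) {
        s <- sim_fun(units[[i]]$pathways, units[[j]]$pathways)
        if (s > best_sim + 1e-12) {
          best <- c(i, j)
          best_sim <- s
        } else if (!is.null(best) && abs(s - best_sim) <= 1e-12) {
          # tie: prefer the pair with the smaller sorted member ids
          cand <- sort(c(units[[i]]$members, units[[j]]$members))
          cur <- sort(c(units[[best[1]]]$members, units[[best[2]]]$members))
          if (paste(cand, collapse = "|") < paste(cur, collapse = "|")) {
            best <- c(i, j)
          }
        }
      }
    }
    if (is.null(best)) break
    merged <- list(
      members = sort(c(units[[best[1]]]$members, units[[best[2]]]$members)),
      pathways = sort(union(units[[best[1]]]$pathways,
                            units[[best[2]]]$pathways))
    )
    units <- c(units[-best], list(merged))
  }
  # stable output order by first member id
  ord <- order(purrr::map_chr(units, ~ .x$members[1]))
  units <- units[ord]
  tibble(
    unit = sprintf("unit%02d", seq_along(units)),
    metabolites = purrr::map(units, "members"),
    pathways = purrr::map(units, "pathways"),
    n_metabolites = purrr::map_int(units, ~ length(.x$members))
  )
}
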