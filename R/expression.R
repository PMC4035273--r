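#' Expression from exon read counts
#'
#' Expression is quantified as reads per 100 bp of mappable exon for a
#' 100-bp read: `N * 100 / (L - 99)`, where `N` is the number of reads
#' aligned to the gene's exons and `L` the total exon length in bp. The
#' denominator is the number of distinct read start positions, so the
#' formula is undefined for `L <= 99`.
#'
#' @param n_reads non-negative read counts.
#' @param exon_length total exon lengths (bp), all >= 100.
#' @return Numeric expression values.
#' @examples
#' quantify_expression(100, 199) # 100
#' @export
quantify_expression <- function(n_reads, exon_length) {
  if (any(exon_length <= 99)) abort("`exon_length` must exceed 99 bp")
  if (any(n_reads < 0)) abort("`n_reads` must be non-negative")
  n_reads * 100 / (exon_length - 99)
}

#' Minimal-expression floor
#'
#' The detection cutoff is the `q` quantile of all nonzero expression
#' values in the table; a gene is retained when its mean expression in at
#' least one (species, tissue) cell exceeds the cutoff.
#'
#' @param expr an `expression_set` (see [simulate_expression()]) or a
#'   genes x samples matrix accompanied by `samples` metadata.
#' @param q quantile of nonzero values used as the floor (default 0.05).
#' @param samples sample metadata when `expr` is a plain matrix.
#' @return Character vector of retained gene ids.
#' @export
expression_floor <- function(expr, q = 0.05, samples = NULL) {
  if (inherits(expr, "expression_set")) {
    V <- expr$values
    samples <- expr$samples
  } else {
    V <- as.matrix(expr)
    if (is.null(samples)) abort("supply `samples` metadata with a matrix")
  }
  nz <- V[V > 0]
  if (length(nz) == 0) abort("all-zero expression table")
  cutoff <- quantile(nz, q, names = FALSE)
  cell <- paste(samples$species, samples$tissue)
  keep <- rep(FALSE, nrow(V))
  for (cl in unique(cell)) {
    j <- which(cell == cl)
    keep <- keep | rowMeans(V[, j, drop = FALSE]) > cutoff
  }
  rownames(V)[keep]
}

#' Quantile-rule classification of tissue- and species-specific genes
#'
#' For each gene, the mean log2 expression difference is computed for every
#' pair of tissues (pooled over species) and for every pair of species
#' within each tissue. A gene is tissue-specific for tissue t when its
#' difference against every other tissue falls in the upper (or every one
#' in the lower) `tissue_q` tail of the corresponding per-pair difference
#' distribution; species-specific in a tissue analogously with the
#' `species_q` tails. Primates are compared against the other primates;
#' the mouse against all primates. Tail thresholds are per comparison
#' pair.
#'
#' @param expr an `expression_set`; values are log2-transformed internally
#'   (+1 pseudocount) if on the linear scale.
#' @param tissue_q tail fraction for the tissue comparison (default 0.10).
#' @param species_q tail fraction for the species comparison (default 0.05).
#' @param log2_input set `TRUE` if `expr$values` are already log2.
#' @return Tibble `gene`, `scope` (`"tissue"` or `"species"`), `tissue`,
#'   `label` (the tissue or species), `direction`.
#' @export
classify_specific_genes <- function(expr, tissue_q = 0.10, species_q = 0.05,
                                    log2_input = FALSE) {
  V <- expr$values
  if (!log2_input) V <- log2(V + 1)
  smp <- expr$samples
  tissues <- unique(smp$tissue)
  species <- unique(smp$species)
  if (length(tissues) < 2 || length(species) < 2) {
    abort("need at least 2 tissues and 2 species")
  }
  genes <- rownames(V)
  out <- list()

  # ---- tissue scope: per-pair mean differences pooled over species ----
  tissue_means <- purrr::map(tissues, function(t) {
    rowMeans(V[, smp$tissue == t, drop = FALSE], na.rm = TRUE)
  }) |> setNames(tissues)
  pair_diff <- list()
  for (a in tissues) for (b in tissues) {
    if (a == b) next
    pair_diff[[paste(a, b)]] <- tissue_means[[a]] - tissue_means[[b]]
  }
  pair_thresholds <- purrr::map(pair_diff, function(d) {
    c(lo = quantile(d, tissue_q, names = FALSE),
      hi = quantile(d, 1 - tissue_q, names = FALSE))
  })
  for (t in tissues) {
    others <- setdiff(tissues, t)
    up <- rep(TRUE, length(genes))
    down <- rep(TRUE, length(genes))
    for (o in others) {
      d <- pair_diff[[paste(t, o)]]
      th <- pair_thresholds[[paste(t, o)]]
      up <- up & d >= th["hi"]
      down <- down & d <= th["lo"]
    }
    if (any(up)) {
      out[[length(out) + 1L]] <- tibble(gene = genes[up], scope = "tissue",
                                        tissue = t, label = t,
                                        direction = "up")
    }
    if (any(down)) {
      out[[length(out) + 1L]] <- tibble(gene = genes[down], scope = "tissue",
                                        tissue = t, label = t,
                                        direction = "down")
    }
  }

  # ---- species scope: per tissue, per species-pair differences ----
  primates <- intersect(species, c("human", "chimpanzee", "macaque"))
  for (t in tissues) {
    sp_means <- purrr::map(species, function(s) {
      j <- which(smp$tissue == t & smp$species == s)
      if (length(j) == 0) return(NULL)
      rowMeans(V[, j, drop = FALSE], na.rm = TRUE)
    }) |> setNames(species)
    sp_means <- sp_means[!purrr::map_lgl(sp_means, is.null)]
    for (s in names(sp_means)) {
      comp <- if (s %in% primates) setdiff(primates, s) else
        intersect(primates, names(sp_means))
      comp <- intersect(comp, names(sp_means))
      if (length(comp) == 0) next
      up <- rep(TRUE, length(genes))
      down <- rep(TRUE, length(genes))
      for (o in comp) {
        d <- sp_means[[s]] - sp_means[[o]]
        lo <- quantile(d, species_q, names = FALSE)
        hi <- quantile(d, 1 - species_q, names = FALSE)
        up <- up & d >= hi
        down <- down & d <= lo
      }
      if (any(up)) {
        out[[length(out) + 1L]] <- tibble(gene = genes[up],
                                          scope = "species", tissue = t,
                                          label = s, direction = "up")
      }
      if (any(down)) {
        out[[length(out) + 1L]] <- tibble(gene = genes[down],
                                          scope = "species", tissue = t,
                                          label = s, direction = "down")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(gene = character(0), scope = character(0),
                  tissue = character(0), label = character(0),
                  direction = character(0)))
  }
  bind_rows(out) |> arrange(.data$gene, .data$scope, .data$tissue)
}

# Enzymes whose expression profile matches a (species, tissue) metabolite
# group: species-specific in the same tissue for the same species.
matching_enzymes <- function(spec, species, tissue) {
  spec |>
    filter(.data$scope == "species", .data$label == species,
           .data$tissue == tissue) |>
    pull("gene") |>
    unique()
}

#' Pathway-level metabolite-enzyme agreement
#'
#' For each enriched pathway of a (lineage, tissue) metabolite group,
#' counts (i) the pathway enzymes whose expression profile is specific to
#' the same species in the same tissue, and (ii) those among them that are
#' directly linked to the group's metabolites within the pathway.
#' Significance for (i) is assessed against size-matched random enzyme
#' sets drawn from the measured enzymes, for (ii) against size-matched
#' random metabolite sets drawn from the background (both add-one p).
#'
#' @param enriched_pathways character pathway ids.
#' @param metab_group character metabolite ids of the group.
#' @param spec gene specificity tibble from [classify_specific_genes()].
#' @param db a [pathway_db()].
#' @param species,tissue the group's species and tissue labels.
#' @param background metabolite universe for the resampling of (ii);
#'   defaults to all metabolites in the database.
#' @param n_perm resamples.
#' @param seed RNG seed.
#' @return Tibble per pathway: `pathway_id`, `n_enzymes`,
#'   `matching`, `p_matching`, `linked_matching`, `p_linked`.
#' @export
agreement_pathway_test <- function(enriched_pathways, metab_group, spec, db,
                                   species, tissue,
                                   background = NULL, n_perm = 1000,
                                   seed = 1L) {
  background <- background %||% pathway_universe(db)
  match_set <- matching_enzymes(spec, species, tissue)
  all_enzymes <- sort(unique(unlist(db$enzyme_sets)))
  out <- list()
  withr::with_seed(seed, {
    for (pid in enriched_pathways) {
      ez <- db$enzyme_sets[[pid]]
      if (is.null(ez) || length(ez) == 0) next
      m_obs <- length(intersect(ez, match_set))
      null_m <- purrr::map_int(seq_len(n_perm), function(b) {
        length(intersect(sample(all_enzymes, length(ez)), match_set))
      })
      p_m <- add_one_p(sum(null_m >= m_obs), n_perm)

      linked_to <- function(mets) {
        lk <- db$links |>
          filter(.data$enzyme_id %in% ez, .data$metabolite_id %in% mets)
        unique(lk$enzyme_id)
      }
      l_obs <- length(intersect(linked_to(metab_group), match_set))
      nll <- purrr::map_int(seq_len(n_perm), function(b) {
        smp_m <- sample(background, min(length(metab_group),
                                        length(background)))
        length(intersect(linked_to(smp_m), match_set))
      })
      p_l <- add_one_p(sum(nll >= l_obs), n_perm)
      out[[pid]] <- tibble(
        pathway_id = pid, n_enzymes = length(ez),
        matching = m_obs, p_matching = p_m,
        linked_matching = l_obs, p_linked = p_l
      )
    }
  })
  if (length(out) == 0) {
    return(tibble(pathway_id = character(0), n_enzymes = integer(0),
                  matching = integer(0), p_matching = numeric(0),
                  linked_matching = integer(0), p_linked = numeric(0)))
  }
  bind_rows(out)
}

#' Link-level metabolite-enzyme agreement
#'
#' The observed proportion of matching-profile enzymes among all enzymes
#' directly linked to the group's metabolites is compared with the
#' proportions obtained for size-matched metabolite sets sampled from the
#' metabolites that interact with any measured enzyme.
#'
#' @param metab_group character metabolite ids (must have >= 1 linked
#'   enzyme overall).
#' @param spec gene specificity tibble from [classify_specific_genes()].
#' @param db a [pathway_db()].
#' @param species,tissue the group's species and tissue labels.
#' @param n_perm resamples.
#' @param seed RNG seed.
#' @return A list: `proportion` (observed matching proportion),
#'   `n_linked`, `perm_p` (add-one upper-tail p).
#' @export
agreement_link_test <- function(metab_group, spec, db, species, tissue,
                                n_perm = 1000, seed = 1L) {
  match_set <- matching_enzymes(spec, species, tissue)
  linked_enzymes <- function(mets) {
    unique(db$links$enzyme_id[db$links$metabolite_id %in% mets])
  }
  obs_enz <- linked_enzymes(metab_group)
  if (length(obs_enz) == 0) abort("metabolite group has no linked enzymes")
  obs_prop <- mean(obs_enz %in% match_set)
  linkable <- unique(db$links$metabolite_id)
  exceed <- withr::with_seed(seed, {
    sum(purrr::map_dbl(seq_len(n_perm), function(b) {
      enz <- linked_enzymes(sample(linkable,
                                   min(length(metab_group), length(linkable))))
      if (length(enz) == 0) return(-Inf)
      mean(enz %in% match_set)
    }) >= obs_prop)
  })
  list(proportion = obs_prop, n_linked = length(obs_enz),
       perm_p = add_one_p(exceed, n_perm))
}
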