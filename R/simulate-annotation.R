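#' Simulate metabolite annotation and a pathway database
#'
#' Maps a configurable fraction of peaks to metabolites (the study annotated
#' 1,535 of 10,615 peaks, ~14.5%), assigns each metabolite a monoisotopic
#' neutral mass, and samples pathways of metabolites and enzymes together
#' with direct enzyme-metabolite reaction links. Annotated LC peaks are
#' given an m/z consistent with a randomly chosen mode-appropriate adduct of
#' their metabolite, so accurate-mass annotation can re-derive the mapping.
#'
#' @param peaks peak metadata tibble (from [simulate_metabolome()]), or an
#'   integer number of peaks to invent ids for.
#' @param n_metabolites number of metabolites with known masses.
#' @param n_pathways number of pathways.
#' @param pathway_size_range integer range of metabolites per pathway
#'   (minimum 2).
#' @param annotated_fraction fraction of peaks mapped to a metabolite.
#' @param enzymes_per_pathway integer range of enzymes per pathway.
#' @param link_fraction fraction of (enzyme, pathway-metabolite) pairs
#'   emitted as direct reaction links.
#' @param seed RNG seed.
#' @return A list: `mass_db` (tibble `metabolite_id`, `mass`, `hmdb_id`),
#'   `annotation` (tibble `peak_id`, `metabolite_id`, `adduct`),
#'   `pathways` (a [pathway_db()]).
#' @export
simulate_annotation <- function(peaks, n_metabolites = 500, n_pathways = 60,
                                pathway_size_range = c(5, 40),
                                annotated_fraction = 1535 / 10615,
                                enzymes_per_pathway = c(5, 30),
                                link_fraction = 0.3,
                                seed = 1L) {
  if (is.numeric(peaks) && length(peaks) == 1) {
    peaks <- tibble(peak_id = sprintf("pk%05d", seq_len(peaks)),
                    dataset = "posLC", mz = NA_real_)
  }
  if (n_metabolites > nrow(peaks)) {
    abort("`n_metabolites` cannot exceed the number of peaks")
  }
  if (pathway_size_range[1] < 2) abort("pathway sizes must be at least 2")
  withr::with_seed(seed, {
    met_ids <- sprintf("met%04d", seq_len(n_metabolites))
    mass_db <- tibble(
      metabolite_id = met_ids,
      mass = round(runif(n_metabolites, 80, 900), 5),
      hmdb_id = sprintf("HMDB%07d", sample.int(9999999L, n_metabolites))
    )

    n_ann <- round(annotated_fraction * nrow(peaks))
    annotation <- tibble(peak_id = character(0), metabolite_id = character(0),
                         adduct = character(0))
    if (n_ann > 0) {
      ann_peaks <- sample(peaks$peak_id, n_ann)
      annotation <- tibble(
        peak_id = sort(ann_peaks),
        metabolite_id = sample(met_ids, n_ann, replace = TRUE)
      )
      # give annotated LC peaks an adduct-consistent m/z
      ann <- annotation |>
        left_join(peaks[, c("peak_id", "dataset")], by = "peak_id") |>
        left_join(mass_db[, c("metabolite_id", "mass")], by = "metabolite_id")
      adduct <- purrr::map_chr(ann$dataset, function(ds) {
        if (identical(ds, "negLC")) sample(names(adduct_shifts_negative), 1)
        else sample(names(adduct_shifts_positive), 1)
      })
      annotation$adduct <- ifelse(ann$dataset == "GC", NA_character_, adduct)
      annotation$mz <- ifelse(
        ann$dataset == "GC", NA_real_,
        ann$mass + adduct_shift(annotation$adduct)
      )
    }

    sizes <- sample(seq(pathway_size_range[1], pathway_size_range[2]),
                    n_pathways, replace = TRUE)
    pw_ids <- sprintf("path%03d", seq_len(n_pathways))
    metabolite_sets <- setNames(
      purrr::map(sizes, ~ sort(sample(met_ids, min(.x, n_metabolites)))),
      pw_ids
    )
    enzyme_pool <- sprintf("ENZ%04d", seq_len(600))
    ez_sizes <- sample(seq(enzymes_per_pathway[1], enzymes_per_pathway[2]),
                       n_pathways, replace = TRUE)
    enzyme_sets <- setNames(
      purrr::map(ez_sizes, ~ sort(sample(enzyme_pool, .x))), pw_ids
    )
    links <- purrr::map2(enzyme_sets, metabolite_sets, function(ez, mt) {
      pairs <- tidyr::crossing(enzyme_id = ez, metabolite_id = mt)
      pairs[runif(nrow(pairs)) < link_fraction, ]
    }) |>
      bind_rows() |>
      distinct()
    list(
      mass_db = mass_db,
      annotation = annotation,
      pathways = pathway_db(metabolite_sets, enzyme_sets, links)
    )
  })
}

#' Simulate an enzyme expression table with partially concordant profiles
#'
#' Enzymes directly linked to metabolites carrying planted species-specific
#' concentration shifts receive a matching species-specific expression shift
#' with probability `concordance`; all other genes are drawn from the null
#' (plus a small background rate of independent species-specific genes).
#'
#' @param db a [pathway_db()] supplying the enzyme universe and links.
#' @param truth a `synthetic_truth` from [simulate_metabolome()].
#' @param annotation peak -> metabolite mapping (tibble with `peak_id`,
#'   `metabolite_id`), needed to connect planted peak effects to enzymes.
#' @param concordance probability in \[0, 1\] that a linked enzyme of a
#'   planted metabolite is planted concordantly.
#' @param n_individuals expression individuals per species (study: 6).
#' @param tissues tissue names.
#' @param delta_expr planted expression shift (log2 units).
#' @param background_rate probability of an independent species-specific
#'   planting per (gene, tissue).
#' @param noise_sd per-sample expression noise sd (log2).
#' @param seed RNG seed.
#' @return A list: `expr` (an `expression_set`: genes x samples matrix with
#'   gene/sample tibbles) and `specific_genes` (tibble of planted
#'   species-specific gene profiles: `gene`, `tissue`, `lineage`,
#'   `direction`, `source`).
#' @export
simulate_expression <- function(db, truth, annotation, concordance = 0.5,
                                n_individuals = 6,
                                tissues = c("PFC", "V1", "CBC", "kidney",
                                            "muscle"),
                                delta_expr = 1.5, background_rate = 0.002,
                                noise_sd = 0.5, seed = 1L) {
  if (concordance < 0 || concordance > 1) {
    abort("`concordance` must lie in [0, 1]")
  }
  genes <- sort(unique(c(unlist(db$enzyme_sets), db$links$enzyme_id)))
  species <- c("human", "chimpanzee", "macaque", "mouse")
  withr::with_seed(seed, {
    planted_met <- truth$peak_effects |>
      inner_join(annotation[, c("peak_id", "metabolite_id")], by = "peak_id") |>
      distinct(.data$metabolite_id, .data$tissue, .data$lineage,
               .data$direction)
    linked <- planted_met |>
      inner_join(db$links, by = "metabolite_id",
                 relationship = "many-to-many") |>
      distinct(.data$enzyme_id, .data$tissue, .data$lineage, .data$direction)
    if (nrow(linked) > 0) {
      keep <- runif(nrow(linked)) < concordance
      linked <- linked[keep, , drop = FALSE]
    }
    conc <- if (nrow(linked) > 0) {
      linked |>
        distinct(.data$enzyme_id, .data$tissue, .data$lineage,
                 .keep_all = TRUE) |>
        rename(gene = "enzyme_id") |>
        mutate(source = "concordant")
    } else {
      tibble(gene = character(0), tissue = character(0), lineage = character(0),
             direction = character(0), source = character(0))
    }

    # independent background plantings
    bg <- tidyr::crossing(gene = genes, tissue = tissues) |>
      filter(runif(n()) < background_rate) |>
      mutate(
        lineage = sample(names(lineage_species), n(), replace = TRUE),
        direction = sample(c("up", "down"), n(), replace = TRUE),
        source = "background"
      )
    specific <- bind_rows(conc, bg) |>
      distinct(.data$gene, .data$tissue, .data$lineage, .keep_all = TRUE)

    samples <- tidyr::crossing(
      species = species, individual = seq_len(n_individuals),
      tissue = tissues
    ) |>
      mutate(sample_id = sprintf("%s_%02d.%s", .data$species,
                                 .data$individual, .data$tissue)) |>
      select("sample_id", "species", "tissue")

    base_gene <- rnorm(length(genes), 5, 1.5)
    tissue_off <- matrix(rnorm(length(genes) * length(tissues), 0, 1),
                         length(genes), length(tissues),
                         dimnames = list(genes, tissues))
    M <- matrix(0, length(genes), nrow(samples),
                dimnames = list(genes, samples$sample_id))
    for (t in tissues) {
      jt <- which(samples$tissue == t)
      M[, jt] <- base_gene + tissue_off[, t]
    }
    if (nrow(specific) > 0) {
      for (k in seq_len(nrow(specific))) {
        s <- specific[k, ]
        j <- which(samples$species == lineage_species[[s$lineage]] &
                     samples$tissue == s$tissue)
        i <- match(s$gene, genes)
        M[i, j] <- M[i, j] + ifelse(s$direction == "up", 1, -1) * delta_expr
      }
    }
    expr <- 2^(M + rnorm(length(M), 0, noise_sd))
    expr_set <- structure(
      list(values = expr,
           genes = tibble(gene = genes,
                          exon_length = sample(500:5000, length(genes),
                                               replace = TRUE)),
           samples = samples),
      class = "expression_set"
    )
    list(expr = expr_set, specific_genes = specific)
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  invisible(x)
}
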