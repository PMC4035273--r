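#' Run the full divergence pipeline on synthetic or supplied data
#'
#' Composes the stages in their analysis order: peak filtering (LC and GC)
#' with PCA outlier removal, within-tissue normalization, postmortem-peak
#' exclusion, the permutation ANOVA gate (all-species and primate modes),
#' species-specific classification with composite tissues, the multi-tissue
#' exclusion, and the divergence-vs-branch-length regression. Returns a
#' machine-readable report of per-stage counts together with the result
#' objects.
#'
#' A single `seed` drives every stochastic stage through a fixed counter
#' scheme, so stages re-run in isolation with their derived seed reproduce
#' the pipeline's results.
#'
#' @param config list: either `sim` (a [sim_config()]) to generate data, or
#'   `mset` (+ optional `truth`) to analyse supplied data; optional
#'   `phylogeny`, `n_perm` (default 200), `cutoff` (0.01), `fdr` (0.05),
#'   `pm_q` (0.05), `seed` (1), `run_filters` (TRUE).
#' @return A `pipeline_report`: list with `counts` (named stage counts),
#'   `mset` (normalized), `gates`, `assignment`, `unique_assignment`,
#'   `divergence` and `pm_flags`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(sim = NULL, mset = NULL, truth = NULL, phylogeny = make_phylogeny(),
         n_perm = 200, cutoff = 0.01, fdr = 0.05, pm_q = 0.05, seed = 1L,
         run_filters = TRUE),
    config
  )
  if (is.null(cfg$mset)) {
    if (is.null(cfg$sim)) cfg$sim <- sim_config()
    sim <- simulate_metabolome(cfg$sim, cfg$phylogeny)
    mset <- sim$mset
    cfg$truth <- sim$truth
  } else {
    mset <- cfg$mset
  }
  counts <- list(input_peaks = nrow(mset$intensities),
                 input_samples = ncol(mset$intensities))

  if (cfg$run_filters) {
    parts <- list()
    reports <- list()
    removed <- character(0)
    for (ds in intersect(c("posLC", "negLC"), unique(mset$peaks$dataset))) {
      sub <- subset_mset(mset, peaks = mset$peaks$dataset == ds)
      out <- tryCatch(detect_outlier_samples(sub), error = function(e)
        character(0))
      fl <- filter_lcms_peaks(sub, exclude_samples = out)
      parts[[ds]] <- fl$mset
      reports[[ds]] <- fl$report
      removed <- union(removed, out)
    }
    if ("GC" %in% mset$peaks$dataset) {
      sub <- subset_mset(mset, peaks = mset$peaks$dataset == "GC")
      out <- tryCatch(detect_outlier_samples(sub), error = function(e)
        character(0))
      is_tbl <- tibble(mass = c(150, 320), rt = c(4.5, 9.0))
      fl <- filter_gcms_peaks(sub, is_tbl, exclude_samples = out)
      parts[["GC"]] <- fl$mset
      reports[["GC"]] <- fl$report
      removed <- union(removed, out)
    }
    keep_samples <- setdiff(mset$samples$sample_id, removed)
    parts <- purrr::map(parts, function(p) {
      subset_mset(p, samples = intersect(keep_samples, p$samples$sample_id))
    })
    common <- Reduce(intersect, purrr::map(parts, ~ .x$samples$sample_id))
    parts <- purrr::map(parts, ~ subset_mset(.x, samples = common))
    mset <- metabolome_set(
      do.call(rbind, purrr::map(parts, "intensities")),
      bind_rows(purrr::map(parts, "peaks")),
      parts[[1]]$samples
    )
    counts$filtered_peaks <- nrow(mset$intensities)
    counts$removed_outlier_samples <- length(removed)
    attr(counts, "filter_reports") <- reports
  }

  mset <- normalize_peaks(mset)
  pm <- flag_postmortem_peaks(mset, q = cfg$pm_q)
  counts$pm_flagged <- length(unique(pm$peak_id))

  pf_sp_all <- permutation_fdr(mset, "species", mode = "all",
                               cutoff = cfg$cutoff, n_perm = cfg$n_perm,
                               seed = derive_seed(cfg$seed, 1))
  pf_int_all <- permutation_fdr(mset, "tissue:species", mode = "all",
                                cutoff = cfg$cutoff, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, 2))
  pf_sp_pri <- permutation_fdr(mset, "species", mode = "primates",
                               cutoff = cfg$cutoff, n_perm = cfg$n_perm,
                               seed = derive_seed(cfg$seed, 3))
  pf_int_pri <- permutation_fdr(mset, "tissue:species", mode = "primates",
                                cutoff = cfg$cutoff, n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, 4))
  gate_all <- gate_peaks(pf_sp_all, pf_int_all, cfg$cutoff, cfg$fdr)
  gate_pri <- gate_peaks(pf_sp_pri, pf_int_pri, cfg$cutoff, cfg$fdr)
  counts$gate_all_species <- length(gate_all)
  counts$gate_primates <- length(gate_pri)

  # postmortem-affected peaks are excluded from the gated sets globally
  pm_ids <- unique(pm$peak_id)
  gate_all <- setdiff(gate_all, pm_ids)
  gate_pri <- setdiff(gate_pri, pm_ids)

  assignment <- classify_species_specific(
    mset, gate_primate = gate_pri, gate_mouse = gate_all,
    cutoff = cfg$cutoff, fdr = cfg$fdr, n_perm = cfg$n_perm,
    seed = derive_seed(cfg$seed, 5)
  )
  counts$assignments <- nrow(assignment$assignments)
  unique_assignment <- exclude_multitissue(assignment)
  counts$unique_assignments <- nrow(unique_assignment$assignments)

  divergence <- tryCatch(
    divergence_regression(assignment, phylo = cfg$phylogeny),
    error = function(e) NULL
  )
  structure(
    list(counts = counts, mset = mset, pm_flags = pm,
         gates = list(all = gate_all, primates = gate_pri),
         assignment = assignment, unique_assignment = unique_assignment,
         divergence = divergence, truth = cfg$truth),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$counts)) {
    cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn run_pipeline stage counts as a one-row tibble.
#' @param x a `pipeline_report`.
#' @param ... unused.
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  as_tibble(x$counts)
}
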