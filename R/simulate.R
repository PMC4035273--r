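#' Simulate a multi-species, multi-tissue metabolome peak table
#'
#' Draws per-(peak, tissue) log2 baselines, plants lineage-specific
#' concentration shifts whose per-lineage frequency scales with branch
#' length (with optional tissue accelerations), adds i.i.d. sample noise,
#' censors intensities below the detection limit to zero, and emits pooled
#' QC samples (LC datasets), postmortem-delayed macaques and
#' environment-condition macaques with their own planted shifts.
#'
#' Shifts planted on the `macaque_anc` lineage are applied to macaque
#' samples and `mouse_anc` shifts to mouse samples, mirroring the
#' species-level contrasts used downstream. Identical configurations
#' (including the seed) produce identical output.
#'
#' @param config a [sim_config()].
#' @param phylogeny a [make_phylogeny()].
#' @return A list with `mset` (a [metabolome_set()] on the intensity scale)
#'   and `truth` (a `synthetic_truth` object: `peak_effects`,
#'   `pm_peaks`, `condition_peaks` plus the generating config).
#' @examples
#' sim <- simulate_metabolome(sim_config(n_peaks = 50, n_individuals = 3,
#'                                       seed = 7))
#' sim$mset
#' @export
simulate_metabolome <- function(config = sim_config(),
                                phylogeny = make_phylogeny()) {
  stopifnot(inherits(config, "sim_config"), inherits(phylogeny, "phylogeny"))
  withr::with_seed(config$seed, simulate_metabolome_impl(config, phylogeny))
}

simulate_metabolome_impl <- function(cfg, phylo) {
  tissues <- cfg$tissues
  n_peaks <- cfg$n_peaks
  peak_ids <- sprintf("pk%05d", seq_len(n_peaks))

  dataset <- sample(names(cfg$dataset_fractions), n_peaks, replace = TRUE,
                    prob = cfg$dataset_fractions)
  peaks <- tibble(
    peak_id = peak_ids,
    dataset = dataset,
    mz = ifelse(dataset != "GC", round(runif(n_peaks, 80, 1000), 4), NA_real_),
    mass = ifelse(dataset == "GC", round(runif(n_peaks, 70, 600)), NA_real_),
    rt = round(runif(n_peaks, 0.5, 12), 3),
    rt_spread = ifelse(dataset == "GC", round(abs(rnorm(n_peaks, 0, 0.3)), 3),
                       NA_real_),
    distinct_background = TRUE
  )

  samples <- build_sample_sheet(cfg)
  n_samp <- nrow(samples)

  # per-(peak, tissue) baseline on the log2 scale
  base_peak <- rnorm(n_peaks, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  tissue_off <- matrix(rnorm(n_peaks * length(tissues), 0, cfg$tissue_sd),
                       n_peaks, length(tissues),
                       dimnames = list(peak_ids, tissues))

  # planted lineage effects
  effects <- plant_lineage_effects(cfg, phylo, peak_ids, tissues)

  # planted postmortem / condition effects
  pm_peaks <- character(0)
  pm_dir <- numeric(0)
  if (cfg$n_postmortem > 0 && cfg$pm_effect_fraction > 0 && cfg$pm_delta > 0) {
    pm_peaks <- sort(sample(peak_ids, round(cfg$pm_effect_fraction * n_peaks)))
    pm_dir <- sample(c(-1, 1), length(pm_peaks), replace = TRUE)
  }
  cond_effects <- plant_condition_effects(cfg, peak_ids)

  # mean matrix: baseline + tissue offset + lineage shift (+ pm/cond shifts)
  M <- matrix(0, n_peaks, n_samp, dimnames = list(peak_ids, samples$sample_id))
  for (t in tissues) {
    jt <- which(samples$tissue == t & !samples$is_pooled)
    M[, jt] <- base_peak + tissue_off[, t]
  }
  if (nrow(effects) > 0) {
    for (k in seq_len(nrow(effects))) {
      e <- effects[k, ]
      sp <- lineage_species[[e$lineage]]
      j <- which(samples$species == sp & samples$tissue == e$tissue &
                   !samples$is_pooled)
      i <- match(e$peak_id, peak_ids)
      M[i, j] <- M[i, j] + ifelse(e$direction == "up", 1, -1) * e$delta
    }
  }
  if (length(pm_peaks) > 0) {
    jpm <- which(!samples$is_pooled & samples$postmortem_delay >= 2)
    i <- match(pm_peaks, peak_ids)
    M[i, jpm] <- M[i, jpm] + pm_dir * cfg$pm_delta
  }
  if (nrow(cond_effects) > 0) {
    for (cond in unique(cond_effects$condition)) {
      ce <- cond_effects[cond_effects$condition == cond, ]
      jc <- which(samples$condition == cond & !samples$is_pooled)
      i <- match(ce$peak_id, peak_ids)
      sgn <- ifelse(ce$direction == "up", 1, -1)
      M[i, jc] <- M[i, jc] + sgn * cfg$cond_delta
      # concordant human shift for a subset of condition peaks
      conc <- ce$human_concordant
      if (any(conc)) {
        jh <- which(samples$species == "human" & !samples$is_pooled)
        ih <- match(ce$peak_id[conc], peak_ids)
        M[ih, jh] <- M[ih, jh] + sgn[conc] * cfg$cond_delta
      }
    }
  }

  ind <- which(!samples$is_pooled)
  L <- M
  L[, ind] <- M[, ind] + rnorm(n_peaks * length(ind), 0, cfg$noise_sd)

  # pooled QC samples: per-tissue linear means of individual samples
  pooled_j <- which(samples$is_pooled)
  if (length(pooled_j) > 0) {
    lin_ind <- 2^L[, ind, drop = FALSE]
    tiss_ind <- samples$tissue[ind]
    for (j in pooled_j) {
      jt <- which(tiss_ind == samples$tissue[j])
      L[, j] <- log2(rowMeans(lin_ind[, jt, drop = FALSE])) +
        rnorm(n_peaks, 0, cfg$pooled_noise_sd)
    }
  }

  intensities <- 2^L
  intensities[intensities < cfg$detection_limit] <- 0
  # pooled QC injections exist only in the LC runs; GC rows carry zeros there
  if (length(pooled_j) > 0) {
    intensities[peaks$dataset == "GC", pooled_j] <- 0
  }

  truth <- structure(
    list(
      peak_effects = effects,
      pm_peaks = pm_peaks,
      condition_peaks = cond_effects,
      config = cfg, phylogeny = phylo
    ),
    class = "synthetic_truth"
  )
  list(mset = metabolome_set(intensities, peaks, samples), truth = truth)
}

build_sample_sheet <- function(cfg) {
  tissues <- cfg$tissues
  species <- c("human", "chimpanzee", "macaque", "mouse")
  age_range <- list(human = c(20, 60), chimpanzee = c(10, 40),
                    macaque = c(2, 14), mouse = c(0.3, 1.5))

  make_ind <- function(sp, ids, condition, pm_delay) {
    tibble(
      individual_id = ids, species = sp,
      sex = sample(c("M", "F"), length(ids), replace = TRUE),
      age = round(runif(length(ids), age_range[[sp]][1], age_range[[sp]][2]), 1),
      condition = condition, postmortem_delay = pm_delay
    )
  }
  inds <- bind_rows(
    purrr::map(species, function(sp) {
      make_ind(sp, sprintf("%s_%02d", sp, seq_len(cfg$n_individuals)),
               "standard", 0.2)
    }),
    make_ind("macaque",
             sprintf("macaque_x%02d", seq_len(cfg$n_extra_controls)),
             "standard", 0.2),
    make_ind("macaque",
             sprintf("macaque_pm%02d", seq_len(cfg$n_postmortem)),
             "standard",
             rep_len(cfg$pm_delay_hours, cfg$n_postmortem)),
    make_ind("macaque",
             sprintf("macaque_c1_%02d", seq_len(cfg$n_condition[["condition1"]])),
             "condition1", 0.2),
    make_ind("macaque",
             sprintf("macaque_c2_%02d", seq_len(cfg$n_condition[["condition2"]])),
             "condition2", 0.2)
  )
  # condition animals in the study were male
  inds$sex[inds$condition != "standard"] <- "M"

  samples <- tidyr::crossing(inds, tissue = tissues) |>
    mutate(
      sample_id = paste(.data$individual_id, .data$tissue, sep = "."),
      rin = round(runif(n(), 5, 9.5), 1),
      is_pooled = FALSE
    )
  if (cfg$n_pooled_per_tissue > 0) {
    pooled <- tidyr::crossing(
      tissue = tissues, rep = seq_len(cfg$n_pooled_per_tissue)
    ) |>
      mutate(
        sample_id = sprintf("pooled_%s_%02d", .data$tissue, .data$rep),
        individual_id = NA_character_, species = "mixed", sex = NA_character_,
        age = NA_real_, condition = "standard", postmortem_delay = 0,
        rin = NA_real_, is_pooled = TRUE
      ) |>
      select(-"rep")
    samples <- bind_rows(samples, pooled)
  }
  samples <- samples |>
    mutate(run_order = seq_len(n())) |>
    select("sample_id", "species", "tissue", "individual_id", "sex", "age",
           "rin", "condition", "postmortem_delay", "is_pooled", "run_order")
  samples
}

plant_lineage_effects <- function(cfg, phylo, peak_ids, tissues) {
  if (cfg$delta <= 0 || cfg$effect_rate_per_my <= 0) {
    return(tibble(peak_id = character(0), tissue = character(0),
                  lineage = character(0), direction = character(0),
                  delta = numeric(0)))
  }
  out <- list()
  for (lin in names(phylo$lineage_lengths)) {
    for (t in tissues) {
      f <- cfg$effect_rate_per_my * phylo$lineage_lengths[[lin]] *
        accel_factor(cfg$accel, lin, t)
      if (f > 1) {
        warn(sprintf("planted fraction for %s/%s clipped from %.2f to 1",
                     lin, t, f))
        f <- 1
      }
      if (f <= 0) next
      hit <- runif(length(peak_ids)) < f
      if (!any(hit)) next
      out[[paste(lin, t)]] <- tibble(
        peak_id = peak_ids[hit], tissue = t, lineage = lin,
        direction = sample(c("up", "down"), sum(hit), replace = TRUE),
        delta = cfg$delta
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(peak_id = character(0), tissue = character(0),
                  lineage = character(0), direction = character(0),
                  delta = numeric(0)))
  }
  bind_rows(out) |> arrange(.data$peak_id, .data$tissue, .data$lineage)
}

plant_condition_effects <- function(cfg, peak_ids) {
  out <- list()
  for (cond in names(cfg$cond_effect_fraction)) {
    f <- cfg$cond_effect_fraction[[cond]]
    if (f <= 0 || cfg$cond_delta <= 0) next
    ids <- sort(sample(peak_ids, round(f * length(peak_ids))))
    if (length(ids) == 0) next
    out[[cond]] <- tibble(
      condition = cond, peak_id = ids,
      direction = sample(c("up", "down"), length(ids), replace = TRUE),
      human_concordant = runif(length(ids)) < cfg$cond_human_concordant
    )
  }
  if (length(out) == 0) {
    return(tibble(condition = character(0), peak_id = character(0),
                  direction = character(0), human_concordant = logical(0)))
  }
  bind_rows(out)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n",
      "  planted lineage effects: ", nrow(x$peak_effects), "\n",
      "  postmortem peaks:        ", length(x$pm_peaks), "\n",
      "  condition peaks:         ", nrow(x$condition_peaks), "\n", sep = "")
  invisible(x)
}
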