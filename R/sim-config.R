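#' Configuration for the synthetic metabolome generator
#'
#' Captures the study design being emulated: four species (human,
#' chimpanzee, macaque, mouse) sampled in five tissues (PFC, V1, CBC,
#' kidney, muscle) with 14 individuals each; additionally 3 extra
#' standard-condition macaques (17 controls in total), 2 macaques dissected
#' with 4-6 h postmortem delay, and 6 + 6 macaques kept under environment
#' conditions 1 and 2. Pooled QC samples are emitted for the LC datasets.
#'
#' Lineage-specific concentration shifts are planted per (peak, tissue,
#' lineage) with probability `min(1, effect_rate_per_my * branch_length *
#' accel)`, so the expected planted fraction scales with branch length;
#' `accel` injects tissue-specific accelerations (the defaults accelerate
#' the human lineage 4-fold in PFC and 8-fold in muscle).
#'
#' @param n_individuals individuals per species (default 14).
#' @param tissues tissue names (default the five of the design).
#' @param n_peaks number of peaks (default 10615).
#' @param dataset_fractions named fractions of peaks per acquisition dataset
#'   (`posLC`, `negLC`, `GC`); defaults approximate 4458/2956/3201.
#' @param baseline_log2_mean,baseline_log2_sd per-peak baseline log2
#'   abundance (AU) mean and sd.
#' @param tissue_sd sd of per-(peak, tissue) baseline offsets (log2); this
#'   is what makes most peaks differ between tissues.
#' @param effect_rate_per_my planted-effect probability per million years of
#'   branch length (fraction/MY). The default 0.003 reproduces the observed
#'   scale of between-species difference counts: with it, ~50% of peaks
#'   differ between human and macaque and ~37% between chimpanzee and
#'   macaque in at least one of five tissues (the study reports 46% and
#'   35%).
#' @param accel named list: lineage -> named numeric of per-tissue
#'   acceleration multipliers (missing entries default to 1; 0 disables).
#' @param delta planted effect size (log2 units), split evenly between up
#'   and down shifts.
#' @param noise_sd i.i.d. per-sample noise sd (log2 units), > 0.
#' @param detection_limit intensities below this AU value are recorded as 0.
#' @param n_pooled_per_tissue pooled QC samples per tissue (LC only).
#' @param pooled_noise_sd log2 noise added to pooled means.
#' @param n_extra_controls additional standard-condition macaques.
#' @param n_postmortem postmortem-delayed macaques (delay drawn from
#'   `pm_delay_hours`).
#' @param pm_delay_hours delays (h) assigned to the postmortem animals.
#' @param pm_effect_fraction fraction of peaks shifted in postmortem
#'   samples; `pm_delta` the shift size (log2, sign random).
#' @param pm_delta postmortem shift size (log2 units).
#' @param n_condition named counts of condition-1/2 macaques.
#' @param cond_effect_fraction named fractions of peaks shifted per
#'   condition; `cond_delta` the size.
#' @param cond_delta condition shift size (log2 units).
#' @param cond_human_concordant probability that a planted condition peak
#'   also receives a same-direction human shift (environment effects that
#'   mimic the human state).
#' @param seed integer RNG seed; identical configs give identical output.
#'
#' @return A `sim_config` object (validated named list).
#' @export
sim_config <- function(n_individuals = 14,
                       tissues = c("PFC", "V1", "CBC", "kidney", "muscle"),
                       n_peaks = 10615,
                       dataset_fractions = c(posLC = 0.42, negLC = 0.28,
                                             GC = 0.30),
                       baseline_log2_mean = 12,
                       baseline_log2_sd = 1.5,
                       tissue_sd = 1,
                       effect_rate_per_my = 0.003,
                       accel = list(human = c(PFC = 4, muscle = 8)),
                       delta = 1,
                       noise_sd = 0.7,
                       detection_limit = 32,
                       n_pooled_per_tissue = 3,
                       pooled_noise_sd = 0.1,
                       n_extra_controls = 3,
                       n_postmortem = 2,
                       pm_delay_hours = c(4, 6),
                       pm_effect_fraction = 0.05,
                       pm_delta = 1,
                       n_condition = c(condition1 = 6, condition2 = 6),
                       cond_effect_fraction = c(condition1 = 0.0035,
                                                condition2 = 0.0073),
                       cond_delta = 1,
                       cond_human_concordant = 0.5,
                       seed = 1L) {
  if (n_individuals < 3) abort("`n_individuals` must be at least 3")
  if (noise_sd <= 0) abort("`noise_sd` must be positive")
  fracs <- c(pm_effect_fraction, cond_effect_fraction, cond_human_concordant)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (abs(sum(dataset_fractions) - 1) > 1e-8) {
    abort("`dataset_fractions` must sum to 1")
  }
  if (delta < 0 || effect_rate_per_my < 0) {
    abort("`delta` and `effect_rate_per_my` must be non-negative")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals), tissues = tissues,
      n_peaks = as.integer(n_peaks), dataset_fractions = dataset_fractions,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd, tissue_sd = tissue_sd,
      effect_rate_per_my = effect_rate_per_my, accel = accel, delta = delta,
      noise_sd = noise_sd, detection_limit = detection_limit,
      n_pooled_per_tissue = as.integer(n_pooled_per_tissue),
      pooled_noise_sd = pooled_noise_sd,
      n_extra_controls = as.integer(n_extra_controls),
      n_postmortem = as.integer(n_postmortem),
      pm_delay_hours = pm_delay_hours,
      pm_effect_fraction = pm_effect_fraction, pm_delta = pm_delta,
      n_condition = n_condition,
      cond_effect_fraction = cond_effect_fraction, cond_delta = cond_delta,
      cond_human_concordant = cond_human_concordant,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Acceleration multiplier for one lineage/tissue, defaulting to 1.
accel_factor <- function(accel, lineage, tissue) {
  a <- accel[[lineage]]
  if (is.null(a)) return(1)
  if (is.null(names(a))) return(unname(a[1]))
  if (tissue %in% names(a)) unname(a[[tissue]]) else 1
}
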