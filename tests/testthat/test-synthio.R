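test_that("phylogeny constructor validates and stores branch lengths", {
  ph <- make_phylogeny()
  expect_equal(ph$lineage_lengths[["human"]], 6.5)
  expect_equal(ph$lineage_lengths[["human"]], ph$lineage_lengths[["chimp"]])
  expect_equal(ph$lineage_lengths[["mouse_anc"]], 101)
  ph2 <- make_phylogeny(mouse_my = 130)
  expect_equal(ph2$lineage_lengths[["mouse_anc"]], 130)
  expect_error(make_phylogeny(human_my = 0), "positive")
  expect_error(make_phylogeny(chimp_my = -1), "positive")
})

test_that("identical config and seed give identical output", {
  cfg <- quiet_sim_config(n_peaks = 80, n_individuals = 4, seed = 42)
  a <- simulate_metabolome(cfg)
  b <- simulate_metabolome(cfg)
  expect_identical(a$mset$intensities, b$mset$intensities)
  expect_identical(a$mset$samples, b$mset$samples)
  expect_identical(a$truth$peak_effects, b$truth$peak_effects)
})

test_that("zero effect size plants nothing and species have equal means", {
  cfg <- quiet_sim_config(n_peaks = 150, n_individuals = 8, delta = 0,
                          seed = 7)
  sim <- simulate_metabolome(cfg)
  expect_equal(nrow(sim$truth$peak_effects), 0)
  L <- log2(sim$mset$intensities)
  sp <- sim$mset$samples$species
  mh <- mean(L[, sp == "human"])
  mc <- mean(L[, sp == "chimpanzee"])
  # equal expectations: difference is pure noise, tiny per-cell
  expect_lt(abs(mh - mc), 0.05)
})

test_that("lowering the detection limit never decreases nonzero entries", {
  counts <- sapply(c(4096, 1024, 256, 0), function(dl) {
    cfg <- sim_config(n_peaks = 100, n_individuals = 4, detection_limit = dl,
                      seed = 9)
    sum(simulate_metabolome(cfg)$mset$intensities > 0)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("planted fractions match configured rates over many seeds", {
  rate <- 0.004
  ph <- make_phylogeny()
  n_peaks <- 150
  n_seeds <- 20
  hits <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- quiet_sim_config(n_peaks = n_peaks, n_individuals = 3,
                            effect_rate_per_my = rate, accel = list(),
                            seed = 500 + s)
    te <- simulate_metabolome(cfg)$truth$peak_effects
    hits <- hits + sum(te$lineage == "chimp" & te$tissue == "muscle")
  }
  p_expect <- rate * ph$lineage_lengths[["chimp"]]
  n_trials <- n_peaks * n_seeds
  se <- sqrt(p_expect * (1 - p_expect) / n_trials)
  expect_lt(abs(hits / n_trials - p_expect), 3 * se + 1e-9)
})

test_that("human muscle acceleration yields the planted 8:1 count ratio", {
  ratio_num <- 0
  ratio_den <- 0
  for (s in seq_len(20)) {
    cfg <- quiet_sim_config(
      n_peaks = 200, n_individuals = 3, effect_rate_per_my = 0.004,
      accel = list(human = c(muscle = 8)), seed = 900 + s
    )
    te <- simulate_metabolome(cfg)$truth$peak_effects
    ratio_num <- ratio_num + sum(te$lineage == "human" & te$tissue == "muscle")
    ratio_den <- ratio_den + sum(te$lineage == "chimp" & te$tissue == "muscle")
  }
  # binomial error band on the count ratio via the planted probabilities
  p_h <- 0.004 * 6.5 * 8
  p_c <- 0.004 * 6.5
  n <- 200 * 20
  se_ratio <- (ratio_num / ratio_den) *
    sqrt(p_h * (1 - p_h) / (n * p_h^2) + p_c * (1 - p_c) / (n * p_c^2))
  expect_lt(abs(ratio_num / ratio_den - 8), 3 * se_ratio)
})

test_that("acceleration pushing the fraction above 1 warns and clips", {
  acc <- null_accel()
  acc$human["muscle"] <- 50
  cfg <- quiet_sim_config(n_peaks = 40, n_individuals = 3,
                          effect_rate_per_my = 0.05,
                          accel = acc, seed = 3)
  expect_warning(sim <- simulate_metabolome(cfg), "clipped")
  te <- sim$truth$peak_effects
  expect_equal(sum(te$lineage == "human" & te$tissue == "muscle"), 40)
})

test_that("study-design sample sheet has the expected structure", {
  cfg <- sim_config(n_peaks = 10, seed = 1)
  sim <- suppressWarnings(simulate_metabolome(cfg))
  smp <- sim$mset$samples
  mac <- smp[smp$species == "macaque" & !smp$is_pooled, ]
  # 17 standard controls, 2 delayed, 6 + 6 condition animals per tissue
  per_tissue <- mac[mac$tissue == "muscle", ]
  expect_equal(sum(per_tissue$condition == "standard" &
                     per_tissue$postmortem_delay < 2), 17)
  expect_equal(sum(per_tissue$postmortem_delay >= 2), 2)
  expect_equal(sum(per_tissue$condition == "condition1"), 6)
  expect_equal(sum(per_tissue$condition == "condition2"), 6)
  expect_true(all(smp$individual_id[smp$is_pooled] %in% NA))
  # pooled columns are empty for GC peaks (no pooled QC in the GC run)
  gc <- sim$mset$intensities[sim$mset$peaks$dataset == "GC",
                             smp$is_pooled, drop = FALSE]
  expect_true(all(gc == 0))
})

test_that("simulated annotation matches the requested fraction and seeds", {
  ann1 <- simulate_annotation(400, n_metabolites = 60, n_pathways = 10,
                              annotated_fraction = 0.145, seed = 5)
  ann2 <- simulate_annotation(400, n_metabolites = 60, n_pathways = 10,
                              annotated_fraction = 0.145, seed = 5)
  expect_identical(ann1$pathways$metabolite_sets,
                   ann2$pathways$metabolite_sets)
  expect_equal(nrow(ann1$annotation), round(0.145 * 400))
  ann0 <- simulate_annotation(100, n_metabolites = 10, n_pathways = 3,
                              annotated_fraction = 0, seed = 5)
  expect_equal(nrow(ann0$annotation), 0)
  expect_error(simulate_annotation(10, n_metabolites = 60, seed = 1),
               "cannot exceed")
  expect_error(
    simulate_annotation(100, n_metabolites = 50, n_pathways = 3,
                        pathway_size_range = c(1, 3), seed = 1),
    "at least 2"
  )
})

test_that("expression concordance plants the expected number of enzymes", {
  # one pathway, 200 enzymes all linked to one planted metabolite
  enzymes <- sprintf("ENZ%03d", 1:200)
  db <- pathway_db(
    metabolite_sets = list(P1 = c("m1", "m2")),
    enzyme_sets = list(P1 = enzymes),
    links = tibble::tibble(enzyme_id = enzymes, metabolite_id = "m1")
  )
  truth <- structure(list(
    peak_effects = tibble::tibble(peak_id = "pk1", tissue = "muscle",
                                  lineage = "human", direction = "up",
                                  delta = 1)
  ), class = "synthetic_truth")
  ann <- tibble::tibble(peak_id = "pk1", metabolite_id = "m1")
  n_conc <- sapply(c(0, 0.5, 1), function(cc) {
    res <- simulate_expression(db, truth, ann, concordance = cc,
                               background_rate = 0, seed = 31)
    sum(res$specific_genes$source == "concordant")
  })
  expect_equal(n_conc[1], 0)
  expect_equal(n_conc[3], 200)
  se <- sqrt(200 * 0.25)
  expect_lt(abs(n_conc[2] - 100), 3 * se)
})
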