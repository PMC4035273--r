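toy_db <- function() {
  pathway_db(list(
    P1 = sprintf("m%02d", 1:5),
    P2 = sprintf("m%02d", 4:9),
    P3 = sprintf("m%02d", 8:10)
  ))
}

test_that("hypergeometric enrichment matches hand-derived values", {
  db <- pathway_db(list(P = sprintf("m%02d", 1:5)))
  bg <- sprintf("m%02d", 1:10)
  # N=10, K=5, n=4, k=4: C(5,4)C(5,0)/C(10,4) = 5/210
  res <- hypergeom_enrichment(sprintf("m%02d", 1:4), bg, db)
  expect_equal(res$p_hyper, 5 / 210, tolerance = 1e-12)
  expect_equal(res[, c("k", "K", "n", "N")],
               tibble::tibble(k = 4L, K = 5L, n = 4L, N = 10L),
               ignore_attr = TRUE)
  # zero overlap: upper tail at zero is 1
  res0 <- hypergeom_enrichment(sprintf("m%02d", 6:9), bg,
                               pathway_db(list(P = c("m10"))))
  expect_equal(res0$p_hyper, 1)
  # the whole background as test set forces k = K, p = 1
  resf <- hypergeom_enrichment(bg, bg, db)
  expect_equal(resf$p_hyper, 1)
  expect_error(hypergeom_enrichment(character(0), bg, db), "empty")
  expect_error(hypergeom_enrichment("zzz", bg, db), "subset")
})

test_that("hypergeometric p equals exhaustive subset enumeration (N <= 12)", {
  set.seed(91)
  for (rep in 1:8) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    bg <- sprintf("m%02d", seq_len(N))
    db <- pathway_db(list(P = bg[seq_len(K)]))
    test_set <- sample(bg, n)
    k_obs <- sum(test_set %in% bg[seq_len(K)])
    res <- hypergeom_enrichment(test_set, bg, db)
    expect_equal(res$p_hyper, ref_hypergeom_enum(N, K, n, k_obs),
                 tolerance = 1e-12)
  }
})

test_that("permutation enrichment has the documented extremes and converges", {
  bg <- sprintf("m%02d", 1:6)
  db <- pathway_db(list(P = bg[1:3]))
  # observed overlap 0 -> p = 1
  p0 <- permutation_enrichment(bg[4:5], bg, db, n_perm = 200, seed = 1)
  expect_equal(p0$perm_p, 1)
  # tiny universe: permutation p within 3 MC SDs of the exact tail
  test_set <- bg[1:2]
  res <- permutation_enrichment(test_set, bg, db, n_perm = 2000, seed = 2)
  exact <- ref_hypergeom_enum(6, 3, 2, 2)
  se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(res$perm_p - exact), 3 * se + 1 / 2000)
  expect_error(permutation_enrichment(bg, bg[1:3], db, 100, 1), "smaller")
})

test_that("permutation and hypergeometric p agree under matched sampling", {
  set.seed(92)
  bg <- sprintf("m%03d", 1:60)
  db <- pathway_db(list(P = bg[1:15]))
  test_set <- sample(bg, 12)
  hy <- hypergeom_enrichment(test_set, bg, db)
  pe <- permutation_enrichment(test_set, bg, db, n_perm = 4000, seed = 3)
  se <- sqrt(hy$p_hyper * (1 - hy$p_hyper) / 4000)
  expect_lt(abs(pe$perm_p - hy$p_hyper), 3 * se + 1 / 4000)
})

test_that("uniform random test sets are called enriched at most at the nominal rate", {
  set.seed(93)
  ann <- simulate_annotation(600, n_metabolites = 200, n_pathways = 25,
                             pathway_size_range = c(5, 25), seed = 7)
  bg <- sprintf("met%04d", 1:200)
  calls <- 0
  total <- 0
  for (r in 1:40) {
    res <- enrich_pathways(sample(bg, 20), bg, ann$pathways, n_perm = 150,
                           seed = 400 + r)
    calls <- calls + sum(res$enriched)
    total <- total + nrow(res)
  }
  expect_lte(calls / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

env_fixture <- function(seed = 94) {
  set.seed(seed)
  ctrl <- make_samples(list(macaque = 8, human = 6), "muscle")
  cond <- make_samples(list(macaque = 5), "muscle") |>
    dplyr::mutate(sample_id = paste0("c1_", sample_id),
                  individual_id = paste0("c1_", individual_id),
                  condition = "condition1")
  samples <- dplyr::bind_rows(ctrl, cond)
  samples$run_order <- seq_len(nrow(samples))
  X <- matrix(rnorm(30 * nrow(samples), 10, 0.4), 30)
  is_cond <- samples$condition == "condition1"
  is_human <- samples$species == "human"
  X[1, is_cond] <- X[1, is_cond] + 2   # condition peak, human concordant
  X[1, is_human] <- X[1, is_human] + 2
  X[2, is_cond] <- X[2, is_cond] + 2   # condition peak, human opposite
  X[2, is_human] <- X[2, is_human] - 2
  make_mset(X, samples, scale = "log2")
}

test_that("environment peaks require agreement with the human direction", {
  mset <- env_fixture()
  res <- environment_effect_peaks(mset, "condition1", cutoff = 0.01,
                                  n_perm = 400, seed = 5)
  expect_true("pk001" %in% res$peak_id)
  expect_false("pk002" %in% res$peak_id)
  expect_equal(res$direction[res$peak_id == "pk001"], "up")
  expect_error(environment_effect_peaks(mset, "condition2"), "condition2")
})

test_that("null environment comparisons stay near the nominal rate", {
  set.seed(95)
  mset <- env_fixture()
  mset$intensities <- matrix(rnorm(200 * ncol(mset$intensities), 10, 1), 200,
                             dimnames = NULL)
  rownames(mset$intensities) <- sprintf("pk%03d", 1:200)
  colnames(mset$intensities) <- mset$samples$sample_id
  mset$peaks <- tibble::tibble(peak_id = rownames(mset$intensities),
                               dataset = "posLC", mz = 200, mass = NA, rt = 2)
  res <- environment_effect_peaks(mset, "condition1", cutoff = 0.01,
                                  n_perm = 200, seed = 6)
  # dual threshold plus direction agreement: conservative under the null
  expect_lte(nrow(res) / 200, 0.01 + 3 * sqrt(0.01 * 0.99 / 200))
})

test_that("overlap significance has its documented trivial cases", {
  db <- toy_db()
  ann <- tibble::tibble(peak_id = c("pk1", "pk2"),
                        metabolite_id = c("m01", "m08"))
  human <- tibble::tibble(peak_id = c("pk1", "pk2"), tissue = "muscle",
                          lineage = "human", direction = "up")
  # all pathways enriched: the null equals the observed count, p = 1
  res_all <- overlap_significance(names(db$metabolite_sets), human, ann, db,
                                  n_perm = 100, seed = 1)
  expect_equal(res_all$count, 2L)
  expect_equal(res_all$perm_p, 1)
  # no human-specific peaks: count 0, p = 1
  none <- human[0, ]
  res0 <- overlap_significance("P1", none, ann, db, n_perm = 100, seed = 1)
  expect_equal(res0$count, 0L)
  expect_equal(res0$perm_p, 1)
  expect_error(overlap_significance(character(0), human, ann, db), "empty")
})

test_that("human peaks concentrated in the enriched pathways give a small p", {
  set.seed(96)
  mets <- sprintf("m%03d", 1:60)
  # the null resamples whole pathways, so its resolution is 1 / #pathways;
  # 40 pathways put the smallest achievable p well below 0.05
  sets <- c(
    list(env = mets[1:10]),
    setNames(lapply(1:39, function(i) sample(mets[11:60], 8)),
             sprintf("bg%02d", 1:39))
  )
  db <- pathway_db(sets)
  ann <- tibble::tibble(peak_id = sprintf("pk%02d", 1:10),
                        metabolite_id = mets[1:10])
  human <- tibble::tibble(peak_id = sprintf("pk%02d", 1:10),
                          tissue = "muscle", lineage = "human",
                          direction = "up")
  res <- overlap_significance("env", human, ann, db, n_perm = 400, seed = 2)
  expect_equal(res$count, 10L)
  expect_lt(res$perm_p, 0.05)
})
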