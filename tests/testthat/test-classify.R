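test_that("composite tissue categories pool the cortical regions", {
  samples <- make_samples(list(human = 14),
                          tissues = c("PFC", "V1", "CBC", "kidney"))
  cats <- build_composite_tissues(samples)
  expect_equal(sum(cats$tissue_category == "cortex"), 28)
  expect_equal(sum(cats$tissue_category == "brain"), 42)
  expect_equal(sum(cats$tissue_category == "kidney"), 14)
  # without CBC samples the brain category equals cortex
  no_cbc <- make_samples(list(human = 5), tissues = c("PFC", "V1"))
  cats2 <- build_composite_tissues(no_cbc)
  expect_setequal(cats2$sample_id[cats2$tissue_category == "brain"],
                  cats2$sample_id[cats2$tissue_category == "cortex"])
})

classify_fixture <- function(seed = 61, delta_human_muscle = 2) {
  set.seed(seed)
  samples <- make_samples(list(human = 6, chimpanzee = 6, macaque = 6),
                          tissues = c("muscle", "kidney"))
  X <- matrix(rnorm(40 * nrow(samples), 10, 0.5), 40)
  hit <- samples$species == "human" & samples$tissue == "muscle"
  X[1, hit] <- X[1, hit] + delta_human_muscle
  make_mset(X, samples, scale = "log2")
}

test_that("a planted human-up muscle peak is assigned (human, muscle, up)", {
  mset <- classify_fixture()
  res <- classify_species_specific(
    mset, gate_primate = mset$peaks$peak_id, n_perm = 200, seed = 2,
    lineages = c("human", "chimp", "macaque_anc")
  )
  a <- tidy(res)
  hit <- a[a$peak_id == "pk001", ]
  expect_true(any(hit$tissue == "muscle" & hit$lineage == "human" &
                    hit$direction == "up"))
  # the planted peak is not attributed to the sister lineages
  expect_false(any(hit$tissue == "muscle" & hit$lineage != "human"))
})

test_that("elevation shared by human and chimp is assigned to the macaque lineage", {
  set.seed(62)
  samples <- make_samples(list(human = 6, chimpanzee = 6, macaque = 6),
                          "muscle")
  X <- matrix(rnorm(10 * nrow(samples), 10, 0.4), 10)
  both <- samples$species %in% c("human", "chimpanzee")
  X[1, both] <- X[1, both] + 2
  mset <- make_mset(X, samples, scale = "log2")
  res <- classify_species_specific(
    mset, gate_primate = mset$peaks$peak_id, n_perm = 200, seed = 3,
    lineages = c("human", "chimp", "macaque_anc")
  )
  a <- tidy(res)[tidy(res)$peak_id == "pk001", ]
  expect_true(any(a$lineage == "macaque_anc" & a$direction == "down"))
  expect_false(any(a$lineage %in% c("human", "chimp")))
})

test_that("null data yield a discovery rate at or below the nominal level", {
  set.seed(63)
  samples <- make_samples(list(human = 8, chimpanzee = 8, macaque = 8),
                          c("muscle", "kidney"))
  X <- matrix(rnorm(300 * nrow(samples), 10, 1), 300)
  mset <- make_mset(X, samples, scale = "log2")
  res <- classify_species_specific(
    mset, gate_primate = mset$peaks$peak_id, cutoff = 0.01, fdr = 0.05,
    n_perm = 200, seed = 4, lineages = c("human", "chimp", "macaque_anc")
  )
  n_tests <- sum(res$families$n_tested)
  rate <- nrow(tidy(res)) / n_tests
  # q-gated null calls are rare: bound by nominal + 3 binomial SE
  expect_lte(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / n_tests))
})

test_that("multi-tissue exclusion follows the three tissue groups", {
  mk <- function(peak, tissue, lineage, dir) {
    tibble::tibble(peak_id = peak, tissue = tissue, lineage = lineage,
                   direction = dir)
  }
  assign <- dplyr::bind_rows(
    mk("p1", "PFC", "human", "up"), mk("p1", "V1", "human", "up"),
    mk("p2", "PFC", "human", "up"), mk("p2", "V1", "human", "down"),
    mk("p3", "muscle", "human", "up"),
    mk("p4", "brain", "chimp", "down"), mk("p4", "kidney", "chimp", "down"),
    mk("p5", "cortex", "human", "up"), mk("p5", "CBC", "human", "up"),
    mk("p6", "cortex", "human", "up"), mk("p6", "CBC", "macaque_anc", "up")
  )
  out <- exclude_multitissue(assign)
  expect_false(any(out$peak_id == "p1"))          # same direction in PFC+V1
  expect_equal(sum(out$peak_id == "p2"), 2)       # opposite directions kept
  expect_true(any(out$peak_id == "p3"))           # single tissue kept
  expect_false(any(out$peak_id == "p4"))          # brain+kidney same dir
  expect_false(any(out$peak_id == "p5"))          # cortex+CBC same dir
  expect_equal(sum(out$peak_id == "p6"), 2)       # different lineages kept
})

test_that("exclusion matches a brute-force rule on random assignments", {
  brute <- function(tbl) {
    groups <- list(c("PFC", "V1"), c("cortex", "CBC"),
                   c("brain", "kidney", "muscle"))
    drop <- rep(FALSE, nrow(tbl))
    for (i in seq_len(nrow(tbl))) {
      for (g in groups) {
        if (!tbl$tissue[i] %in% g) next
        partner <- tbl$tissue %in% setdiff(g, tbl$tissue[i]) &
          tbl$peak_id == tbl$peak_id[i] &
          tbl$lineage == tbl$lineage[i] &
          tbl$direction == tbl$direction[i]
        if (any(partner)) drop[i] <- TRUE
      }
    }
    tbl[!drop, ]
  }
  set.seed(64)
  for (rep in 1:10) {
    tbl <- tibble::tibble(
      peak_id = sample(sprintf("p%02d", 1:12), 40, replace = TRUE),
      tissue = sample(c("PFC", "V1", "CBC", "kidney", "muscle", "cortex",
                        "brain"), 40, replace = TRUE),
      lineage = sample(c("human", "chimp"), 40, replace = TRUE),
      direction = sample(c("up", "down"), 40, replace = TRUE)
    ) |> dplyr::distinct()
    expect_equal(exclude_multitissue(tbl), brute(tbl))
  }
})

test_that("shuffled species labels keep the false-call rate near nominal", {
  set.seed(65)
  rates <- numeric(3)
  for (s in 1:3) {
    samples <- make_samples(list(human = 6, chimpanzee = 6, macaque = 6),
                            "muscle")
    samples$species <- sample(samples$species)
    X <- matrix(rnorm(150 * nrow(samples), 10, 1), 150)
    mset <- make_mset(X, samples, scale = "log2")
    res <- classify_species_specific(
      mset, gate_primate = mset$peaks$peak_id, n_perm = 150,
      seed = 70 + s, lineages = c("human", "chimp", "macaque_anc")
    )
    rates[s] <- nrow(tidy(res)) / sum(res$families$n_tested)
  }
  n <- 150 * 3 * 3
  expect_lte(mean(rates), 0.01 + 3 * sqrt(0.01 * 0.99 / n))
})
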