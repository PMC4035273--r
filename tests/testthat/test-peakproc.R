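test_that("LC filter retains exactly the clean peaks and attributes removals", {
  res <- filter_lcms_peaks(lc_fixture())
  expect_equal(nrow(res$mset$intensities), 6)
  expect_equal(res$report$removed,
               c(1, 1, 1, 1)) # one peak per criterion, listed order
  expect_equal(attr(res$report, "retained"), 6)
  # first-failing attribution: retained + removals = input
  expect_equal(attr(res$report, "retained") + sum(res$report$removed), 10)
})

test_that("LC filter keeps a peak at 12,000 AU in 8 of 14 samples", {
  samples <- make_samples(list(human = 14), "muscle", n_pooled = 3)
  x <- rep(0, nrow(samples))
  x[samples$is_pooled] <- 5000
  x[which(!samples$is_pooled)[1:8]] <- 12000
  mset <- make_mset(matrix(x, 1), samples, dataset = "posLC", rt = 1.2)
  res <- filter_lcms_peaks(mset)
  expect_equal(nrow(res$mset$intensities), 1)
})

test_that("LC filtering is idempotent and never alters retained data", {
  first <- filter_lcms_peaks(lc_fixture())
  second <- filter_lcms_peaks(first$mset)
  expect_identical(first$mset$intensities, second$mset$intensities)
  expect_identical(first$mset$peaks$peak_id, second$mset$peaks$peak_id)
  # retained peaks keep their input order and values
  orig <- lc_fixture()
  kept <- match(first$mset$peaks$peak_id, orig$peaks$peak_id)
  expect_true(all(diff(kept) > 0))
  expect_identical(first$mset$intensities,
                   orig$intensities[kept, , drop = FALSE])
})

test_that("LC filter without pooled samples names criterion 2", {
  samples <- make_samples(list(human = 4), "muscle", n_pooled = 0)
  mset <- make_mset(matrix(20000, 2, nrow(samples)), samples,
                    dataset = "posLC")
  expect_error(filter_lcms_peaks(mset), "criterion 2")
})

test_that("GC filter applies its five criteria with correct attribution", {
  is_tbl <- tibble::tibble(mass = c(150, 320), rt = c(4.5, 9.0))
  res <- filter_gcms_peaks(gc_fixture(), is_tbl)
  kept <- res$mset$peaks$peak_id
  # pk003 background, pk009 rt spread, pk004 shares IS mass at 1.0 min,
  # pk005 below level, pk007/pk008 overlapping (same mass, dRT 0.4);
  # overlap pair sits at rt 6.8/7.2, clear of both internal standards
  expect_setequal(kept, c("pk001", "pk002", "pk006"))
  rep <- res$report
  expect_equal(rep$removed[rep$criterion == "background"], 1)
  expect_equal(rep$removed[rep$criterion == "rt_consistency"], 1)
  expect_equal(rep$removed[rep$criterion == "internal_standard"], 1)
  expect_equal(rep$removed[rep$criterion == "species_tissue_level"], 1)
  expect_equal(rep$removed[rep$criterion == "overlapping"], 2)
  # boundary peak at 3,000 AU in exactly 50% of the cell is retained
  expect_true("pk006" %in% kept)
  expect_error(filter_gcms_peaks(gc_fixture(), NULL), "internal_standards")
})

test_that("a peak not sharing the IS mass only needs 0.75 min separation", {
  samples <- make_samples(list(macaque = 4), "kidney")
  mset <- make_mset(matrix(5000, 2, nrow(samples)), samples, dataset = "GC",
                    rt = c(5.5, 5.3),
                    peaks_extra = list(mass = c(210, 211), rt_spread = 0.1,
                                       distinct_background = TRUE))
  is_tbl <- tibble::tibble(mass = 150, rt = 4.5)
  res <- filter_gcms_peaks(mset, is_tbl)
  # |5.5 - 4.5| = 1.0 > 0.75 passes; |5.3 - 4.5| = 0.8 > 0.75 passes
  expect_equal(nrow(res$mset$intensities), 2)
})

test_that("PCA outlier detection flags a shifted sample and needs 4 samples", {
  set.seed(11)
  samples <- make_samples(list(human = 10), "muscle")
  X <- 2^matrix(rnorm(200 * 10, 12, 1), 200, 10)
  X[, 4] <- X[, 4] * 2^10 # one sample shifted by 10 log2 units on all peaks
  mset <- make_mset(X, samples)
  expect_equal(detect_outlier_samples(mset), samples$sample_id[4])
  # homogeneous data: nothing flagged across seeds
  for (s in 1:5) {
    set.seed(100 + s)
    Xh <- 2^matrix(rnorm(100 * 8, 12, 1), 100, 8)
    mh <- make_mset(Xh, make_samples(list(human = 8), "muscle"))
    expect_length(detect_outlier_samples(mh), 0)
  }
  small <- make_mset(2^matrix(rnorm(30), 10, 3),
                     make_samples(list(human = 3), "muscle"))
  expect_error(detect_outlier_samples(small), "at least 4")
})

test_that("quantile normalization matches the rank-mean reference", {
  set.seed(21)
  samples <- make_samples(list(human = 3), "muscle")
  M <- matrix(2^rnorm(9, 10, 1), 3, 3) # no ties
  mset <- make_mset(M, samples)
  norm <- normalize_peaks(mset)
  expect_equal(unname(norm$intensities),
               unname(ref_quantile_normalize(log2(M))), tolerance = 1e-12)
})

test_that("a constant log2 offset between samples vanishes after normalization", {
  set.seed(22)
  samples <- make_samples(list(human = 2), "muscle")
  a <- 2^rnorm(50, 10, 1)
  M <- cbind(a, a * 4) # +2 log2 offset
  mset <- make_mset(M, samples)
  norm <- normalize_peaks(mset)
  expect_equal(sort(norm$intensities[, 1]), sort(norm$intensities[, 2]),
               tolerance = 1e-12)
  expect_equal(norm$intensities[, 1], norm$intensities[, 2],
               tolerance = 1e-12) # same ranks here, so identical vectors
})

test_that("normalization preserves within-sample rank order per tissue", {
  set.seed(23)
  samples <- make_samples(list(human = 4, mouse = 4),
                          tissues = c("muscle", "kidney"))
  M <- 2^matrix(rnorm(60 * nrow(samples), 11, 1.5), 60)
  norm <- normalize_peaks(make_mset(M, samples))
  for (j in seq_len(ncol(M))) {
    expect_equal(order(norm$intensities[, j]), order(M[, j]))
  }
})

test_that("single-sample tissue is log2 only, zeros propagate as NA", {
  samples <- make_samples(list(human = 1), "muscle")
  M <- matrix(c(8, 0, 32), 3, 1)
  mset <- make_mset(M, samples)
  expect_warning(norm <- normalize_peaks(mset), "single sample")
  expect_equal(norm$intensities[, 1], c(pk001 = 3, pk002 = NA, pk003 = 5))
})

test_that("postmortem flags equal a brute-force sort of mean differences", {
  set.seed(31)
  samples <- dplyr::bind_rows(
    make_samples(list(macaque = 6), "muscle"),
    dplyr::mutate(make_samples(list(macaque = 2), "muscle"),
                  sample_id = paste0("pm_", sample_id),
                  individual_id = paste0("pm_", individual_id),
                  postmortem_delay = 5)
  )
  samples$run_order <- seq_len(nrow(samples))
  X <- matrix(rnorm(40 * nrow(samples), 10, 0.5), 40)
  X[1, samples$postmortem_delay >= 2] <- X[1, samples$postmortem_delay >= 2] + 5
  X[2, samples$postmortem_delay >= 2] <- X[2, samples$postmortem_delay >= 2] - 5
  mset <- make_mset(2^X, samples)
  norm <- normalize_peaks(mset)
  flags <- flag_postmortem_peaks(norm, q = 0.05)
  # brute force: floor(0.05 * 40) = 2 per side of the sorted differences
  d <- rowMeans(norm$intensities[, samples$postmortem_delay >= 2]) -
    rowMeans(norm$intensities[, samples$postmortem_delay < 2])
  o <- order(d)
  expected <- rownames(norm$intensities)[c(o[1:2], o[39:40])]
  expect_setequal(flags$peak_id, expected)
  expect_true(all(c("pk001", "pk002") %in% flags$peak_id))
  # the median peak is never flagged
  expect_false(rownames(norm$intensities)[o[20]] %in% flags$peak_id)
})

test_that("postmortem flagging covers ~10% of peaks per tissue", {
  set.seed(32)
  samples <- dplyr::bind_rows(
    make_samples(list(macaque = 8), "kidney"),
    dplyr::mutate(make_samples(list(macaque = 2), "kidney"),
                  sample_id = paste0("pm_", sample_id),
                  individual_id = paste0("pm_", individual_id),
                  postmortem_delay = 5)
  )
  samples$run_order <- seq_len(nrow(samples))
  X <- 2^matrix(rnorm(200 * nrow(samples), 10, 0.5), 200)
  flags <- flag_postmortem_peaks(normalize_peaks(make_mset(X, samples)))
  expect_equal(nrow(flags), 2 * floor(0.05 * 200))
})
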