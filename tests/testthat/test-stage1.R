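test_that("relative methylation centers each site and preserves missingness", {
  vals <- matrix(c(
    1, 1, 0,
    1, 1, 1,
    NA, 0, 1
  ), nrow = 3, byrow = TRUE)
  mat <- mat_from_dense(vals)
  rel <- relative_methylation(mat)
  # x = 1 at a site with mean 2/3 -> 1/3
  expect_equal(rel$rel[rel$site == 1 & rel$cell == 1], 1 / 3)
  # identical cells at a site -> all zeros
  expect_equal(rel$rel[rel$site == 2], c(0, 0, 0))
  # missing entries stay missing
  expect_equal(nrow(rel), sum(!is.na(vals)))
  # fully observed sites have relative values summing to zero
  sums <- tapply(rel$rel, rel$site, sum)
  expect_equal(unname(sums[["1"]]), 0)
  expect_equal(unname(sums[["2"]]), 0)
})

test_that("box smoothing averages within the window, per cell", {
  # worked example: x* = {0.4, -0.2, 0.4} at positions {1000, 1500, 1900},
  # bandwidth 2000 -> window +/- 1000 covers all three at the middle site
  rel <- tibble::tibble(site = 1:3, cell = 1L, rel = c(0.4, -0.2, 0.4))
  sm <- smooth_cells(rel, pos = c(1000L, 1500L, 1900L), bandwidth_bp = 2000)
  expect_equal(sm$smooth[2], 0.2)
  # partial windows: with positions {0, 500, 1600} the first site's window
  # [-1000, 1000] misses the third site, and the third sees only itself
  rel2 <- tibble::tibble(site = 1:3, cell = 1L, rel = c(0.4, -0.2, 0.4))
  sm2 <- smooth_cells(rel2, pos = c(0L, 500L, 1600L), bandwidth_bp = 2000)
  expect_equal(sm2$smooth, c(0.1, 0.1, 0.4))
  # isolated site: smoothed value equals the raw value
  iso <- smooth_cells(
    tibble::tibble(site = 1:2, cell = 1L, rel = c(0.7, -0.1)),
    pos = c(100L, 99999L), bandwidth_bp = 2000
  )
  expect_equal(iso$smooth, c(0.7, -0.1))
  # constant input stays constant
  cst <- smooth_cells(
    tibble::tibble(site = 1:5, cell = 1L, rel = rep(0.3, 5)),
    pos = seq(100L, 900L, by = 200L), bandwidth_bp = 2000
  )
  expect_equal(cst$smooth, rep(0.3, 5))
})

test_that("bandwidth shrinking to zero recovers the raw relative values", {
  set.seed(3)
  rel <- tibble::tibble(
    site = 1:20, cell = rep(1:2, 10), rel = rnorm(20)
  )
  pos <- cumsum(sample(50:300, 20, replace = TRUE))
  sm <- smooth_cells(rel, pos, bandwidth_bp = 0)
  expect_equal(sm$smooth, rel$rel)
})

test_that("cross-cell variance follows the n - 1 formula and degenerates to NA", {
  summ <- tibble::tibble(site = 1:3, n = c(2L, 3L, 1L))
  sm <- tibble::tibble(
    site = c(1L, 1L, 2L, 2L, 2L, 3L),
    cell = c(1L, 2L, 1L, 2L, 3L, 1L),
    smooth = c(0.5, -0.5, 0, 0, 0, 0.9)
  )
  v <- cross_cell_variance(sm, summ)
  expect_equal(v[1], (0.25 + 0.25) / 1)
  expect_equal(v[2], 0)
  expect_true(is.na(v[3]))
})

test_that("null threshold is deterministic, monotone in alpha, and calibrated", {
  set.seed(11)
  sc <- simulate_scaffold(2000, 80, 0.5)
  mat <- simulate_hmm_chromosome(sc)
  mat <- filter_low_coverage_sites(mat)
  t1 <- null_variance_threshold(mat, default_em, n_sim_sites = 3000, seed = 5)
  t2 <- null_variance_threshold(mat, default_em, n_sim_sites = 3000, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_strict <- null_variance_threshold(
    mat, default_em,
    alpha = 0.01, n_sim_sites = 3000, seed = 5
  )
  t_loose <- null_variance_threshold(
    mat, default_em,
    alpha = 0.5, n_sim_sites = 3000, seed = 5
  )
  expect_gte(t_strict, as.numeric(t1))
  expect_lte(t_loose, as.numeric(t1))
  expect_error(
    null_variance_threshold(mat, default_em, alpha = 1.5),
    "alpha"
  )
  # self-calibration: under the null simulator's own variances, the
  # exceedance of the threshold is alpha by construction of the quantile
  v <- attr(t1, "null_variances")
  expect_lt(abs(mean(v > as.numeric(t1)) - 0.05), 0.01)
})

test_that("candidate regions are maximal above-threshold runs split at large gaps", {
  pos <- c(100L, 300L, 500L, 700L, 900L, 1100L, 1300L)
  v <- rep(1, 7)
  cr <- segment_candidate_regions(v, pos, threshold = 0.5)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$n_cpgs, 7L)
  expect_equal(cr$start_pos, 100L)
  expect_equal(cr$end_pos, 1300L)
  # all below threshold -> empty
  expect_equal(
    nrow(segment_candidate_regions(rep(0.1, 7), pos, threshold = 0.5)), 0L
  )
  # a 2500-bp gap splits 6 above-threshold sites into 3 + 3, both dropped
  pos2 <- c(100L, 200L, 300L, 2800L, 2900L, 3000L)
  cr2 <- segment_candidate_regions(rep(1, 6), pos2, threshold = 0.5)
  expect_equal(nrow(cr2), 0L)
  # but kept when the minimum length allows
  cr3 <- segment_candidate_regions(
    rep(1, 6), pos2,
    threshold = 0.5, min_cr_cpgs = 3
  )
  expect_equal(cr3$start_pos, c(100L, 2800L))
  # below-threshold or NA sites break runs
  v4 <- c(1, 1, NA, 1, 1, 1, 1)
  cr4 <- segment_candidate_regions(v4, pos, threshold = 0.5, min_cr_cpgs = 4)
  expect_equal(cr4$start_idx, 4L)
  expect_equal(cr4$end_idx, 7L)
})

test_that("emitted candidate regions satisfy their invariants on random input", {
  set.seed(7)
  for (rep in 1:20) {
    K <- 200
    pos <- cumsum(sample(c(50:500, 3000), K, replace = TRUE))
    v <- abs(rnorm(K, 0.05, 0.05))
    v[sample(K, 10)] <- NA
    thr <- 0.07
    cr <- segment_candidate_regions(v, pos, thr, min_cr_cpgs = 3, max_gap_bp = 2000)
    if (nrow(cr) == 0) next
    expect_true(all(cr$n_cpgs >= 3))
    expect_true(all(cr$end_idx >= cr$start_idx))
    expect_true(all(diff(cr$start_pos) > 0))
    for (r in seq_len(nrow(cr))) {
      idx <- cr$start_idx[r]:cr$end_idx[r]
      expect_true(all(!is.na(v[idx]) & v[idx] > thr))
      if (length(idx) > 1) expect_true(all(diff(pos[idx]) <= 2000))
    }
  }
})
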