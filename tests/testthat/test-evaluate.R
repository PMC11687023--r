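pos_universe <- seq(100L, by = 100L, length.out = 100)

span <- function(i, j) {
  tibble::tibble(start_pos = pos_universe[i], end_pos = pos_universe[j])
}

test_that("region matching uses the 3-shared-CpG boundary", {
  truth <- span(10, 20)
  # exactly 3 shared sites -> TP
  r3 <- region_match(span(18, 30), truth, pos_universe)
  expect_equal(r3$tp, 1L)
  expect_equal(r3$precision, 1)
  expect_equal(r3$recall, 1)
  # 2 shared sites -> FP and the truth is missed
  r2 <- region_match(span(19, 30), truth, pos_universe)
  expect_equal(r2$tp, 0L)
  expect_equal(r2$fp, 1L)
  expect_equal(r2$recall, 0)
  # perfect detection
  rp <- region_match(truth, truth, pos_universe)
  expect_equal(rp$precision, 1)
  expect_equal(rp$recall, 1)
  # invariant to region order
  det <- dplyr::bind_rows(span(1, 5), span(40, 50), span(18, 30))
  a <- region_match(det, truth, pos_universe)
  b <- region_match(det[c(3, 1, 2), ], truth, pos_universe)
  expect_equal(a$tp, b$tp)
  expect_equal(a$precision, b$precision)
})

test_that("CpG matching intersects site sets", {
  out <- cpg_match(span(1, 40), span(11, 70), pos_universe)
  expect_equal(out$n_shared, 30L)
  expect_equal(out$precision, 30 / 40)
  expect_equal(out$recall, 30 / 60)
  disj <- cpg_match(span(1, 5), span(50, 60), pos_universe)
  expect_equal(disj$precision, 0)
  expect_equal(disj$recall, 0)
  sub <- cpg_match(span(20, 30), span(10, 50), pos_universe)
  expect_equal(sub$precision, 1)
})

test_that("F1 is the harmonic mean with a 0/0 convention", {
  expect_equal(f1(1, 1), 1)
  expect_equal(f1(1, 0), 0)
  expect_equal(f1(0, 0), 0)
  expect_equal(f1(0.75, 0.5), 0.6)
})

test_that("restricted precision-recall area follows the band convention", {
  # precision 1 across all recall -> full band
  expect_equal(
    rra(tibble::tibble(recall = c(0, 1), precision = c(1, 1))), 1
  )
  # precision never reaches the band -> 0
  expect_equal(
    rra(tibble::tibble(recall = c(0, 0.5, 1), precision = c(0.7, 0.6, 0.5))), 0
  )
  # worked trapezoid: recall 0 -> 0.5 at precision 0.9, then a vertical
  # drop below the band: 0.5 * (0.9 - 0.8) / 0.2
  pts <- tibble::tibble(recall = c(0, 0.5, 0.5), precision = c(0.9, 0.9, 0.6))
  expect_equal(rra(pts), 0.25)
  # linear interpolation at a band crossing
  pts2 <- tibble::tibble(recall = c(0, 1), precision = c(0.9, 0.7))
  # crosses 0.8 at recall 0.5; triangle area 0.5 * 0.1 / 2 = 0.025
  expect_equal(rra(pts2), 0.025 / 0.2)
  # monotone in pointwise precision improvements inside the band
  base <- tibble::tibble(recall = c(0, 0.5, 1), precision = c(0.95, 0.85, 0.82))
  better <- base
  better$precision <- pmin(base$precision + 0.03, 1)
  expect_gte(rra(better), rra(base))
})

test_that("regional means average observed CpGs per cell", {
  vals <- matrix(c(
    1, NA,
    1, NA,
    0, 1,
    NA, 0
  ), nrow = 4, byrow = TRUE)
  mat <- mat_from_dense(vals, pos = c(100L, 150L, 200L, 900L))
  regions <- tibble::tibble(start_pos = c(100L, 850L), end_pos = c(300L, 950L))
  rm <- regional_mean_matrix(mat, regions)
  expect_equal(rm[1, 1], 2 / 3)
  expect_equal(rm[1, 2], 1)
  expect_true(is.na(rm[2, 1]))
  expect_equal(rm[2, 2], 0)
  # single-site region equals that site's row
  one <- regional_mean_matrix(mat, tibble::tibble(start_pos = 200L, end_pos = 200L))
  expect_equal(unname(one[1, ]), c(0, 1))
})

test_that("Manhattan dissimilarity is symmetric, rescaled, and strict on empty pairs", {
  reg <- rbind(
    c(0.0, 1.0, 0.5),
    c(0.2, 1.0, NA),
    c(0.8, 1.0, 0.8)
  )
  colnames(reg) <- c("a", "b", "c")
  D <- manhattan_dissimilarity(reg)
  expect_equal(D["a", "b"], 1.0 + 0.8 + 0.2)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # pair (a, c) shares 2 of 3 regions -> rescale by 3/2
  expect_equal(D["a", "c"], (0.5 + 0) * 3 / 2)
  expect_equal(
    manhattan_dissimilarity(reg, rescale = FALSE)["a", "c"], 0.5
  )
  # identical cells -> zero
  reg2 <- cbind(x = c(0.1, 0.9), y = c(0.1, 0.9))
  expect_equal(manhattan_dissimilarity(reg2)["x", "y"], 0)
  # a pair sharing no region is an error naming the pair
  reg3 <- cbind(p = c(0.1, NA), q = c(NA, 0.2))
  expect_error(manhattan_dissimilarity(reg3), "share no observed region")
})

test_that("nearest-neighbor count score separates labeled blobs", {
  set.seed(14)
  # two perfectly separated blobs -> score 1
  x <- c(rnorm(30, 0, 0.1), rnorm(30, 10, 0.1))
  D <- as.matrix(dist(x, method = "manhattan"))
  labels <- rep(c("A", "B"), each = 30)
  expect_equal(nn_count_score(D, labels, g = 20, theta = 0.7), 1)
  # all same label -> 1 regardless of distances
  expect_equal(nn_count_score(D, rep("A", 60), g = 20, theta = 0.7), 1)
  # random labels on one blob: binomial tail P(count > 14 of 20) is tiny
  xr <- rnorm(60, 0, 1)
  Dr <- as.matrix(dist(xr, method = "manhattan"))
  lr <- sample(rep(c("A", "B"), each = 30))
  expect_lte(nn_count_score(Dr, lr, g = 20, theta = 0.7), 0.1)
  expect_error(nn_count_score(D, labels, g = 60), "smaller")
  # invariance to monotone transforms of the dissimilarity
  expect_equal(
    nn_count_score(D, labels, g = 20, theta = 0.7),
    nn_count_score(D^2, labels, g = 20, theta = 0.7)
  )
})
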