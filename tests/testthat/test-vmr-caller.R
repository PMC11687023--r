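# build an hmm_fit-shaped object with a prescribed decoded state sequence
fake_two_fit <- function(code, pos, log_score, pi0 = 0.4) {
  structure(
    list(
      model = "two_group", state_code = code,
      path = matrix(c(0, 0, 1, 0, 1, 1), ncol = 2)[code, , drop = FALSE],
      log_score = log_score, log_marginal = log_score + 1,
      pi_hat = c(pi0, 1 - pi0), m = rep(1L, length(code)),
      n = rep(2L, length(code)), pos = pos
    ),
    class = "hmm_fit"
  )
}

fake_one_fit <- function(K, pos, log_score) {
  structure(
    list(
      model = "one_group", state_code = rep(1L, K), path = rep(0L, K),
      log_score = log_score, log_marginal = log_score + 1,
      pi_hat = NULL, m = rep(1L, K), n = rep(2L, K), pos = pos
    ),
    class = "hmm_fit"
  )
}

cr_row <- function(K, pos) {
  tibble::tibble(
    cr_id = 1L, chrom = "chrT", start_idx = 10L, end_idx = 10L + K - 1L,
    start_pos = pos[1], end_pos = pos[K], n_cpgs = K
  )
}

test_that("a losing two-grouping model yields no VMR", {
  pos <- seq(100L, by = 50L, length.out = 10)
  cr <- cr_row(10, pos)
  one <- fake_one_fit(10, pos, log_score = -5)
  two <- fake_two_fit(rep(2L, 10), pos, log_score = -6)
  expect_equal(nrow(call_vmrs(cr, one, two)), 0L)
  # ties are conservative: no VMR
  two_tie <- fake_two_fit(rep(2L, 10), pos, log_score = -5)
  expect_equal(nrow(call_vmrs(cr, one, two_tie)), 0L)
})

test_that("an all-(0,1) winning decode spans the whole candidate region", {
  pos <- seq(100L, by = 50L, length.out = 10)
  cr <- cr_row(10, pos)
  one <- fake_one_fit(10, pos, -10)
  two <- fake_two_fit(rep(2L, 10), pos, -4)
  v <- call_vmrs(cr, one, two)
  expect_equal(nrow(v), 1L)
  expect_equal(v$start_idx, 10L)
  expect_equal(v$end_idx, 19L)
  expect_equal(v$n_cpgs, 10L)
  expect_equal(v$loglik_increment, 6)
})

test_that("short mixed runs are rejected and edge states trimmed", {
  pos <- seq(100L, by = 50L, length.out = 10)
  cr <- cr_row(10, pos)
  one <- fake_one_fit(10, pos, -10)
  # longest (0,1) run has 4 sites -> no VMR at the default minimum of 5
  code <- c(1L, 2L, 2L, 2L, 2L, 1L, 3L, 3L, 3L, 3L)
  expect_equal(nrow(call_vmrs(cr, one, fake_two_fit(code, pos, -4))), 0L)
  # edges decoded (0,0)/(1,1) are trimmed off
  code2 <- c(3L, 3L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L)
  v <- call_vmrs(cr, one, fake_two_fit(code2, pos, -4), min_vmr_cpgs = 5)
  expect_equal(v$start_idx, 12L)
  expect_equal(v$end_idx, 17L)
})

test_that("multiple qualifying runs merge into one enveloping VMR", {
  pos <- seq(100L, by = 50L, length.out = 14)
  cr <- cr_row(14, pos)
  one <- fake_one_fit(14, pos, -10)
  # runs of 6 and 5 mixed sites separated by 3 (1,1) sites
  code <- c(rep(2L, 6), rep(3L, 3), rep(2L, 5))
  v <- call_vmrs(cr, one, fake_two_fit(code, pos, -4), min_vmr_cpgs = 5)
  expect_equal(nrow(v), 1L)
  expect_equal(v$start_idx, 10L)
  expect_equal(v$end_idx, 23L)
  # diagnostics mode reports the runs separately
  v2 <- call_vmrs(cr, one, fake_two_fit(code, pos, -4),
    min_vmr_cpgs = 5, merge = FALSE
  )
  expect_equal(nrow(v2), 2L)
  expect_equal(v2$n_cpgs, c(6L, 5L))
  # the untrimmed span is never smaller than the trimmed one
  v3 <- call_vmrs(cr, one, fake_two_fit(code, pos, -4), trim = FALSE)
  expect_lte(v3$start_idx, v$start_idx)
  expect_gte(v3$end_idx, v$end_idx)
})

test_that("ranking is a deterministic total order on the increment", {
  vmrs <- tibble::tibble(
    chrom = "chrT", start_pos = c(500L, 100L, 900L), end_pos = c(600L, 200L, 950L),
    loglik_increment = c(3.2, 7.1, 0.4)
  )
  r <- rank_vmrs(vmrs)
  expect_equal(r$loglik_increment, c(7.1, 3.2, 0.4))
  expect_equal(r$rank, 1:3)
  # equal increments fall back to genomic order
  vmrs$loglik_increment <- 1
  r2 <- rank_vmrs(vmrs)
  expect_equal(r2$start_pos, c(100L, 500L, 900L))
  expect_equal(nrow(rank_vmrs(vmrs[0, ])), 0L)
})

test_that("the pipeline is deterministic and its VMRs sit inside their CRs", {
  sim <- simulate_dataset(
    n_sites = 1500, n_cells = 150, sparsity = 0.85, n_vmrs = 6, rho = 2,
    max_cpgs = 40, seed = 31
  )
  res1 <- detect_vmrs(sim$mat, null_sim_sites = 3000, seed = 17)
  res2 <- detect_vmrs(sim$mat, null_sim_sites = 3000, seed = 17)
  expect_equal(res1$vmr, res2$vmr)
  expect_equal(res1$threshold, res2$threshold)
  v <- res1$vmr
  if (nrow(v)) {
    cr <- res1$cr
    for (i in seq_len(nrow(v))) {
      parent <- cr[cr$cr_id == v$cr_id[i], ]
      expect_gte(v$start_idx[i], parent$start_idx)
      expect_lte(v$end_idx[i], parent$end_idx)
    }
    # disjoint and sorted across CRs
    if (nrow(v) > 1) {
      vs <- v[order(v$start_pos), ]
      expect_true(all(vs$start_pos[-1] > vs$end_pos[-nrow(vs)]))
    }
  }
  g <- glance(res1)
  expect_equal(g$n_vmrs, nrow(res1$vmr))
  expect_s3_class(autoplot(res1), "ggplot")
})
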