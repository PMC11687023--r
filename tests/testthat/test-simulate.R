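test_that("scaffolds hit the target sparsity and are reproducible", {
  sc <- simulate_scaffold(2000, 100, 0.9, seed = 1)
  expect_lt(abs(sc$sparsity_realized - 0.9), 0.02)
  expect_true(all(diff(sc$pos) > 0))
  sc2 <- simulate_scaffold(2000, 100, 0.9, seed = 1)
  expect_identical(sc$entries, sc2$entries)
  expect_identical(sc$pos, sc2$pos)
  # zero sparsity: fully observed
  sc0 <- simulate_scaffold(50, 10, 0, seed = 2)
  expect_equal(nrow(sc0$entries), 500L)
  # spacing roughly matches the configured median
  expect_lt(abs(median(diff(sc$pos)) - 120), 30)
})

test_that("HMM chromosomes follow the transition table and are reproducible", {
  # absorbing table with a forced methylated start stays methylated
  abs_tt <- transition_table(0, 2000, 0, 1)
  sc <- simulate_scaffold(300, 30, 0.5, seed = 3)
  mat <- simulate_hmm_chromosome(sc, abs_tt, default_em, s_init = 1, seed = 4)
  expect_equal(attr(mat, "hidden_states"), rep(1L, 300))
  # empirical transition frequencies match the table within 3 s.e.
  flat_tt <- transition_table(0, 2000, 0.3, 0.7)
  sc2 <- simulate_scaffold(20000, 5, 0.5, seed = 5)
  m2 <- simulate_hmm_chromosome(sc2, flat_tt, default_em, seed = 6)
  s <- attr(m2, "hidden_states")
  from0 <- s[-length(s)] == 0
  p10 <- mean(s[-1][from0])
  p11 <- mean(s[-1][!from0])
  se <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(p10 - 0.3), se(0.3, sum(from0)))
  expect_lt(abs(p11 - 0.7), se(0.7, sum(!from0)))
  # determinism
  m3 <- simulate_hmm_chromosome(sc, abs_tt, default_em, s_init = 1, seed = 4)
  expect_identical(m2$entries, simulate_hmm_chromosome(
    sc2, flat_tt, default_em,
    seed = 6
  )$entries)
  expect_identical(mat$entries, m3$entries)
})

test_that("cluster sampling honors the weight formula and the constraints", {
  # weight formula spot values
  w <- function(p) 1 - sqrt(2 * abs(0.5 - p))
  expect_equal(w(0.5), 1)
  expect_equal(w(0.375), 0.5)
  expect_equal(w(0), 0)
  set.seed(8)
  pos <- cumsum(sample(c(40:200, 600), 3000, replace = TRUE))
  meanm <- runif(3000)
  cl <- sample_vmr_clusters(pos, meanm, 30,
    min_cpgs = 5, max_cpgs = 50,
    max_gap_bp = 500, max_width_bp = 10000
  )
  expect_true(all(cl$n_cpgs >= 5))
  # sampled clusters respect the width cap; post-merge spans may exceed it
  # by at most one extra cluster plus the bridge
  expect_true(all(pos[cl$end_idx] - pos[cl$start_idx] <= 2 * 10000 + 3 * 500))
  for (r in seq_len(nrow(cl))) {
    idx <- cl$start_idx[r]:cl$end_idx[r]
    if (length(idx) > 1) expect_true(all(diff(pos[idx]) <= 500))
  }
  # adjacent spans with <= 2 CpGs between were merged unless the bridge
  # breaks the gap constraint
  n_between <- cl$start_idx[-1] - cl$end_idx[-nrow(cl)] - 1L
  for (i in which(n_between <= 2L)) {
    bridge <- cl$end_idx[i]:cl$start_idx[i + 1]
    expect_gt(max(diff(pos[bridge])), 500)
  }
  # a chromosome at extreme methylation has zero-weight clusters only
  expect_error(
    sample_vmr_clusters(pos, rep(1, 3000), 5),
    "eligible"
  )
})

test_that("prevalence draws follow the binomial-coefficient distribution", {
  # rho = 2: the only support point is 1/2
  expect_equal(unique(sample_prevalence(2, n = 50, seed = 1)$pi0), 0.5)
  expect_error(sample_prevalence(1), "rho")
  # rho = 4: P(1/4, 1/2, 3/4) = (4, 6, 4) / 14 = (2/7, 3/7, 2/7)
  draws <- sample_prevalence(4, n = 2e4, seed = 2)
  freq <- as.numeric(table(factor(draws$rho_r, levels = 1:3))) / 2e4
  expected <- c(2, 3, 2) / 7
  se3 <- 3 * sqrt(expected * (1 - expected) / 2e4)
  expect_true(all(abs(freq - expected) < se3))
  expect_equal(draws$pi0 + draws$pi1, rep(1, 2e4))
})

test_that("injected VMR signal matches the emission moments by grouping", {
  em <- emission_params(19, 1, 1, 19, 0.3)
  sc <- simulate_scaffold(400, 200, 0.3, seed = 9)
  mat <- simulate_hmm_chromosome(sc, default_tt, em, seed = 10)
  spans <- tibble::tibble(
    start_idx = c(50L, 200L), end_idx = c(120L, 280L),
    n_cpgs = c(71L, 81L), mean_meth = 0.5, weight = 1
  )
  truth <- build_synthetic_truth(spans, mat$pos, 200, rho = 2, seed = 11)
  out <- inject_vmr_signal(mat, truth, em, seed = 12)
  tb <- tibble::as_tibble(out)
  grp <- truth$group_of(1)
  site_sel <- out$pos[spans$start_idx[1]:spans$end_idx[1]]
  inside <- tb[tb$pos %in% site_sel, ]
  cellnum <- match(inside$cell_id, out$cell_ids)
  mean_u <- mean(inside$value[grp[cellnum] == "U"])
  mean_m <- mean(inside$value[grp[cellnum] == "M"])
  # expected means: ZIBB (1 - w0) * 0.05, BB 0.95
  expect_lt(abs(mean_u - 0.7 * 0.05), 0.02)
  expect_lt(abs(mean_m - 0.95), 0.02)
  # sites outside the spans keep their background values
  outside_pos <- out$pos[1:40]
  before <- tibble::as_tibble(mat)
  expect_identical(
    tb[tb$pos %in% outside_pos, ],
    before[before$pos %in% outside_pos, ]
  )
})

test_that("generated matrices satisfy the container invariants", {
  sim <- simulate_dataset(
    n_sites = 800, n_cells = 60, sparsity = 0.7, n_vmrs = 4, rho = 3,
    max_cpgs = 30, seed = 13
  )
  expect_s3_class(sim$mat, "meth_mat")
  expect_true(all(sim$mat$entries$value %in% c(0, 1)))
  expect_true(all(diff(sim$mat$pos) > 0))
  tv <- sim$truth$vmrs
  expect_true(all(tv$start_idx[-1] > tv$end_idx[-nrow(tv)]))
  # group assignment fractions match the drawn prevalence up to rounding
  for (r in seq_len(nrow(tv))) {
    frac_u <- mean(sim$truth$group_of(r) == "U")
    expect_lt(abs(frac_u - tv$pi0[r]), 1 / sim$truth$n_subpop)
  }
})
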