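# Shared fixtures and independent oracles used across test files.

default_em <- default_emission_params()
default_tt <- default_transition_table()

# small dense matrix builder: `values` is a K x C matrix with NA = missing
mat_from_dense <- function(values, pos = NULL, chrom = "chrT") {
  K <- nrow(values)
  C <- ncol(values)
  pos <- pos %||% seq(100L, by = 100L, length.out = K)
  obs <- which(!is.na(values), arr.ind = TRUE)
  meth_mat(
    chrom, pos, sprintf("c%02d", seq_len(C)),
    tibble::tibble(
      site = obs[, 1], cell = obs[, 2],
      value = values[obs]
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force decoding oracle: enumerates every state sequence and scores
# it with independent scalar probability calls; ties resolved toward the
# lexicographically smaller sequence (first strict improvement wins)
bf_decode <- function(m, n, pos, table, emission, model, pi = NULL) {
  K <- length(m)
  S <- if (model == "one_group") 2L else 3L
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), K)))[, K:1, drop = FALSE]
  best <- -Inf
  bpath <- NULL
  for (r in seq_len(nrow(grid))) {
    cd <- unname(grid[r, ])
    if (model == "one_group") {
      ll <- log(1 / 2) + sum(one_group_emission(m, n, cd - 1, emission, log = TRUE))
      if (K > 1) {
        for (k in 2:K) {
          ll <- ll + log(
            transition_prob(table, cd[k - 1] - 1, cd[k] - 1, pos[k] - pos[k - 1])
          )
        }
      }
    } else {
      Sm <- two_group_states_fixture
      ll <- log(1 / 3)
      for (k in seq_len(K)) {
        ll <- ll + two_group_emission(m[k], n[k], Sm[cd[k], ], pi, emission,
          log = TRUE
        )
      }
      if (K > 1) {
        for (k in 2:K) {
          ll <- ll + log(two_group_transition(
            table, Sm[cd[k - 1], ], Sm[cd[k], ], pos[k] - pos[k - 1]
          ))
        }
      }
    }
    if (ll > best + 1e-12) {
      best <- ll
      bpath <- cd
    }
  }
  list(code = unname(bpath), log_score = unname(best))
}

two_group_states_fixture <- matrix(c(0, 0, 1, 0, 1, 1), ncol = 2)

# random (m, n) counts for a region
random_counts <- function(K, n_max = 6L) {
  n <- sample(0:n_max, K, replace = TRUE)
  m <- vapply(n, function(x) sample(0:x, 1L), 1L)
  list(m = m, n = n)
}

# simulate one candidate region's counts under the two-grouping model with
# all sites in state (0,1) -- the generator used for recovery checks
sim_two_group_cr <- function(K, C, sparsity, pi0, emission, seed) {
  set.seed(seed)
  pos <- cumsum(c(1000L, sample(20:200, K - 1, replace = TRUE)))
  n_u <- round(pi0 * C)
  grp <- sample(c(rep("U", n_u), rep("M", C - n_u)))
  m <- integer(K)
  n <- integer(K)
  for (k in seq_len(K)) {
    cov <- runif(C) < (1 - sparsity)
    nu <- sum(cov & grp == "U")
    nm <- sum(cov & grp == "M")
    mu <- vmrscan:::rzibb(1, nu, emission$alpha_u, emission$beta_u, emission$w0_u)
    mm <- vmrscan:::rbb(1, nm, emission$alpha_m, emission$beta_m)
    m[k] <- mu + mm
    n[k] <- nu + nm
  }
  list(m = m, n = n, pos = pos)
}
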