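#' Beta-binomial probability mass
#'
#' Mass of `m` successes in `n` trials when the success probability is drawn
#' from `Beta(alpha, beta)`: `choose(n, m) * B(m + alpha, n - m + beta) /
#' B(alpha, beta)`. Computed in log space; `bb_pmf()` exponentiates.
#'
#' @param m,n Integer counts with `0 <= m <= n` (vectorized, recycled).
#' @param alpha,beta Positive shape parameters.
#' @return Probability (or log-probability) vector.
#' @export
bb_pmf <- function(m, n, alpha, beta) exp(bb_lpmf(m, n, alpha, beta))

#' @rdname bb_pmf
#' @export
bb_lpmf <- function(m, n, alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0)) abort("shapes must be positive")
  if (any(m < 0 | m > n)) abort("m must satisfy 0 <= m <= n")
  lchoose(n, m) + lbeta(m + alpha, n - m + beta) - lbeta(alpha, beta)
}

#' Zero-inflated beta-binomial probability mass
#'
#' `w0 * 1{m = 0} + (1 - w0) * bb_pmf(m, n, alpha, beta)`. The empty-site
#' convention gives mass 1 at `(n, m) = (0, 0)`.
#'
#' @inheritParams bb_pmf
#' @param w0 Zero-inflation probability in \[0, 1\].
#' @return Probability (or log-probability) vector.
#' @export
zibb_pmf <- function(m, n, alpha, beta, w0) exp(zibb_lpmf(m, n, alpha, beta, w0))

#' @rdname zibb_pmf
#' @export
zibb_lpmf <- function(m, n, alpha, beta, w0) {
  if (length(w0) != 1L || w0 < 0 || w0 > 1) abort("w0 must lie in [0, 1]")
  lbb <- bb_lpmf(m, n, alpha, beta)
  out <- log1p(-w0) + lbb
  z <- m == 0
  if (any(z)) {
    # log(w0 + (1 - w0) exp(lbb)) without underflow
    out[z] <- log(w0 + exp(log1p(-w0) + lbb[z]))
  }
  out
}

#' One-grouping emission probability
#'
#' `P(m | s, n)`: beta-binomial under the methylated hidden state (`s = 1`),
#' zero-inflated beta-binomial under the unmethylated state (`s = 0`).
#'
#' @inheritParams bb_pmf
#' @param s Hidden state, 0 or 1.
#' @param emission An [emission_params()].
#' @param log Return log probability?
#' @return Probability vector.
#' @export
one_group_emission <- function(m, n, s, emission, log = FALSE) {
  if (!all(s %in% c(0, 1))) abort("s must be 0 or 1")
  lp <- ifelse(
    rep_len(s, length(m)) == 1,
    bb_lpmf(m, n, emission$alpha_m, emission$beta_m),
    zibb_lpmf(m, n, emission$alpha_u, emission$beta_u, emission$w0_u)
  )
  if (log) lp else exp(lp)
}

# the 3-element two-grouping state space, in lexicographic order
two_group_states <- function() {
  matrix(c(0L, 0L, 1L, 0L, 1L, 1L),
    ncol = 2,
    dimnames = list(c("(0,0)", "(0,1)", "(1,1)"), c("s0", "s1"))
  )
}

check_pair_state <- function(s) {
  if (length(s) != 2L || !all(s %in% c(0, 1))) {
    abort("a two-grouping state is a pair with entries in {0, 1}")
  }
  if (s[1] == 1 && s[2] == 0) {
    abort("state (1,0) is excluded from the two-grouping state space")
  }
  invisible(s)
}

#' Two-grouping transition probability
#'
#' The bivariate transition factorizes over the two groupings,
#' `P(s | s_prev, d) proportional to P(s0 | s0_prev, d) * P(s1 | s1_prev,
#' d)`, renormalized over the three allowed target states (the pair (1,0) is
#' excluded).
#'
#' @param table A [transition_table()].
#' @param s_prev,s Length-2 state pairs from `{(0,0), (0,1), (1,1)}`.
#' @param d Positive distance in bp.
#' @return Normalized transition probability (scalar).
#' @export
two_group_transition <- function(table, s_prev, s, d) {
  check_pair_state(s_prev)
  check_pair_state(s)
  S <- two_group_states()
  w <- transition_prob(table, s_prev[1], S[, 1], d) *
    transition_prob(table, s_prev[2], S[, 2], d)
  tgt <- which(S[, 1] == s[1] & S[, 2] == s[2])
  unname(w[tgt] / sum(w))
}

# K x 2 log transition matrices (one-grouping) for each inter-site gap
ltr_one_group <- function(table, gaps) {
  p <- trans_p1(table, gaps)
  lapply(seq_along(gaps), function(g) {
    matrix(
      log(c(
        1 - p$p1_given_0[g], 1 - p$p1_given_1[g],
        p$p1_given_0[g], p$p1_given_1[g]
      )),
      nrow = 2
    ) # rows: from-state 0/1; cols: to-state 0/1
  })
}

# 3 x 3 log transition matrices (two-grouping) for each inter-site gap
ltr_two_group <- function(table, gaps) {
  S <- two_group_states()
  p <- trans_p1(table, gaps)
  lapply(seq_along(gaps), function(g) {
    p1 <- c(p$p1_given_0[g], p$p1_given_1[g]) # P(1 | from = 0/1)
    w <- outer(seq_len(3), seq_len(3), function(a, b) {
      pa <- ifelse(S[b, 1] == 1, p1[S[a, 1] + 1], 1 - p1[S[a, 1] + 1])
      pb <- ifelse(S[b, 2] == 1, p1[S[a, 2] + 1], 1 - p1[S[a, 2] + 1])
      pa * pb
    })
    log(w / rowSums(w))
  })
}

# Precomputed structure for the (0,1)-state emission of a whole region.
# For site k the emission is a double sum over (i, j): i cells drawn from
# the M grouping (binomial in r = pi1), j of them observed methylated
# (beta-binomial), and the remaining m - j observed methylated among the
# n - i U-grouping cells (zero-inflated beta-binomial). Everything except
# the binomial factor in r is constant in pi and precomputed once.
cr_emission_precomp <- function(m, n, emission) {
  K <- length(m)
  stopifnot(length(n) == K, all(m >= 0), all(m <= n))
  lp_u <- zibb_lpmf(m, n, emission$alpha_u, emission$beta_u, emission$w0_u)
  lp_m <- bb_lpmf(m, n, emission$alpha_m, emission$beta_m)
  ii <- jj <- kk <- vector("list", K)
  for (k in seq_len(K)) {
    if (n[k] == 0L) next
    i <- rep.int(0:n[k], pmin(m[k], 0:n[k]) + 1L)
    j <- sequence(pmin(m[k], 0:n[k]) + 1L) - 1L
    ok <- (m[k] - j) <= (n[k] - i)
    ii[[k]] <- i[ok]
    jj[[k]] <- j[ok]
    kk[[k]] <- rep.int(k, sum(ok))
  }
  i <- unlist(ii, use.names = FALSE) %||% integer(0)
  j <- unlist(jj, use.names = FALSE) %||% integer(0)
  site <- unlist(kk, use.names = FALSE) %||% integer(0)
  nk <- n[site]
  mk <- m[site]
  const <- lchoose(nk, i) +
    bb_lpmf(j, i, emission$alpha_m, emission$beta_m) +
    zibb_lpmf(
      mk - j, nk - i, emission$alpha_u, emission$beta_u, emission$w0_u
    )
  groups <- split.default(seq_along(site), factor(site, levels = seq_len(K)))
  list(
    K = K, m = m, n = n, lp_u = lp_u, lp_m = lp_m,
    i = i, n_minus_i = nk - i, const = const, site = site, groups = groups
  )
}

# log P(m_k | s = (0,1), pi, n_k) for all sites, plus per-site E[i] under
# the normalized summand weights (used by the analytic gradient)
em01_eval <- function(pre, pi1, want_mean_i = FALSE) {
  K <- pre$K
  lp <- numeric(K) # n = 0 sites have emission 1
  mean_i <- rep(NA_real_, K)
  if (pi1 <= 0 || pi1 >= 1) {
    # degenerate prevalence: collapse identities
    lp <- if (pi1 <= 0) pre$lp_u else pre$lp_m
    return(list(lp = lp, mean_i = mean_i))
  }
  lw <- pre$const + pre$i * log(pi1) + pre$n_minus_i * log1p(-pi1)
  for (k in seq_len(K)) {
    ix <- pre$groups[[k]]
    if (length(ix) == 0L) next
    mx <- max(lw[ix])
    w <- exp(lw[ix] - mx)
    sw <- sum(w)
    lp[k] <- mx + log(sw)
    if (want_mean_i) mean_i[k] <- sum(w * pre$i[ix]) / sw
  }
  list(lp = lp, mean_i = mean_i)
}

#' Two-grouping emission probability
#'
#' `P(m | s, pi, n)` under the two-grouping model: a binomial split of the
#' `n` covered cells into the methylated grouping (success rate
#' r = s0 \* pi0 + s1 \* pi1) convolved with the beta-binomial (methylated
#' grouping) and zero-inflated beta-binomial (unmethylated grouping)
#' observation components, summed with log-sum-exp. At `s = (0,0)` and
#' `s = (1,1)` this collapses exactly to the one-grouping emissions.
#'
#' @inheritParams bb_pmf
#' @param s Length-2 state pair from `{(0,0), (0,1), (1,1)}`.
#' @param pi Length-2 prevalence vector `(pi0, pi1)` summing to 1.
#' @param emission An [emission_params()].
#' @param log Return log probability?
#' @return Probability (scalar; `m` must be scalar here).
#' @export
two_group_emission <- function(m, n, s, pi, emission, log = FALSE) {
  check_pair_state(s)
  check_prevalence(pi)
  stopifnot(length(m) == 1L, length(n) == 1L)
  r <- s[1] * pi[1] + s[2] * pi[2]
  if (r <= 0) {
    lp <- zibb_lpmf(m, n, emission$alpha_u, emission$beta_u, emission$w0_u)
  } else if (r >= 1) {
    lp <- bb_lpmf(m, n, emission$alpha_m, emission$beta_m)
  } else {
    pre <- cr_emission_precomp(m, n, emission)
    lp <- em01_eval(pre, r)$lp
  }
  if (log) lp else exp(lp)
}

check_prevalence <- function(pi) {
  if (length(pi) != 2L || any(!is.finite(pi)) || any(pi < 0)) {
    abort("pi must be a non-negative pair")
  }
  if (abs(sum(pi) - 1) > 1e-10) abort("pi must sum to 1 (tolerance 1e-10)")
  invisible(pi)
}
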