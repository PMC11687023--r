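# Generic max-path decoding over a log-space HMM.
#
# Backward dynamic programming followed by a greedy forward selection: among
# all maximum-probability state sequences this returns the lexicographically
# smallest one (state order = index order), which makes decoding fully
# deterministic under ties.
#
# log_init: length-S log initial-state probabilities
# log_em:   K x S log emission matrix
# ltr:      list of K - 1 S x S log transition matrices (row = from-state)
viterbi_decode <- function(log_init, log_em, ltr) {
  K <- nrow(log_em)
  S <- ncol(log_em)
  delta <- matrix(0, K, S) # delta[k, s]: best log prob of suffix k..K from s
  delta[K, ] <- log_em[K, ]
  if (K > 1) {
    for (k in (K - 1):1) {
      step <- ltr[[k]] + matrix(delta[k + 1, ], S, S, byrow = TRUE)
      delta[k, ] <- log_em[k, ] + apply(step, 1, max)
    }
  }
  path <- integer(K)
  tot <- log_init + delta[1, ]
  path[1] <- which.max(tot) # first index attaining the max
  if (K > 1) {
    for (k in 2:K) {
      cand <- ltr[[k - 1]][path[k - 1], ] + delta[k, ]
      path[k] <- which.max(cand)
    }
  }
  list(path = path, log_score = max(tot))
}

# forward log marginal likelihood (sum over all state sequences)
forward_logml <- function(log_init, log_em, ltr) {
  lse <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) {
      return(mx)
    }
    mx + log(sum(exp(x - mx)))
  }
  K <- nrow(log_em)
  S <- ncol(log_em)
  a <- log_init + log_em[1, ]
  if (K > 1) {
    for (k in 2:K) {
      a <- vapply(
        seq_len(S),
        function(s) lse(a + ltr[[k - 1]][, s]),
        0
      ) + log_em[k, ]
    }
  }
  lse(a)
}

# emission matrices for the two models
log_em_one_group <- function(m, n, emission) {
  cbind(
    zibb_lpmf(m, n, emission$alpha_u, emission$beta_u, emission$w0_u),
    bb_lpmf(m, n, emission$alpha_m, emission$beta_m)
  )
}

log_em_two_group <- function(pre, pi) {
  cbind(pre$lp_u, em01_eval(pre, pi[2])$lp, pre$lp_m)
}

#' Viterbi decoding of the one- or two-grouping HMM
#'
#' Finds the maximum-probability hidden-state sequence for the counts of one
#' region under the chosen model, with a uniform initial-state distribution.
#' Ties are broken toward the lexicographically smaller state sequence.
#'
#' @param m,n Per-site methylated and covered cell counts (length `K`).
#' @param pos Site coordinates (length `K`).
#' @param table A [transition_table()].
#' @param emission An [emission_params()].
#' @param model `"one_group"` or `"two_group"`.
#' @param pi Prevalence pair `(pi0, pi1)`; required for the two-grouping
#'   model.
#' @return A list: `path` (for `one_group` a 0/1 vector; for `two_group` a
#'   `K x 2` matrix of state pairs), `state_code` (1-based index into the
#'   state space), and `log_score` (the decoded path's joint log
#'   likelihood).
#' @export
viterbi <- function(m, n, pos, table, emission,
                    model = c("one_group", "two_group"), pi = NULL) {
  model <- match.arg(model)
  K <- length(m)
  stopifnot(length(n) == K, length(pos) == K, K >= 1)
  gaps <- if (K > 1) diff(pos) else numeric(0)
  if (model == "one_group") {
    log_em <- log_em_one_group(m, n, emission)
    ltr <- ltr_one_group(table, gaps)
    res <- viterbi_decode(rep(log(1 / 2), 2), log_em, ltr)
    list(
      path = res$path - 1L, state_code = res$path,
      log_score = res$log_score
    )
  } else {
    if (is.null(pi)) abort("two_group model requires `pi`")
    check_prevalence(pi)
    pre <- cr_emission_precomp(m, n, emission)
    log_em <- log_em_two_group(pre, pi)
    ltr <- ltr_two_group(table, gaps)
    res <- viterbi_decode(rep(log(1 / 3), 3), log_em, ltr)
    list(
      path = two_group_states()[res$path, , drop = FALSE],
      state_code = res$path, log_score = res$log_score
    )
  }
}
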