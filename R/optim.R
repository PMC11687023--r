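#' Exponentiated-gradient update on the 2-simplex
#'
#' `pi_new` is proportional to `pi * exp(-eta * gradient)`, renormalized to
#' sum to one. The gradient is centered before exponentiation (subtracting
#' its mean), which leaves the update mathematically unchanged (a common
#' factor cancels in the normalization) but avoids overflow for large
#' gradients. Equal gradient components therefore leave `pi` exactly
#' unchanged, as does `eta = 0`.
#'
#' @param pi Prevalence pair on the simplex.
#' @param gradient Length-2 finite gradient of the objective.
#' @param eta Learning rate (> 0 for a real step; 0 is the identity).
#' @return Updated prevalence pair.
#' @export
eg_update <- function(pi, gradient, eta) {
  check_prevalence(pi)
  if (length(gradient) != 2L || any(!is.finite(gradient))) {
    abort("gradient must be a finite pair")
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0) {
    abort("eta must be a non-negative scalar")
  }
  g <- gradient - mean(gradient)
  w <- pi * exp(-eta * g)
  x <- w[1] / (w[1] + w[2])
  c(x, 1 - x) # sums to 1 exactly
}

#' Prevalence objective and analytic gradient at a fixed path
#'
#' The prevalence objective is the negative sum over sites of the log
#' two-grouping emission probability at the fixed decoded path. Only sites
#' decoded `(0,1)` depend on `pi`: their emission involves the binomial
#' split rate r = pi1, and the partial derivative with respect to `pi1`
#' follows from differentiating the binomial factor inside the double sum,
#' giving `d log P / d pi1 = E[i] / pi1 - (n - E[i]) / (1 - pi1)` with the
#' expectation taken under the normalized summand weights. Sites decoded
#' `(0,0)` or `(1,1)` have `r` pinned at 0 or 1 on the simplex, so their
#' contribution to the gradient is zero.
#'
#' @param path Integer state codes (1 = (0,0), 2 = (0,1), 3 = (1,1)) or a
#'   `K x 2` state matrix.
#' @param m,n Per-site counts.
#' @param pi Prevalence pair (interior of the simplex for a finite
#'   gradient at `(0,1)` sites).
#' @param emission An [emission_params()].
#' @param pre Optional precomputed emission structure (internal reuse).
#' @return List with `objective` (scalar) and `gradient` (length-2).
#' @export
pi_objective_and_gradient <- function(path, m, n, pi, emission, pre = NULL) {
  check_prevalence(pi)
  code <- path_codes(path)
  K <- length(code)
  stopifnot(length(m) == K, length(n) == K)
  pre <- pre %||% cr_emission_precomp(m, n, emission)
  lp <- numeric(K)
  lp[code == 1L] <- pre$lp_u[code == 1L]
  lp[code == 3L] <- pre$lp_m[code == 3L]
  grad <- c(0, 0)
  mixed <- which(code == 2L)
  if (length(mixed)) {
    ev <- em01_eval(pre, pi[2], want_mean_i = TRUE)
    lp[mixed] <- ev$lp[mixed]
    ei <- ev$mean_i[mixed]
    nn <- pre$n[mixed]
    ok <- !is.na(ei) # n = 0 sites contribute nothing
    dll <- sum(ei[ok] / pi[2] - (nn[ok] - ei[ok]) / (1 - pi[2]))
    grad <- c(0, -dll)
  }
  objective <- -sum(lp)
  if (!is.finite(objective)) {
    abort(sprintf(
      "non-finite prevalence objective (first bad site: %d)",
      which(!is.finite(lp))[1]
    ))
  }
  list(objective = objective, gradient = grad)
}

path_codes <- function(path) {
  if (is.matrix(path)) {
    S <- two_group_states()
    code <- match(
      paste(path[, 1], path[, 2]),
      paste(S[, 1], S[, 2])
    )
    if (anyNA(code)) abort("invalid two-grouping state in path")
    code
  } else {
    code <- as.integer(path)
    if (!all(code %in% 1:3)) abort("state codes must be 1, 2 or 3")
    code
  }
}

# joint log likelihood of a decoded path at given pi (two-grouping)
joint_loglik_two <- function(code, pi, pre, ltr) {
  lem <- log_em_two_group(pre, pi)
  K <- length(code)
  ll <- log(1 / 3) + sum(lem[cbind(seq_len(K), code)])
  if (K > 1) {
    for (k in 2:K) ll <- ll + ltr[[k - 1]][code[k - 1], code[k]]
  }
  ll
}

#' Fit the one-grouping HMM to a region
#'
#' The one-grouping model has no free parameters beyond the hidden states,
#' so fitting is a single Viterbi decode.
#'
#' @inheritParams viterbi
#' @return An object of class `hmm_fit` with elements `model`, `path`
#'   (0/1 per site), `log_score`, `log_marginal` (forward likelihood) and
#'   the per-site data.
#' @export
fit_one_group <- function(m, n, pos, table, emission) {
  v <- viterbi(m, n, pos, table, emission, model = "one_group")
  gaps <- if (length(m) > 1) diff(pos) else numeric(0)
  lm <- forward_logml(
    rep(log(1 / 2), 2), log_em_one_group(m, n, emission),
    ltr_one_group(table, gaps)
  )
  structure(
    list(
      model = "one_group", path = v$path, state_code = v$state_code,
      log_score = v$log_score, log_marginal = lm, pi_hat = NULL,
      per_init = NULL, trace = NULL, m = m, n = n, pos = pos
    ),
    class = "hmm_fit"
  )
}

#' Fit the two-grouping HMM to a region
#'
#' Maximizes the two-grouping joint likelihood by alternating between
#' Viterbi decoding of the hidden states at fixed prevalence and
#' exponentiated-gradient (EG) optimization of the prevalence at a fixed
#' path. EG steps use backtracking (the learning rate is halved whenever a
#' proposed step would increase the objective), so each phase never
#' degrades the joint likelihood. The alternation is run from each starting
#' value in `pi_inits` and the best final joint log likelihood wins;
#' convergence requires both the objective and `pi0` to stabilize.
#'
#' @inheritParams viterbi
#' @param pi_inits Starting values for `pi0` (default `c(0.2, 0.5, 0.8)`).
#' @param eta Initial EG learning rate (default 0.05).
#' @param tol Relative convergence tolerance for the objective and absolute
#'   tolerance for `pi0` (default 1e-4).
#' @param max_iter Maximum alternation rounds per initialization.
#' @param max_eg_steps Maximum EG steps within one round.
#' @return An `hmm_fit` with `path` (`K x 2` state matrix), `state_code`,
#'   `log_score`, `log_marginal`, `pi_hat`, a `per_init` diagnostics tibble
#'   and the per-round `trace` (joint log likelihood after the Viterbi and
#'   EG phases of each round, plus the Eq.-style prevalence objective).
#' @export
fit_two_group <- function(m, n, pos, table, emission,
                          pi_inits = c(0.2, 0.5, 0.8), eta = 0.05,
                          tol = 1e-4, max_iter = 100L, max_eg_steps = 50L) {
  K <- length(m)
  stopifnot(length(n) == K, length(pos) == K, K >= 1)
  gaps <- if (K > 1) diff(pos) else numeric(0)
  pre <- cr_emission_precomp(m, n, emission)
  ltr <- ltr_two_group(table, gaps)
  log_init <- rep(log(1 / 3), 3)

  run_init <- function(pi0) {
    pi <- c(pi0, 1 - pi0)
    prev_ll <- -Inf
    prev_pi0 <- pi0
    converged <- FALSE
    trace <- list()
    iter <- 0L
    code <- NULL
    for (round in seq_len(max_iter)) {
      iter <- round
      vit <- viterbi_decode(log_init, log_em_two_group(pre, pi), ltr)
      code <- vit$path
      ll_vit <- vit$log_score
      eg <- eg_phase(code, pi, pre, eta, tol, max_eg_steps)
      pi <- eg$pi
      ll_eg <- joint_loglik_two(code, pi, pre, ltr)
      trace[[round]] <- tibble(
        round = round, ll_after_viterbi = ll_vit, ll_after_eg = ll_eg,
        objective = eg$objective, pi0 = pi[1]
      )
      if (round > 1 &&
          abs(ll_eg - prev_ll) <= tol * (abs(prev_ll) + 1e-12) &&
          abs(pi[1] - prev_pi0) <= tol) {
        converged <- TRUE
        break
      }
      prev_ll <- ll_eg
      prev_pi0 <- pi[1]
    }
    # final decode at the final prevalence
    vit <- viterbi_decode(log_init, log_em_two_group(pre, pi), ltr)
    list(
      pi = pi, code = vit$path, log_score = vit$log_score,
      converged = converged, iterations = iter,
      trace = bind_rows(trace)
    )
  }

  fits <- lapply(pi_inits, run_init)
  scores <- vapply(fits, function(f) f$log_score, 0)
  best <- which.max(scores)
  per_init <- tibble(
    pi_init = pi_inits,
    pi0_hat = vapply(fits, function(f) f$pi[1], 0),
    log_score = scores,
    converged = vapply(fits, function(f) f$converged, TRUE),
    iterations = vapply(fits, function(f) f$iterations, 1L)
  )
  if (!any(per_init$converged)) {
    warn("no initialization converged; returning best attained fit")
  }
  f <- fits[[best]]
  lm <- forward_logml(log_init, log_em_two_group(pre, f$pi), ltr)
  structure(
    list(
      model = "two_group",
      path = two_group_states()[f$code, , drop = FALSE],
      state_code = f$code, log_score = f$log_score, log_marginal = lm,
      pi_hat = f$pi, per_init = per_init, trace = f$trace,
      m = m, n = n, pos = pos
    ),
    class = "hmm_fit"
  )
}

# EG inner loop at a fixed path, with backtracking halving
eg_phase <- function(code, pi, pre, eta, tol, max_steps) {
  og <- pi_objective_and_gradient(code, pre$m, pre$n, pi, NULL, pre = pre)
  obj <- og$objective
  if (all(og$gradient == 0)) {
    return(list(pi = pi, objective = obj, steps = 0L))
  }
  eta_cur <- eta
  for (step in seq_len(max_steps)) {
    g <- og$gradient - mean(og$gradient)
    # cap the exponent magnitude; backtracking handles the rest
    gmax <- max(abs(g))
    eta_eff <- if (gmax > 0) min(eta_cur, 50 / gmax) else eta_cur
    accepted <- FALSE
    for (bt in 1:30) {
      pi_new <- eg_update(pi, og$gradient, eta_eff)
      obj_new <- pi_objective_and_gradient(
        code, pre$m, pre$n, pi_new, NULL,
        pre = pre
      )$objective
      if (obj_new <= obj + 1e-12) {
        accepted <- TRUE
        break
      }
      eta_eff <- eta_eff / 2
    }
    if (!accepted) break
    d_obj <- abs(obj - obj_new)
    d_pi <- abs(pi_new[1] - pi[1])
    pi <- pi_new
    obj <- obj_new
    og <- pi_objective_and_gradient(code, pre$m, pre$n, pi, NULL, pre = pre)
    if (d_obj <= tol * (abs(obj) + 1e-12) && d_pi <= tol) break
    eta_cur <- min(eta, eta_eff * 2)
  }
  list(pi = pi, objective = obj, steps = step)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<hmm_fit> %s model, %d sites, log score %.3f\n",
    x$model, length(x$m), x$log_score
  ))
  if (!is.null(x$pi_hat)) {
    cat(sprintf("  pi_hat = (%.3f, %.3f)\n", x$pi_hat[1], x$pi_hat[2]))
  }
  invisible(x)
}

#' Tidy a fitted HMM into a per-site tibble
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per site: `site`, `pos`, `m`, `n` and the
#'   decoded state (`state` for one-grouping; `state_u`, `state_m` for
#'   two-grouping).
#' @export
tidy.hmm_fit <- function(x, ...) {
  base <- tibble(
    site = seq_along(x$m), pos = x$pos, m = x$m, n = x$n
  )
  if (x$model == "one_group") {
    base$state <- x$path
  } else {
    base$state_u <- x$path[, 1]
    base$state_m <- x$path[, 2]
  }
  base
}

#' One-row summary of a fitted HMM
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n_sites`, `log_score`,
#'   `log_marginal`, `pi0_hat`, `converged`.
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(
    model = x$model, n_sites = length(x$m), log_score = x$log_score,
    log_marginal = x$log_marginal,
    pi0_hat = if (is.null(x$pi_hat)) NA_real_ else x$pi_hat[1],
    converged = if (is.null(x$per_init)) TRUE else any(x$per_init$converged)
  )
}
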