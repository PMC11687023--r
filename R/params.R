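#' Distance-binned hidden-state transition probabilities
#'
#' The one-grouping HMM moves between an unmethylated (0) and a methylated
#' (1) hidden state; the probability of landing in state 1 depends on the
#' previous state and on the genomic distance between the two CpGs,
#' tabulated in distance bins. Beyond the last bin edge the probabilities
#' plateau at the final row's values, reflecting the decay of CpG-CpG
#' methylation correlation to a constant at large distances.
#'
#' @param bin_start,bin_end Integer bin edges in bp; bins are
#'   `(bin_start, bin_end]`, contiguous and strictly increasing. The final
#'   row is the plateau (applied to any distance beyond its `bin_start`).
#' @param p1_given_0 `P(s = 1 | s_prev = 0, d in bin)` per bin.
#' @param p1_given_1 `P(s = 1 | s_prev = 1, d in bin)` per bin.
#' @return A tibble of class `transition_table`.
#' @export
transition_table <- function(bin_start, bin_end, p1_given_0, p1_given_1) {
  n <- length(bin_start)
  stopifnot(
    n >= 1L, length(bin_end) == n, length(p1_given_0) == n,
    length(p1_given_1) == n
  )
  if (any(bin_end <= bin_start)) abort("bin_end must exceed bin_start")
  if (n > 1 && !all(bin_start[-1] == bin_end[-n])) {
    abort("distance bins must be contiguous")
  }
  if (is.unsorted(bin_end, strictly = TRUE)) {
    abort("bin edges must be strictly increasing")
  }
  p <- c(p1_given_0, p1_given_1)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("transition probabilities must lie in [0, 1]")
  }
  out <- tibble(
    bin_start = as.integer(bin_start), bin_end = as.integer(bin_end),
    p1_given_0 = as.numeric(p1_given_0), p1_given_1 = as.numeric(p1_given_1)
  )
  class(out) <- c("transition_table", class(out))
  out
}

#' Beta-binomial / zero-inflated beta-binomial emission parameters
#'
#' Emission priors of the HMM: under a methylated hidden state the
#' methylated cell count at a site follows a beta-binomial with shape
#' `(alpha_m, beta_m)`; under an unmethylated state it follows a
#' zero-inflated beta-binomial with shapes `(alpha_u, beta_u)` and extra
#' point mass `w0_u` at zero, capturing the excess of fully unobserved
#' methylation at unmethylated CpGs in single-cell data.
#'
#' @param alpha_m,beta_m Positive shapes of the methylated-state beta prior.
#' @param alpha_u,beta_u Positive shapes of the unmethylated-state beta prior.
#' @param w0_u Zero-inflation probability in \[0, 1\].
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(alpha_m, beta_m, alpha_u, beta_u, w0_u) {
  vals <- c(alpha_m, beta_m, alpha_u, beta_u)
  if (length(vals) != 4L || any(!is.finite(vals) | vals <= 0)) {
    abort("beta shape parameters must be positive finite scalars")
  }
  if (length(w0_u) != 1L || !is.finite(w0_u) || w0_u < 0 || w0_u > 1) {
    abort("w0_u must lie in [0, 1]")
  }
  structure(
    list(
      alpha_m = as.numeric(alpha_m), beta_m = as.numeric(beta_m),
      alpha_u = as.numeric(alpha_u), beta_u = as.numeric(beta_u),
      w0_u = as.numeric(w0_u)
    ),
    class = "emission_params"
  )
}

#' @export
print.emission_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<emission_params> methylated BB(%.3g, %.3g) [mean %.3f], ",
      "unmethylated ZIBB(%.3g, %.3g, w0 = %.3g) [beta mean %.3f]\n"
    ),
    x$alpha_m, x$beta_m, x$alpha_m / (x$alpha_m + x$beta_m),
    x$alpha_u, x$beta_u, x$w0_u, x$alpha_u / (x$alpha_u + x$beta_u)
  ))
  invisible(x)
}

#' Default parameter tables
#'
#' Shipped defaults used when no trained tables are supplied. The transition
#' probability toward the methylated state follows an exponential approach to
#' a plateau, `P(1 | s_prev, d) = p_inf + (1{s_prev = 1} - p_inf) *
#' exp(-d / lambda)` with `p_inf = 0.8` (matching the roughly 80% global CpG
#' methylation typical of mammalian tissues) and decay scale `lambda = 700`
#' bp, tabulated in 20-bp bins up to 2000 bp and a plateau beyond. The
#' emission defaults put the methylated beta prior mean at 0.95
#' (`BB(19, 1)`) and the unmethylated at 0.05 (`ZIBB(1, 19)`) with
#' zero-inflation 0.3. All of these are configuration, not ground truth, and
#' can be replaced by tables trained with [estimate_transition_table()] and
#' [estimate_emission_priors()].
#'
#' @param p_inf Plateau probability of the methylated state.
#' @param lambda_bp Exponential decay scale in bp.
#' @param bin_width_bp,max_bp Tabulation grid.
#' @return `default_transition_table()`: a [transition_table()];
#'   `default_emission_params()`: an [emission_params()].
#' @export
default_transition_table <- function(p_inf = 0.8, lambda_bp = 700,
                                     bin_width_bp = 20, max_bp = 2000) {
  bin_start <- seq(0L, max_bp - bin_width_bp, by = bin_width_bp)
  bin_end <- bin_start + bin_width_bp
  mid <- (bin_start + bin_end) / 2
  transition_table(
    bin_start = bin_start, bin_end = bin_end,
    p1_given_0 = p_inf + (0 - p_inf) * exp(-mid / lambda_bp),
    p1_given_1 = p_inf + (1 - p_inf) * exp(-mid / lambda_bp)
  )
}

#' @rdname default_transition_table
#' @export
default_emission_params <- function() {
  emission_params(
    alpha_m = 19, beta_m = 1, alpha_u = 1, beta_u = 19,
    w0_u = 0.3
  )
}

#' Look up transition probabilities for given distances
#'
#' Returns `P(s = 1 | s_prev, d)` for each distance; distances beyond the
#' last bin take the plateau (final-row) values.
#'
#' @param table A [transition_table()].
#' @param s_prev Previous hidden state, 0 or 1 (scalar or vector).
#' @param s Target hidden state, 0 or 1 (scalar or vector).
#' @param d Positive distances in bp.
#' @return Probability vector, recycled to the common length.
#' @export
transition_prob <- function(table, s_prev, s, d) {
  if (any(d <= 0)) abort("distances must be positive")
  if (!all(s_prev %in% c(0, 1)) || !all(s %in% c(0, 1))) {
    abort("states must be 0 or 1")
  }
  p <- trans_p1(table, d)
  p1 <- ifelse(s_prev == 1, p$p1_given_1, p$p1_given_0)
  ifelse(s == 1, p1, 1 - p1)
}

# internal: vectorized bin lookup, returns list(p1_given_0, p1_given_1)
trans_p1 <- function(table, d) {
  idx <- findInterval(d, c(table$bin_start[1], table$bin_end),
    left.open = TRUE
  )
  idx[idx < 1L] <- 1L # distances at/below the first edge use the first bin
  idx[idx > nrow(table)] <- nrow(table) # plateau
  list(
    p1_given_0 = table$p1_given_0[idx],
    p1_given_1 = table$p1_given_1[idx]
  )
}
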