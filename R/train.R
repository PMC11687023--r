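#' Pseudo-bulk site summaries per annotated subtype
#'
#' Aggregates the cells of each annotated subtype into one pseudo-bulk
#' sample; within a subtype the cells are treated as homogeneous, so the
#' per-site (m, n) counts of a pseudo-bulk approximate draws from a single
#' hidden-state chain and can be used to train the transition and emission
#' tables.
#'
#' @param mat A binarized [meth_mat()].
#' @param labels Subtype label per cell: either a vector aligned with
#'   `mat$cell_ids` or a named vector keyed by cell id. Every cell must be
#'   labeled and every label level non-empty.
#' @return Tibble with one row per (subtype, site): `subtype`, `site`,
#'   `pos`, `m`, `n`, `mean_meth` (rows with `n = 0` are dropped).
#' @export
pseudo_bulk <- function(mat, labels) {
  C <- length(mat$cell_ids)
  if (!is.null(names(labels))) {
    if (!all(mat$cell_ids %in% names(labels))) {
      missing_ids <- setdiff(mat$cell_ids, names(labels))
      abort(sprintf("unlabeled cell(s): %s", paste(
        head(missing_ids, 3),
        collapse = ", "
      )))
    }
    labels <- labels[mat$cell_ids]
  }
  if (length(labels) != C || anyNA(labels)) {
    abort("every cell must carry a subtype label")
  }
  labels <- as.character(labels)
  tibble(
    subtype = labels[mat_cell(mat)],
    site = mat_site(mat),
    value = mat_value(mat)
  ) |>
    group_by(.data$subtype, .data$site) |>
    summarise(m = sum(.data$value), n = n(), .groups = "drop") |>
    mutate(
      pos = .env$mat$pos[.data$site],
      m = as.integer(.data$m),
      mean_meth = .data$m / .data$n
    ) |>
    select("subtype", "site", "pos", "m", "n", "mean_meth") |>
    arrange(.data$subtype, .data$site)
}

#' Estimate the distance-binned transition table from pseudo-bulks
#'
#' Each pseudo-bulk site is called methylated when its mean methylation is
#' at or above `state_call_threshold`; state pairs of adjacent sites are
#' tallied into distance bins pooled across pseudo-bulks, and the table
#' entries are the add-one-smoothed conditional frequencies
#' `P(s = 1 | s_prev, bin)`. Pairs beyond the last break fall into the
#' final (plateau) bin. A bin with no observed pairs from a given previous
#' state inherits the neighboring bin's value, with a warning.
#'
#' @param pb Pseudo-bulk tibble from [pseudo_bulk()].
#' @param distance_breaks Increasing break points in bp defining the bins
#'   `(b[i], b[i+1]]`; the final bin is the plateau.
#' @param state_call_threshold Mean-methylation cutoff for calling a site
#'   methylated (default 0.5, inclusive).
#' @return A [transition_table()]. Attribute `pair_counts` carries the raw
#'   per-bin tallies.
#' @export
estimate_transition_table <- function(pb,
                                      distance_breaks = c(
                                        0, 40, 80, 120, 160, 200, 300, 400,
                                        600, 1000, 2000
                                      ),
                                      state_call_threshold = 0.5) {
  stopifnot(length(distance_breaks) >= 2)
  if (is.unsorted(distance_breaks, strictly = TRUE)) {
    abort("distance breaks must be strictly increasing")
  }
  n_bins <- length(distance_breaks) - 1L
  counts <- array(0, dim = c(n_bins, 2, 2)) # bin x s_prev x s
  for (sub in split(pb, pb$subtype)) {
    if (nrow(sub) < 2) abort("each pseudo-bulk needs at least 2 sites")
    s <- as.integer(sub$mean_meth >= state_call_threshold)
    d <- diff(sub$pos)
    bin <- findInterval(d, distance_breaks, left.open = TRUE)
    bin[bin < 1L] <- 1L
    bin[bin > n_bins] <- n_bins # plateau bin absorbs long distances
    sp <- s[-length(s)] + 1L
    sc <- s[-1] + 1L
    for (p in 1:2) {
      for (q in 1:2) {
        t <- tabulate(bin[sp == p & sc == q], nbins = n_bins)
        counts[, p, q] <- counts[, p, q] + t
      }
    }
  }
  p1 <- matrix(NA_real_, n_bins, 2)
  for (p in 1:2) {
    tot <- counts[, p, 1] + counts[, p, 2]
    p1[, p] <- (counts[, p, 2] + 1) / (tot + 2) # add-one smoothing
    empty <- tot == 0
    if (any(empty)) {
      warn(sprintf(
        "%d empty distance bin(s) for previous state %d; inheriting neighbors",
        sum(empty), p - 1L
      ))
      filled <- which(!empty)
      if (length(filled) > 0L) {
        nearest <- vapply(
          which(empty),
          function(b) filled[which.min(abs(filled - b))], 1L
        )
        p1[empty, p] <- p1[nearest, p]
      }
      # a previous state never observed keeps the uninformative
      # add-one value 1/2 in every bin
    }
  }
  out <- transition_table(
    bin_start = distance_breaks[-length(distance_breaks)],
    bin_end = distance_breaks[-1],
    p1_given_0 = p1[, 1], p1_given_1 = p1[, 2]
  )
  attr(out, "pair_counts") <- counts
  out
}

# method-of-moments beta-binomial fit on (m, n) pairs with unequal n;
# returns list(alpha, beta, mu, rho)
fit_bb_moments <- function(m, n, mu = NULL, s2 = NULL) {
  f <- m / n
  mu <- mu %||% mean(f)
  s2 <- s2 %||% mean((f - mu)^2)
  if (mu <= 0 || mu >= 1) abort("degenerate mean methylation fraction")
  if (s2 <= 1e-12) {
    abort("degenerate variance: all fractions identical; need more sites")
  }
  a1 <- mean(1 / n)
  a2 <- mean((n - 1) / n)
  rho <- (s2 / (mu * (1 - mu)) - a1) / a2
  rho <- min(max(rho, 1e-4), 1 - 1e-4)
  list(
    alpha = mu * (1 - rho) / rho, beta = (1 - mu) * (1 - rho) / rho,
    mu = mu, rho = rho
  )
}

#' Estimate emission priors from pseudo-bulks
#'
#' Sites are partitioned by called state (mean methylation at or above
#' `state_call_threshold` = methylated). The methylated-state beta prior is
#' fit by the method of moments on the beta-binomial. For the unmethylated
#' state, the zero-inflation weight is estimated as the excess of
#' exact-zero counts over the beta-binomial-implied zero mass, and the beta
#' shapes are refit on zero-inflation-adjusted moments; weight and shapes
#' are alternated to a fixed point.
#'
#' @param pb Pseudo-bulk tibble from [pseudo_bulk()].
#' @param state_call_threshold Mean-methylation cutoff (default 0.5).
#' @param max_iter Maximum fixed-point iterations for the zero-inflation
#'   fit.
#' @return An [emission_params()].
#' @export
estimate_emission_priors <- function(pb, state_call_threshold = 0.5,
                                     max_iter = 50L) {
  is_m <- pb$mean_meth >= state_call_threshold
  if (!any(is_m) || all(is_m)) {
    abort("both called states must be represented among the sites")
  }
  mm <- pb$m[is_m]
  nm <- pb$n[is_m]
  fm <- fit_bb_moments(mm, nm)

  mu_ <- pb$m[!is_m]
  nu_ <- pb$n[!is_m]
  f <- mu_ / nu_
  p0_obs <- mean(mu_ == 0)
  mu_obs <- mean(f)
  m2_obs <- mean(f^2)
  fit <- fit_bb_moments(mu_, nu_) # w0 = 0 start
  w0 <- 0
  for (it in seq_len(max_iter)) {
    z <- mean(bb_pmf(0L, nu_, fit$alpha, fit$beta))
    w0_new <- min(max((p0_obs - z) / (1 - z), 0), 0.95)
    mu_bb <- min(mu_obs / (1 - w0_new), 0.999)
    s2_bb <- max(m2_obs / (1 - w0_new) - mu_bb^2, 1e-10)
    fit <- fit_bb_moments(mu_, nu_, mu = mu_bb, s2 = s2_bb)
    if (abs(w0_new - w0) < 1e-6) {
      w0 <- w0_new
      break
    }
    w0 <- w0_new
  }
  emission_params(
    alpha_m = fm$alpha, beta_m = fm$beta,
    alpha_u = fit$alpha, beta_u = fit$beta, w0_u = w0
  )
}
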