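#' Relative methylation per observed entry
#'
#' Centers each observed binary value by its site's across-cell mean, giving
#' the "relative" methylation `x* = x - mean(x at site)`. Smoothing operates
#' on these centered values so that methylation-state transitions shared by
#' the whole population do not create spurious intermediate values.
#'
#' @param mat A binarized [meth_mat()].
#' @param summaries Output of [site_summaries()] for `mat` (computed if
#'   missing).
#' @return A tibble with one row per observed entry: `site`, `cell`, `rel`.
#' @export
relative_methylation <- function(mat, summaries = NULL) {
  summaries <- summaries %||% site_summaries(mat)
  tibble(
    site = mat_site(mat), cell = mat_cell(mat),
    rel = mat_value(mat) - summaries$mean_meth[mat_site(mat)]
  )
}

# box-kernel running mean over a +/- half_bw window for one cell
smooth_one_cell <- function(pos_obs, x, half_bw) {
  cs <- c(0, cumsum(x))
  hi <- findInterval(pos_obs + half_bw, pos_obs)
  lo <- findInterval(pos_obs - half_bw - 0.5, pos_obs) + 1L
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Box-kernel smoothing of relative methylation, per cell
#'
#' For every cell, each observed relative value is replaced by the mean of
#' that cell's observed relative values at positions within
#' `pos +/- bandwidth_bp / 2` (a box kernel; the bandwidth is the total
#' window width). Values are computed only at sites the cell itself covers,
#' so the missingness pattern is preserved.
#'
#' @param rel Tibble from [relative_methylation()].
#' @param pos Site coordinates (the matrix's `pos` vector).
#' @param bandwidth_bp Total window width in bp (default 2000, matching the
#'   distance at which CpG-CpG methylation correlation plateaus).
#' @return `rel` with an added column `smooth`.
#' @export
smooth_cells <- function(rel, pos, bandwidth_bp = 2000) {
  half_bw <- bandwidth_bp / 2
  out <- numeric(nrow(rel))
  by_cell <- split.default(seq_len(nrow(rel)), rel$cell)
  for (ix in by_cell) {
    s <- rel$site[ix]
    o <- order(s)
    ixo <- ix[o]
    out[ixo] <- smooth_one_cell(pos[s[o]], rel$rel[ixo], half_bw)
  }
  rel$smooth <- out
  rel
}

#' Across-cell variance of smoothed relative methylation
#'
#' The per-site variance statistic: the sum of squared smoothed relative
#' values over covered cells, divided by `n - 1`. Sites covered by fewer
#' than 2 cells have no defined variance (`NA`) and can never enter a
#' candidate region.
#'
#' @param smoothed Tibble from [smooth_cells()].
#' @param summaries Output of [site_summaries()].
#' @return Numeric vector of variances, aligned with `summaries$site`.
#' @export
cross_cell_variance <- function(smoothed, summaries) {
  K <- nrow(summaries)
  ss <- numeric(K)
  agg <- rowsum(smoothed$smooth^2, smoothed$site)
  ss[as.integer(rownames(agg))] <- agg[, 1]
  ifelse(summaries$n >= 2, ss / (summaries$n - 1), NA_real_)
}

# draw beta-binomial counts
rbb <- function(k, n, alpha, beta) {
  rbinom(k, n, rbeta(k, alpha, beta))
}

# draw zero-inflated beta-binomial counts
rzibb <- function(k, n, alpha, beta, w0) {
  out <- rbb(k, n, alpha, beta)
  out[runif(k) < w0] <- 0L
  out
}

#' Null variance threshold by homogeneous simulation
#'
#' Builds the candidate-region variance threshold as the `1 - alpha`
#' quantile of an approximate null distribution of the variance statistic.
#' The null emulates a homogeneous cell population with the input's own
#' coverage structure: for `n_sim_sites` synthetic sites, the covered-cell
#' count and the inter-site spacing are resampled from the input's empirical
#' distributions, a single hidden methylation state per site is drawn as
#' Bernoulli(global mean methylation), methylated cell counts are drawn from
#' the corresponding emission component (beta-binomial if methylated,
#' zero-inflated beta-binomial if not) and assigned to randomly chosen
#' cells; the full stage-1 machinery (centering, smoothing, variance) is
#' then applied to the simulated sites.
#'
#' @param mat A binarized, filtered [meth_mat()].
#' @param emission An [emission_params()].
#' @param alpha Significance level in (0, 1); the threshold is the
#'   `1 - alpha` empirical quantile (default 0.05).
#' @param n_sim_sites Number of simulated null sites (default 1e5).
#' @param bandwidth_bp Smoothing bandwidth, as in [smooth_cells()].
#' @param summaries Optional precomputed [site_summaries()].
#' @param seed Optional integer seed; the result is deterministic given it.
#' @return The threshold (scalar). Attribute `null_variances` holds the
#'   simulated variance sample.
#' @export
null_variance_threshold <- function(mat, emission, alpha = 0.05,
                                    n_sim_sites = 1e5, bandwidth_bp = 2000,
                                    summaries = NULL, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie strictly between 0 and 1")
  }
  if (!is.null(seed)) set.seed(seed)
  summaries <- summaries %||% site_summaries(mat)
  C <- length(mat$cell_ids)
  n_sim_sites <- as.integer(n_sim_sites)
  emp_n <- summaries$n[summaries$n > 0]
  emp_gap <- if (length(mat$pos) > 1) diff(mat$pos) else 100L
  p_global <- mean(summaries$mean_meth, na.rm = TRUE)

  n_sim <- sample(emp_n, n_sim_sites, replace = TRUE)
  gaps <- sample(emp_gap, n_sim_sites - 1L, replace = TRUE)
  pos_sim <- cumsum(c(1L, gaps))
  s_sim <- rbinom(n_sim_sites, 1L, p_global)
  m_sim <- integer(n_sim_sites)
  im <- s_sim == 1L
  m_sim[im] <- rbb(sum(im), n_sim[im], emission$alpha_m, emission$beta_m)
  m_sim[!im] <- rzibb(
    sum(!im), n_sim[!im], emission$alpha_u, emission$beta_u, emission$w0_u
  )

  # random covered-cell sets; the first m of each (already random) set are
  # the methylated cells
  cells <- mapply(sample.int, rep.int(C, n_sim_sites), n_sim, SIMPLIFY = FALSE)
  site_vec <- rep.int(seq_len(n_sim_sites), n_sim)
  within <- sequence(n_sim)
  value <- as.numeric(within <= rep.int(m_sim, n_sim))

  f <- m_sim / n_sim
  rel <- tibble(
    site = site_vec, cell = unlist(cells, use.names = FALSE),
    rel = value - f[site_vec]
  )
  sm <- smooth_cells(rel, pos_sim, bandwidth_bp)
  summ_sim <- tibble(site = seq_len(n_sim_sites), n = n_sim)
  v <- cross_cell_variance(sm, summ_sim)
  v <- v[!is.na(v)]
  thr <- unname(quantile(v, 1 - alpha))
  attr(thr, "null_variances") <- v
  thr
}

#' Segment candidate regions from the variance track
#'
#' Candidate regions (CRs) are maximal runs of consecutive retained CpG
#' sites whose variance exceeds the threshold, split wherever the distance
#' between two adjacent sites exceeds `max_gap_bp`; runs with fewer than
#' `min_cr_cpgs` sites are discarded.
#'
#' @param variance Per-site variance vector (NA allowed), aligned with `pos`.
#' @param pos Site coordinates.
#' @param threshold Variance threshold from [null_variance_threshold()].
#' @param min_cr_cpgs Minimum CpG count per CR (default 5).
#' @param max_gap_bp Maximum distance between adjacent CpGs within a CR
#'   (default 2000).
#' @param chrom Optional chromosome label carried into the output.
#' @return A tibble of CRs sorted by position: `cr_id`, `chrom`,
#'   `start_idx`, `end_idx`, `start_pos`, `end_pos`, `n_cpgs`.
#' @export
segment_candidate_regions <- function(variance, pos, threshold,
                                      min_cr_cpgs = 5L, max_gap_bp = 2000,
                                      chrom = NA_character_) {
  stopifnot(length(variance) == length(pos))
  above <- which(!is.na(variance) & variance > threshold)
  empty <- tibble(
    cr_id = integer(), chrom = character(), start_idx = integer(),
    end_idx = integer(), start_pos = integer(), end_pos = integer(),
    n_cpgs = integer()
  )
  if (length(above) == 0L) {
    return(empty)
  }
  new_run <- c(
    TRUE,
    diff(above) > 1L | diff(pos[above]) > max_gap_bp
  )
  idx_new <- which(new_run)
  starts <- above[idx_new]
  ends <- above[c(idx_new[-1] - 1L, length(above))]
  len <- ends - starts + 1L
  keep <- len >= min_cr_cpgs
  if (!any(keep)) {
    return(empty)
  }
  tibble(
    cr_id = seq_len(sum(keep)),
    chrom = chrom,
    start_idx = starts[keep], end_idx = ends[keep],
    start_pos = pos[starts[keep]], end_pos = pos[ends[keep]],
    n_cpgs = len[keep]
  )
}
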