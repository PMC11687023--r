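#' Extract the VMR (if any) from a candidate region's fitted models
#'
#' A candidate region contains a VMR only when the two-grouping model
#' attains a strictly higher maximum likelihood than the one-grouping model.
#' In that case the VMR is built from the maximal runs of sites decoded in
#' the mixed state `(0,1)`: runs shorter than `min_vmr_cpgs` are ignored,
#' sites decoded `(0,0)` or `(1,1)` at the edges are trimmed off, and if
#' several qualifying runs remain they are merged into a single VMR
#' spanning from the first run's start to the last run's end (one VMR per
#' CR, consistent with the U/M-grouping assumption).
#'
#' @param cr One-row tibble describing the candidate region (needs
#'   `cr_id`, `chrom`, `start_idx`, and the site coordinates used below).
#' @param one_fit,two_fit `hmm_fit` objects from [fit_one_group()] and
#'   [fit_two_group()] on the same sites.
#' @param min_vmr_cpgs Minimum `(0,1)` run length (default 5).
#' @param merge Merge multiple qualifying runs into one VMR (default TRUE;
#'   `FALSE` reports each run separately, for diagnostics).
#' @param trim Trim non-(0,1) edges (default TRUE; `FALSE` spans the whole
#'   CR, for diagnostics).
#' @param score Model score used for the comparison: `"viterbi"` (max-path
#'   joint log likelihood, default) or `"forward"` (marginal likelihood).
#' @return A tibble with 0 or 1 row (`merge = TRUE`) or 0+ rows
#'   (`merge = FALSE`): `chrom`, `cr_id`, `start_idx`, `end_idx`,
#'   `start_pos`, `end_pos`, `n_cpgs`, `loglik_increment`, `pi0_hat`,
#'   `pi1_hat`.
#' @export
call_vmrs <- function(cr, one_fit, two_fit, min_vmr_cpgs = 5L,
                      merge = TRUE, trim = TRUE,
                      score = c("viterbi", "forward")) {
  score <- match.arg(score)
  s1 <- if (score == "viterbi") one_fit$log_score else one_fit$log_marginal
  s2 <- if (score == "viterbi") two_fit$log_score else two_fit$log_marginal
  empty <- empty_vmr_tbl()
  if (s2 <= s1) {
    return(empty)
  }
  mixed <- two_fit$state_code == 2L
  r <- rle(mixed)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_vmr_cpgs)
  if (length(qual) == 0L) {
    return(empty)
  }
  spans <- if (merge) {
    cbind(run_start[qual[1]], run_end[qual[length(qual)]])
  } else {
    cbind(run_start[qual], run_end[qual])
  }
  if (!trim) spans <- cbind(1L, length(two_fit$m))
  offset <- cr$start_idx - 1L
  tibble(
    chrom = cr$chrom,
    cr_id = cr$cr_id,
    start_idx = offset + spans[, 1], end_idx = offset + spans[, 2],
    start_pos = two_fit$pos[spans[, 1]], end_pos = two_fit$pos[spans[, 2]],
    n_cpgs = spans[, 2] - spans[, 1] + 1L,
    loglik_increment = s2 - s1,
    pi0_hat = two_fit$pi_hat[1], pi1_hat = two_fit$pi_hat[2]
  )
}

empty_vmr_tbl <- function() {
  tibble(
    chrom = character(), cr_id = integer(), start_idx = integer(),
    end_idx = integer(), start_pos = integer(), end_pos = integer(),
    n_cpgs = integer(), loglik_increment = numeric(),
    pi0_hat = numeric(), pi1_hat = numeric()
  )
}

#' Rank VMRs by log-likelihood increment
#'
#' Orders VMRs by decreasing increment of the two-grouping over the
#' one-grouping log likelihood (a larger increment = stronger evidence of
#' two methylation groupings); ties are broken by genomic position so the
#' ranking is a deterministic total order.
#'
#' @param vmrs Tibble of VMRs with `loglik_increment`, `chrom`, `start_pos`.
#' @return The tibble, sorted, with a `rank` column.
#' @export
rank_vmrs <- function(vmrs) {
  vmrs <- as_tibble(vmrs)
  if (nrow(vmrs) == 0L) {
    vmrs$rank <- integer(0)
    return(vmrs)
  }
  ord <- order(-vmrs$loglik_increment, vmrs$chrom, vmrs$start_pos)
  vmrs <- vmrs[ord, ]
  vmrs$rank <- seq_len(nrow(vmrs))
  vmrs
}

#' Detect variably methylated regions in a methylation matrix
#'
#' Runs the full two-stage scan on one chromosome: intermediate-value
#' removal (if the input still holds fractions), low-coverage site
#' filtering, per-cell smoothing of relative methylation, construction of
#' the null variance threshold, candidate-region segmentation, and per-CR
#' decoding of the one- and two-grouping HMMs with prevalence estimation;
#' VMRs are extracted, merged and ranked. Candidate regions are processed
#' independently. The run is deterministic given `seed`.
#'
#' @param mat A [meth_mat()].
#' @param transition A [transition_table()] (default
#'   [default_transition_table()]).
#' @param emission An [emission_params()] (default
#'   [default_emission_params()]).
#' @param alpha Variance-threshold significance level (default 0.05).
#' @param bandwidth_bp Smoothing bandwidth (default 2000).
#' @param min_cells Minimum covered cells per retained site (default 3).
#' @param min_cr_cpgs,min_vmr_cpgs Minimum CpG counts (defaults 5).
#' @param max_gap_bp Maximum adjacent-CpG distance within a CR (default
#'   2000).
#' @param null_sim_sites Null-simulation size for the threshold (default
#'   1e5).
#' @param pi_inits,eta,tol,max_iter Two-grouping optimizer controls, see
#'   [fit_two_group()].
#' @param score Model-comparison score, see [call_vmrs()].
#' @param seed Integer seed for the null simulation.
#' @param threshold Optional precomputed variance threshold (skips the null
#'   simulation).
#' @param verbose Print per-stage progress.
#' @return An object of class `vmr_scan`: a list with `vmr` (ranked VMR
#'   tibble), `cr` (candidate-region tibble), `variance` (per-site variance
#'   track), `threshold`, `cr_fits` (per-CR diagnostics tibble) and
#'   `report` (stage-by-stage counts and settings).
#' @export
detect_vmrs <- function(mat,
                        transition = default_transition_table(),
                        emission = default_emission_params(),
                        alpha = 0.05, bandwidth_bp = 2000,
                        min_cells = 3L, min_cr_cpgs = 5L, min_vmr_cpgs = 5L,
                        max_gap_bp = 2000, null_sim_sites = 1e5,
                        pi_inits = c(0.2, 0.5, 0.8), eta = 0.05, tol = 1e-4,
                        max_iter = 100L, score = c("viterbi", "forward"),
                        seed = NULL, threshold = NULL, verbose = FALSE) {
  score <- match.arg(score)
  n_sites_input <- length(mat$pos)
  if (any(!mat_value(mat) %in% c(0, 1))) {
    mat <- filter_intermediate_values(mat)
  }
  mat <- filter_low_coverage_sites(mat, min_cells = min_cells)
  summ <- site_summaries(mat)
  if (verbose) {
    inform(sprintf(
      "retained %d / %d sites after filtering", nrow(summ), n_sites_input
    ))
  }
  rel <- relative_methylation(mat, summ)
  sm <- smooth_cells(rel, mat$pos, bandwidth_bp)
  variance <- cross_cell_variance(sm, summ)
  if (is.null(threshold)) {
    threshold <- null_variance_threshold(
      mat, emission,
      alpha = alpha, n_sim_sites = null_sim_sites,
      bandwidth_bp = bandwidth_bp, summaries = summ, seed = seed
    )
  }
  threshold <- as.numeric(threshold[1])
  cr <- segment_candidate_regions(
    variance, mat$pos, threshold,
    min_cr_cpgs = min_cr_cpgs, max_gap_bp = max_gap_bp, chrom = mat$chrom
  )
  if (verbose) inform(sprintf("%d candidate region(s)", nrow(cr)))

  vmr_list <- vector("list", nrow(cr))
  fit_rows <- vector("list", nrow(cr))
  for (r in seq_len(nrow(cr))) {
    idx <- cr$start_idx[r]:cr$end_idx[r]
    m <- summ$m[idx]
    n <- summ$n[idx]
    p <- summ$pos[idx]
    one <- fit_one_group(m, n, p, transition, emission)
    two <- fit_two_group(m, n, p, transition, emission,
      pi_inits = pi_inits, eta = eta, tol = tol, max_iter = max_iter
    )
    vmr_list[[r]] <- call_vmrs(cr[r, ], one, two,
      min_vmr_cpgs = min_vmr_cpgs, score = score
    )
    fit_rows[[r]] <- tibble(
      cr_id = cr$cr_id[r], n_cpgs = length(idx),
      one_log_score = one$log_score, two_log_score = two$log_score,
      loglik_increment = two$log_score - one$log_score,
      pi0_hat = two$pi_hat[1],
      converged = any(two$per_init$converged)
    )
  }
  vmr <- bind_rows(vmr_list)
  if (nrow(vmr) == 0L) vmr <- empty_vmr_tbl()
  vmr <- rank_vmrs(vmr)
  res <- structure(
    list(
      vmr = vmr, cr = cr,
      variance = tibble(
        site = summ$site, pos = summ$pos, n = summ$n, variance = variance
      ),
      threshold = threshold,
      cr_fits = bind_rows(fit_rows),
      report = list(
        chrom = mat$chrom, n_cells = length(mat$cell_ids),
        n_sites_input = n_sites_input, n_sites_retained = nrow(summ),
        n_crs = nrow(cr), n_vmrs = nrow(vmr),
        n_cpgs_in_crs = sum(cr$n_cpgs), n_cpgs_in_vmrs = sum(vmr$n_cpgs),
        alpha = alpha, threshold = threshold, bandwidth_bp = bandwidth_bp,
        min_cells = min_cells, min_cr_cpgs = min_cr_cpgs,
        min_vmr_cpgs = min_vmr_cpgs, max_gap_bp = max_gap_bp,
        null_sim_sites = null_sim_sites, score = score, seed = seed
      )
    ),
    class = "vmr_scan"
  )
  if (verbose) inform(sprintf("%d VMR(s) called", nrow(vmr)))
  res
}

#' @export
print.vmr_scan <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<vmr_scan> %s: %d cells, %d sites -> %d CRs -> %d VMRs (alpha = %g, threshold = %.4g)\n",
    r$chrom, r$n_cells, r$n_sites_retained, r$n_crs, r$n_vmrs, r$alpha,
    r$threshold
  ))
  invisible(x)
}

#' Tidy a VMR scan: the ranked VMR table
#'
#' @param x A `vmr_scan`.
#' @param ... Unused.
#' @return The ranked VMR tibble.
#' @export
tidy.vmr_scan <- function(x, ...) x$vmr

#' One-row summary of a VMR scan
#'
#' @param x A `vmr_scan`.
#' @param ... Unused.
#' @return One-row tibble with cell/site/CR/VMR counts and the threshold.
#' @export
glance.vmr_scan <- function(x, ...) {
  r <- x$report
  tibble(
    chrom = r$chrom, n_cells = r$n_cells,
    n_sites = r$n_sites_retained, n_crs = r$n_crs, n_vmrs = r$n_vmrs,
    n_cpgs_in_vmrs = r$n_cpgs_in_vmrs, alpha = r$alpha,
    threshold = r$threshold
  )
}

#' Plot the variance track with candidate regions and VMRs
#'
#' @param object A `vmr_scan`.
#' @param ... Unused.
#' @return A ggplot: per-site smoothed-variance track, the null threshold,
#'   and shaded candidate-region (grey) and VMR (red) spans.
#' @export
autoplot.vmr_scan <- function(object, ...) {
  v <- object$variance
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$pos, y = .data$variance)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_hline(
      yintercept = object$threshold, linetype = "dashed", colour = "blue"
    ) +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", object$report$chrom),
      y = "across-cell variance of smoothed relative methylation"
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$cr)) {
    p <- p + ggplot2::geom_rect(
      data = object$cr,
      ggplot2::aes(
        xmin = .data$start_pos, xmax = .data$end_pos,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "grey70", alpha = 0.3
    )
  }
  if (nrow(object$vmr)) {
    p <- p + ggplot2::geom_rect(
      data = object$vmr,
      ggplot2::aes(
        xmin = .data$start_pos, xmax = .data$end_pos,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "red", alpha = 0.25
    )
  }
  p
}
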