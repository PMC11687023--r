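#' Remove intermediate methylation values
#'
#' Single-cell bisulfite calls are expected to be binary per cell; fractions
#' strictly between 0 and 1 arise from hemimethylation or technical error at
#' the small minority of sites covered by several reads, and are removed per
#' cell before any modelling. Comparison against 0/1 uses a tolerance of
#' 1e-9 to absorb float noise from text parsing.
#'
#' @param mat A [meth_mat()] whose values are fractions in \[0, 1\].
#' @param tol Tolerance for exact-0/1 comparison.
#' @return A binarized [meth_mat()] (values exactly 0 or 1). The attribute
#'   `filter_log` holds a tibble with the per-cell removed fraction.
#' @export
filter_intermediate_values <- function(mat, tol = 1e-9) {
  v <- mat_value(mat)
  is0 <- abs(v) <= tol
  is1 <- abs(v - 1) <= tol
  keep <- is0 | is1
  removed <- tibble(cell = mat_cell(mat), removed = !keep) |>
    group_by(.data$cell) |>
    summarise(
      n_sites = n(), n_removed = sum(.data$removed),
      removed_fraction = mean(.data$removed)
    ) |>
    ungroup()
  entries <- mat$entries[keep, ]
  entries$value <- as.numeric(abs(entries$value - 1) <= tol)
  out <- meth_mat(mat$chrom, mat$pos, mat$cell_ids, entries)
  attr(out, "filter_log") <- removed
  out
}

#' Drop CpG sites covered by too few cells
#'
#' Sites observed in fewer than `min_cells` cells carry too little
#' information for across-cell variance or emission modelling and are
#' removed before analysis; remaining sites are re-indexed and inter-site
#' distances are computed on the retained set only.
#'
#' @param mat A binarized [meth_mat()].
#' @param min_cells Minimum number of covered cells per retained site
#'   (default 3).
#' @return A [meth_mat()] with low-coverage sites removed. Attribute
#'   `original_pos` keeps the pre-filter coordinates; `n_dropped_sites` the
#'   count removed.
#' @export
filter_low_coverage_sites <- function(mat, min_cells = 3L) {
  ncov <- tabulate(mat_site(mat), nbins = length(mat$pos))
  keep <- which(ncov >= min_cells)
  if (length(keep) == 0L) {
    abort(sprintf(
      "all %d sites have coverage below min_cells = %d; consider lowering the threshold",
      length(mat$pos), min_cells
    ))
  }
  sel <- mat_site(mat) %in% keep
  entries <- mat$entries[sel, ]
  entries$site <- match(entries$site, keep)
  out <- meth_mat(mat$chrom, mat$pos[keep], mat$cell_ids, entries)
  attr(out, "original_pos") <- mat$pos
  attr(out, "n_dropped_sites") <- length(mat$pos) - length(keep)
  out
}

#' Per-site methylated and covered cell counts
#'
#' Computes, for every retained CpG site, the methylated cell count `m`, the
#' covered cell count `n` and the mean methylation `m / n` (`NA` when
#' `n = 0`).
#'
#' @param mat A binarized [meth_mat()].
#' @return A tibble with one row per site: `site`, `pos`, `m`, `n`,
#'   `mean_meth`.
#' @export
site_summaries <- function(mat) {
  K <- length(mat$pos)
  n <- tabulate(mat_site(mat), nbins = K)
  m <- numeric(K)
  agg <- rowsum(mat_value(mat), mat_site(mat))
  m[as.integer(rownames(agg))] <- agg[, 1]
  tibble(
    site = seq_len(K), pos = mat$pos, m = as.integer(round(m)),
    n = as.integer(n),
    mean_meth = ifelse(n > 0, m / n, NA_real_)
  )
}
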