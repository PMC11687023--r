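# number of CpG coordinates in `pos` falling inside [lo, hi]
n_sites_in <- function(pos, lo, hi) {
  if (hi < lo) {
    return(0L)
  }
  findInterval(hi, pos) - findInterval(lo - 0.5, pos)
}

#' Region-based detection accuracy
#'
#' A detected region counts as a true positive when it shares at least
#' `min_overlap_sites` CpGs with some truth region; a truth region counts
#' as recalled when some detected region overlaps it by at least that many
#' CpGs. Precision is the true-positive fraction of detected regions,
#' recall the recalled fraction of truth regions.
#'
#' @param detected,truth Tibbles of spans with `start_pos`, `end_pos`
#'   (1-based inclusive).
#' @param pos CpG coordinate universe used to count shared sites.
#' @param min_overlap_sites Minimum shared CpGs (default 3).
#' @return List: `tp`, `fp`, `fn`, `recalled`, `precision`, `recall`.
#' @export
region_match <- function(detected, truth, pos, min_overlap_sites = 3L) {
  nd <- nrow(detected)
  nt <- nrow(truth)
  ov <- matrix(0L, nd, nt)
  for (i in seq_len(nd)) {
    for (j in seq_len(nt)) {
      ov[i, j] <- n_sites_in(
        pos,
        max(detected$start_pos[i], truth$start_pos[j]),
        min(detected$end_pos[i], truth$end_pos[j])
      )
    }
  }
  hit <- ov >= min_overlap_sites
  tp <- if (nd) sum(apply(hit, 1, any)) else 0L
  recalled <- if (nt && nd) sum(apply(hit, 2, any)) else 0L
  list(
    tp = tp, fp = nd - tp, fn = nt - recalled, recalled = recalled,
    precision = if (nd) tp / nd else NA_real_,
    recall = if (nt) recalled / nt else NA_real_
  )
}

#' CpG-based detection accuracy
#'
#' Compares the sets of individual CpGs covered by detected versus truth
#' regions.
#'
#' @inheritParams region_match
#' @return List: `n_detected`, `n_truth`, `n_shared`, `precision`,
#'   `recall`.
#' @export
cpg_match <- function(detected, truth, pos) {
  in_spans <- function(spans) {
    sel <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(spans))) {
      sel <- sel | (pos >= spans$start_pos[i] & pos <= spans$end_pos[i])
    }
    sel
  }
  d <- in_spans(detected)
  t <- in_spans(truth)
  list(
    n_detected = sum(d), n_truth = sum(t), n_shared = sum(d & t),
    precision = if (any(d)) sum(d & t) / sum(d) else NA_real_,
    recall = if (any(t)) sum(d & t) / sum(t) else NA_real_
  )
}

#' F1 score
#'
#' Harmonic mean of precision and recall; 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @export
f1 <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
    2 * precision * recall / (precision + recall)
  )
}

#' Ratio of relative areas of a precision-recall curve
#'
#' Restricts the area under the precision-recall curve to the
#' high-precision band (default `0.8 <= precision <= 1`) and normalizes by
#' the band's own area, yielding a score in \[0, 1\] that emphasizes
#' performance under low-false-discovery conditions. The curve is taken
#' piecewise-linear in recall order; segments entering or leaving the band
#' are interpolated linearly at the crossing.
#'
#' @param points Tibble with columns `recall` and `precision` (one point
#'   per threshold setting; at least 2 points).
#' @param precision_band Length-2 band, default `c(0.8, 1)`.
#' @return RRA value in \[0, 1\].
#' @export
rra <- function(points, precision_band = c(0.8, 1)) {
  stopifnot(nrow(points) >= 2)
  lo <- precision_band[1]
  hi <- precision_band[2]
  pts <- points[order(points$recall), ] # stable: sweep order kept at ties
  r <- pts$recall
  p <- pmin(pts$precision, hi)
  area <- 0
  for (i in seq_len(length(r) - 1)) {
    r1 <- r[i]
    r2 <- r[i + 1]
    if (r2 <= r1) next
    p1 <- p[i]
    p2 <- p[i + 1]
    # subdivide at the band-bottom crossing, if any
    xs <- c(r1, r2)
    ys <- c(p1, p2)
    if ((p1 - lo) * (p2 - lo) < 0) {
      rc <- r1 + (r2 - r1) * (lo - p1) / (p2 - p1)
      xs <- c(r1, rc, r2)
      ys <- c(p1, lo, p2)
    }
    for (s in seq_len(length(xs) - 1)) {
      h1 <- max(ys[s] - lo, 0)
      h2 <- max(ys[s + 1] - lo, 0)
      area <- area + (xs[s + 1] - xs[s]) * (h1 + h2) / 2
    }
  }
  area / (hi - lo)
}

#' Region-by-cell mean methylation matrix
#'
#' Entry (r, c) is the mean of cell c's observed values over the CpGs of
#' region r, or `NA` when the cell observes no site there.
#'
#' @param mat A binarized [meth_mat()].
#' @param regions Sorted, non-overlapping spans with `start_pos`,
#'   `end_pos`.
#' @return A regions-by-cells numeric matrix with `NA` for unobserved
#'   pairs.
#' @export
regional_mean_matrix <- function(mat, regions) {
  R <- nrow(regions)
  C <- length(mat$cell_ids)
  if (R > 1 && any(regions$start_pos[-1] <= regions$end_pos[-R])) {
    abort("regions must be sorted and non-overlapping")
  }
  p <- mat$pos[mat_site(mat)]
  reg <- rep(NA_integer_, length(p))
  for (r in seq_len(R)) {
    reg[p >= regions$start_pos[r] & p <= regions$end_pos[r]] <- r
  }
  keep <- !is.na(reg)
  out <- matrix(NA_real_, R, C)
  if (any(keep)) {
    key <- (reg[keep] - 1L) * C + mat_cell(mat)[keep]
    sums <- rowsum(mat_value(mat)[keep], key)
    cnts <- rowsum(rep(1, sum(keep)), key)
    idx <- as.integer(rownames(sums))
    out[cbind((idx - 1L) %/% C + 1L, (idx - 1L) %% C + 1L)] <-
      sums[, 1] / cnts[, 1]
  }
  rownames(out) <- sprintf("region_%d", seq_len(R))
  colnames(out) <- mat$cell_ids
  out
}

#' Cell-to-cell Manhattan dissimilarity over regional methylation
#'
#' Pairwise Manhattan (L1) distances between regional mean-methylation
#' profiles, using only regions observed in both cells of a pair. By
#' default the sum is rescaled by `total regions / shared regions` so that
#' pairs sharing few regions remain comparable to well-covered pairs; set
#' `rescale = FALSE` for the raw pairwise-complete sum.
#'
#' @param regional Regions-by-cells matrix from [regional_mean_matrix()].
#' @param rescale Rescale by shared-region count (default TRUE).
#' @return Symmetric cells-by-cells dissimilarity matrix with zero
#'   diagonal.
#' @export
manhattan_dissimilarity <- function(regional, rescale = TRUE) {
  C <- ncol(regional)
  if (C < 2) abort("need at least 2 cells")
  R <- nrow(regional)
  obs <- !is.na(regional)
  x <- regional
  x[!obs] <- 0
  D <- matrix(0, C, C, dimnames = list(colnames(regional), colnames(regional)))
  for (c1 in seq_len(C - 1)) {
    idx <- (c1 + 1):C
    both <- obs[, c1] & obs[, idx, drop = FALSE]
    shared <- colSums(both)
    if (any(shared == 0)) {
      bad <- idx[which(shared == 0)[1]]
      abort(sprintf(
        "cells %s and %s share no observed region",
        colnames(regional)[c1] %||% c1, colnames(regional)[bad] %||% bad
      ))
    }
    dif <- abs(x[, c1] - x[, idx, drop = FALSE]) * both
    d <- colSums(dif)
    if (rescale) d <- d * R / shared
    D[c1, idx] <- d
    D[idx, c1] <- d
  }
  D
}

#' Nearest-neighbor count score
#'
#' For each cell, counts how many of its `g` nearest neighbors (by the
#' dissimilarity matrix, self excluded, distance ties broken by cell
#' index) share its label; a cell is well-assigned when that count exceeds
#' `theta * g`, and the score is the fraction of well-assigned cells.
#'
#' @param dissimilarity Symmetric cells-by-cells matrix.
#' @param labels Label per cell.
#' @param g Neighborhood size (default 100; must be < number of cells).
#' @param theta Well-assignment fraction threshold (default 0.7).
#' @return Score in \[0, 1\].
#' @export
nn_count_score <- function(dissimilarity, labels, g = 100L, theta = 0.7) {
  C <- ncol(dissimilarity)
  stopifnot(length(labels) == C)
  if (g >= C) abort("g must be smaller than the number of cells")
  well <- logical(C)
  for (c1 in seq_len(C)) {
    d <- dissimilarity[, c1]
    ord <- order(d, seq_len(C))
    ord <- ord[ord != c1][seq_len(g)]
    well[c1] <- sum(labels[ord] == labels[c1]) > theta * g
  }
  mean(well)
}
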