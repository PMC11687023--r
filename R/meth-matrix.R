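#' Sparse site-by-cell methylation container
#'
#' `meth_mat()` builds the central data structure of vmrscan: a sparse
#' site-by-cell matrix of per-cell methylation values on one chromosome,
#' stored in long (triplet) form. Only observed entries are stored; a CpG not
#' covered by a cell is simply absent. Values are methylation fractions in
#' \[0, 1\] on input and become strictly binary after
#' [filter_intermediate_values()].
#'
#' @param chrom Single chromosome name.
#' @param pos Integer vector of 1-based CpG coordinates, strictly increasing
#'   (length `K`).
#' @param cell_ids Character vector of cell identifiers (length `C`), in
#'   column order.
#' @param entries Tibble with integer columns `site` (index into `pos`),
#'   `cell` (index into `cell_ids`) and numeric `value` in \[0, 1\].
#'
#' @return An object of class `meth_mat`: a list with elements `chrom`,
#'   `pos`, `cell_ids` and `entries`.
#' @seealso [assemble_matrix()], [as_tibble.meth_mat()]
#' @export
meth_mat <- function(chrom, pos, cell_ids, entries) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  pos <- as.integer(pos)
  if (length(pos) < 1L) abort("`pos` must contain at least one CpG site.")
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("`pos` must be strictly increasing.")
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) < 1L) abort("need at least one cell")
  if (anyDuplicated(cell_ids)) abort("duplicated cell ids")
  entries <- as_tibble(entries)
  stopifnot(all(c("site", "cell", "value") %in% names(entries)))
  entries$site <- as.integer(entries$site)
  entries$cell <- as.integer(entries$cell)
  if (nrow(entries)) {
    if (min(entries$site) < 1L || max(entries$site) > length(pos)) {
      abort("entry site index out of range")
    }
    if (min(entries$cell) < 1L || max(entries$cell) > length(cell_ids)) {
      abort("entry cell index out of range")
    }
    if (anyDuplicated(entries[c("site", "cell")])) {
      abort("duplicated (site, cell) entries")
    }
    bad <- !is.finite(entries$value) | entries$value < 0 | entries$value > 1
    if (any(bad)) abort("entry values must be finite and within [0, 1]")
  }
  entries <- dplyr::arrange(entries, .data$site, .data$cell)
  structure(
    list(chrom = chrom, pos = pos, cell_ids = cell_ids, entries = entries),
    class = "meth_mat"
  )
}

#' @export
dim.meth_mat <- function(x) c(length(x$pos), length(x$cell_ids))

#' @export
print.meth_mat <- function(x, ...) {
  d <- dim(x)
  dens <- nrow(x$entries) / (d[1] * d[2])
  cat(sprintf(
    "<meth_mat> %s: %d CpG sites x %d cells, %d observed entries (%.1f%% dense)\n",
    x$chrom, d[1], d[2], nrow(x$entries), 100 * dens
  ))
  invisible(x)
}

#' Convert a methylation matrix to a long tibble
#'
#' @param x A [meth_mat()].
#' @param ... Unused.
#' @return A tibble with one row per observed entry: `chrom`, `pos`,
#'   `cell_id`, `value`.
#' @export
as_tibble.meth_mat <- function(x, ...) {
  tibble(
    chrom = x$chrom,
    pos = x$pos[x$entries$site],
    cell_id = x$cell_ids[x$entries$cell],
    value = x$entries$value
  )
}

#' Assemble per-cell methylomes into a site-by-cell matrix
#'
#' Takes per-cell CpG reports (as returned by [read_cell_coverage_file()], or
#' any tibble with `cell_id`, `chrom`, `pos`, `meth_fraction`) and assembles
#' the sparse site-by-cell matrix for one chromosome. Site coordinates are
#' the sorted union over cells; an entry is present iff that cell covers the
#' site. Values are kept as fractions; binarization happens later in
#' [filter_intermediate_values()].
#'
#' @param cells A single tibble of stacked per-cell records, or a list of
#'   such tibbles. Cell column order follows first appearance.
#' @param chrom Chromosome to assemble (records on other chromosomes are an
#'   error: callers are expected to split by chromosome first).
#' @return A [meth_mat()].
#' @export
assemble_matrix <- function(cells, chrom) {
  if (is.data.frame(cells)) cells <- list(cells)
  tab <- bind_rows(cells)
  stopifnot(all(c("cell_id", "chrom", "pos", "meth_fraction") %in% names(tab)))
  if (nrow(tab) == 0L) abort("no CpG records supplied")
  if (!all(tab$chrom == chrom)) {
    abort(sprintf("records found on chromosomes other than '%s'", chrom))
  }
  if (anyDuplicated(tab[c("cell_id", "pos")])) {
    abort("duplicated positions within one cell")
  }
  cell_ids <- unique(tab$cell_id)
  pos <- sort(unique(tab$pos))
  entries <- tibble(
    site = match(tab$pos, pos),
    cell = match(tab$cell_id, cell_ids),
    value = tab$meth_fraction
  )
  meth_mat(chrom, pos, cell_ids, entries)
}

# internal: observed-entry vectors without tibble overhead
mat_site <- function(mat) mat$entries$site
mat_cell <- function(mat) mat$entries$cell
mat_value <- function(mat) mat$entries$value
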