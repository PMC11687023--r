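#' Read a per-cell CpG coverage report
#'
#' Parses one cell's CpG methylation report. Two dialects are supported:
#' `bismark_cov` (tab- or space-separated: chrom, start, end, percent
#' methylation, count methylated, count unmethylated) and `bedgraph` (chrom,
#' start, end, value; 0-based half-open starts, value either a fraction in
#' \[0, 1\] or a percentage). Internal coordinates are 1-based inclusive;
#' bedGraph starts are shifted by +1, bismark coverage files are already
#' 1-based.
#'
#' Sites with zero total coverage are dropped (their count is reported in the
#' `dropped` attribute and via a message).
#'
#' @param path File path.
#' @param dialect `"bismark_cov"` or `"bedgraph"`.
#' @param cell_id Cell identifier; defaults to the file base name.
#' @return A tibble with columns `cell_id`, `chrom`, `pos`, `meth_fraction`
#'   and `coverage` (`NA` for bedGraph input), sorted by `chrom`, `pos`.
#' @export
read_cell_coverage_file <- function(path,
                                    dialect = c("bismark_cov", "bedgraph"),
                                    cell_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  cell_id <- cell_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty file: %s", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  want <- if (dialect == "bismark_cov") 6L else 4L
  bad <- which(nf != want)
  if (length(bad)) {
    abort(sprintf(
      "%s line %d: expected %d fields under dialect '%s', found %d",
      path, bad[1], want, dialect, nf[bad[1]]
    ))
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  chrom <- m[, 1]
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      abort(sprintf(
        "%s line %d: non-numeric %s field", path, which(is.na(v))[1], what
      ))
    }
    v
  }
  if (dialect == "bismark_cov") {
    pos <- num(2, "start")
    n_meth <- num(5, "count-methylated")
    n_unmeth <- num(6, "count-unmethylated")
    cov <- n_meth + n_unmeth
    drop <- cov == 0
    out <- tibble(
      cell_id = cell_id, chrom = chrom[!drop], pos = as.integer(pos[!drop]),
      meth_fraction = n_meth[!drop] / cov[!drop],
      coverage = as.integer(cov[!drop])
    )
  } else {
    start0 <- num(2, "start")
    val <- num(4, "value")
    if (any(val > 1)) val <- val / 100 # percent scale
    if (any(val < 0 | val > 1)) {
      abort(sprintf("%s: bedGraph values outside [0, 1] after rescaling", path))
    }
    drop <- rep(FALSE, length(val))
    out <- tibble(
      cell_id = cell_id, chrom = chrom, pos = as.integer(start0 + 1),
      meth_fraction = val, coverage = NA_integer_
    )
  }
  n_drop <- sum(drop)
  if (n_drop > 0) {
    inform(sprintf("%s: dropped %d zero-coverage site(s)", cell_id, n_drop))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "dropped") <- n_drop
  out
}

#' Write regions to BED with a companion statistics TSV
#'
#' Writes genomic spans as BED6 (0-based half-open; internal coordinates are
#' 1-based inclusive, so `start - 1` is written) with the rank statistic in
#' the score column, plus a companion TSV carrying all columns of `regions`.
#'
#' @param regions Tibble with at least `chrom`, `start_pos`, `end_pos`
#'   (1-based inclusive); optional `name`, `score` (defaults: `region_<i>`,
#'   `loglik_increment` if present, else 0).
#' @param path Output BED path.
#' @param tsv_path Companion TSV path; default: `path` with `.tsv` extension.
#' @return Invisibly, the tibble written to the TSV.
#' @export
write_regions_bed <- function(regions, path, tsv_path = NULL) {
  tsv_path <- tsv_path %||% sub("\\.bed$", ".tsv", path)
  if (identical(tsv_path, path)) tsv_path <- paste0(path, ".tsv")
  regions <- as_tibble(regions)
  if (nrow(regions)) {
    stopifnot(all(c("chrom", "start_pos", "end_pos") %in% names(regions)))
    ord <- order(regions$chrom, regions$start_pos)
    if (!identical(ord, seq_len(nrow(regions)))) {
      abort("regions must be sorted by chrom and start_pos")
    }
    same <- regions$chrom[-1] == regions$chrom[-nrow(regions)]
    if (nrow(regions) > 1 &&
        any(same & regions$start_pos[-1] <= regions$end_pos[-nrow(regions)])) {
      abort("regions must be non-overlapping")
    }
    name <- regions[["name"]] %||% sprintf("region_%d", seq_len(nrow(regions)))
    score <- regions[["score"]] %||% regions[["loglik_increment"]] %||%
      rep(0, nrow(regions))
    bed <- data.frame(
      chrom = regions$chrom,
      start = regions$start_pos - 1L,
      end = regions$end_pos,
      name = name,
      score = score,
      strand = "."
    )
    utils::write.table(bed, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  } else {
    file.create(path)
  }
  utils::write.table(regions, tsv_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(regions)
}

#' Read regions written by [write_regions_bed()]
#'
#' @param path BED path.
#' @return Tibble with `chrom`, `start_pos`, `end_pos` (1-based inclusive),
#'   `name`, `score`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble(
      chrom = character(), start_pos = integer(), end_pos = integer(),
      name = character(), score = numeric()
    ))
  }
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  tibble(
    chrom = d[[1]], start_pos = as.integer(d[[2]] + 1L),
    end_pos = as.integer(d[[3]]),
    name = if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_,
    score = if (ncol(d) >= 5) as.numeric(d[[5]]) else NA_real_
  )
}

#' Load transition and emission parameter tables from TSV
#'
#' Schemas (see [write_param_tables()]): the transition TSV has columns
#' `bin_start`, `bin_end`, `p1_given_0`, `p1_given_1`, `plateau` (logical;
#' exactly the final row `TRUE`); the emission TSV has a single row with
#' columns `alpha_m`, `beta_m`, `alpha_u`, `beta_u`, `w0_u`. Out-of-range
#' probabilities or non-increasing bins are validation errors, never clipped.
#'
#' @param transition_path,emission_path TSV paths.
#' @return List with elements `transition` ([transition_table()]) and
#'   `emission` ([emission_params()]).
#' @export
load_param_tables <- function(transition_path, emission_path) {
  tr <- utils::read.table(transition_path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  em <- utils::read.table(emission_path,
    header = TRUE, sep = "\t",
    stringsAsFactors = FALSE
  )
  trt <- transition_table(
    bin_start = tr$bin_start, bin_end = tr$bin_end,
    p1_given_0 = tr$p1_given_0, p1_given_1 = tr$p1_given_1
  )
  if (!identical(as.logical(tr$plateau), c(
    rep(FALSE, nrow(tr) - 1L), TRUE
  ))) {
    abort("transition table: exactly the final row must be flagged plateau")
  }
  emp <- emission_params(
    alpha_m = em$alpha_m, beta_m = em$beta_m,
    alpha_u = em$alpha_u, beta_u = em$beta_u, w0_u = em$w0_u
  )
  list(transition = trt, emission = emp)
}

#' Write parameter tables to TSV
#'
#' @param transition A [transition_table()].
#' @param emission An [emission_params()].
#' @param transition_path,emission_path Output TSV paths.
#' @return Invisibly `NULL`.
#' @export
write_param_tables <- function(transition, emission,
                               transition_path, emission_path) {
  tr <- as_tibble(transition)
  tr$plateau <- c(rep(FALSE, nrow(tr) - 1L), TRUE)
  utils::write.table(tr, transition_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  em <- data.frame(
    alpha_m = emission$alpha_m, beta_m = emission$beta_m,
    alpha_u = emission$alpha_u, beta_u = emission$beta_u,
    w0_u = emission$w0_u
  )
  utils::write.table(em, emission_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(NULL)
}
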