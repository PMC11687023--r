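#' Simulate a CpG scaffold with realistic spacing and sparsity
#'
#' Generates CpG coordinates with geometric-like inter-CpG gaps (median
#' about `median_gap_bp`, capped) and a site-by-cell coverage mask with a
#' target fraction of missing entries. Cells get lognormal depth
#' multipliers (normalized to hit the target sparsity on average), so some
#' cells are systematically better covered than others, as in real
#' single-cell bisulfite data.
#'
#' @param n_sites,n_cells Grid dimensions.
#' @param sparsity Target fraction of missing (site, cell) entries, in
#'   (0, 1); 0 gives a fully observed mask.
#' @param median_gap_bp Median inter-CpG distance (default 120).
#' @param max_gap_bp Gap cap (default 10000).
#' @param depth_sd Standard deviation of the per-cell log depth multiplier.
#' @param seed Optional integer seed.
#' @return An object of class `scaffold`: list with `pos`, `n_cells`,
#'   `entries` (tibble `site`, `cell` of observed pairs), `sparsity_target`
#'   and `sparsity_realized`.
#' @export
simulate_scaffold <- function(n_sites, n_cells, sparsity,
                              median_gap_bp = 120, max_gap_bp = 10000,
                              depth_sd = 0.3, seed = NULL) {
  if (sparsity < 0 || sparsity >= 1) abort("sparsity must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_sites <- as.integer(n_sites)
  n_cells <- as.integer(n_cells)
  p_gap <- 1 - 0.5^(1 / max(median_gap_bp - 2, 1))
  gaps <- pmin(2L + stats::rgeom(n_sites - 1L, p_gap), max_gap_bp)
  pos <- cumsum(c(1000L, gaps))
  if (sparsity == 0) {
    entries <- tibble(
      site = rep(seq_len(n_sites), n_cells),
      cell = rep(seq_len(n_cells), each = n_sites)
    )
  } else {
    w <- exp(rnorm(n_cells, 0, depth_sd))
    u <- pmin(pmax((1 - sparsity) * w / mean(w), 0.001), 0.999)
    n_cov <- rbinom(n_cells, n_sites, u)
    sites <- lapply(n_cov, function(k) sort(sample.int(n_sites, k)))
    entries <- tibble(
      site = unlist(sites, use.names = FALSE),
      cell = rep.int(seq_len(n_cells), n_cov)
    )
  }
  entries <- dplyr::arrange(entries, .data$site, .data$cell)
  structure(
    list(
      pos = as.integer(pos), n_cells = n_cells, entries = entries,
      sparsity_target = sparsity,
      sparsity_realized = 1 - nrow(entries) / (n_sites * n_cells)
    ),
    class = "scaffold"
  )
}

#' @export
print.scaffold <- function(x, ...) {
  cat(sprintf(
    "<scaffold> %d CpG sites x %d cells, sparsity %.3f (target %.3f)\n",
    length(x$pos), x$n_cells, x$sparsity_realized, x$sparsity_target
  ))
  invisible(x)
}

# assign m methylated calls uniformly at random among the covered cells of
# each site; `site` must be sorted, `m` indexed by site id in `levels`
assign_quotas <- function(site, m_by_site) {
  cnt <- as.integer(table(factor(site, levels = names(m_by_site))))
  ord <- order(site, runif(length(site)))
  v <- numeric(length(site))
  v[ord] <- as.numeric(sequence(cnt) <= rep.int(m_by_site, cnt))
  v
}

#' Simulate a whole chromosome from the one-grouping HMM
#'
#' Samples a single hidden methylation-state chain along the scaffold from
#' the distance-dependent transition table (uniform initial state), draws
#' per-site methylated cell counts from the corresponding emission
#' component (beta-binomial under the methylated state, zero-inflated
#' beta-binomial otherwise), and scatters the counts uniformly among the
#' covered cells of each site. The result is a homogeneous (VMR-free)
#' chromosome.
#'
#' @param scaffold A [simulate_scaffold()].
#' @param table A [transition_table()].
#' @param emission An [emission_params()].
#' @param s_init Optional fixed initial state (0/1); default random uniform.
#' @param seed Optional integer seed.
#' @param chrom Chromosome label for the output.
#' @return A binarized [meth_mat()]; the attribute `hidden_states` carries
#'   the simulated chain.
#' @export
simulate_hmm_chromosome <- function(scaffold, table = default_transition_table(),
                                    emission = default_emission_params(),
                                    s_init = NULL, seed = NULL,
                                    chrom = "chrSim") {
  if (!is.null(seed)) set.seed(seed)
  pos <- scaffold$pos
  K <- length(pos)
  p <- trans_p1(table, diff(pos))
  s <- integer(K)
  s[1] <- if (is.null(s_init)) rbinom(1, 1, 0.5) else as.integer(s_init)
  u <- runif(K - 1)
  for (k in seq_len(K - 1)) {
    s[k + 1] <- as.integer(
      u[k] < (if (s[k] == 1L) p$p1_given_1[k] else p$p1_given_0[k])
    )
  }
  n_by_site <- tabulate(scaffold$entries$site, nbins = K)
  m <- integer(K)
  im <- s == 1L
  m[im] <- rbb(sum(im), n_by_site[im], emission$alpha_m, emission$beta_m)
  m[!im] <- rzibb(
    sum(!im), n_by_site[!im],
    emission$alpha_u, emission$beta_u, emission$w0_u
  )
  mk <- setNames(m, seq_len(K))
  value <- assign_quotas(scaffold$entries$site, mk)
  out <- meth_mat(
    chrom, pos,
    sprintf("cell_%04d", seq_len(scaffold$n_cells)),
    tibble(
      site = scaffold$entries$site, cell = scaffold$entries$cell,
      value = value
    )
  )
  attr(out, "hidden_states") <- s
  out
}

#' Sample VMR positions as eligible CpG clusters
#'
#' Enumerates candidate CpG clusters along the scaffold under the
#' constraints of the planted-VMR design — between `min_cpgs` and
#' `max_cpgs` CpGs, no adjacent-CpG gap above `max_gap_bp`, total width at
#' most `max_width_bp` — and samples `n_vmrs` of them without replacement
#' with probability proportional to `w = 1 - sqrt(2 * |0.5 - pi_r|)`,
#' where `pi_r` is the cluster mean of the per-site mean methylation
#' (clusters at intermediate methylation are preferred, where biological
#' cell-to-cell variability concentrates; clusters at 0 or 1 get weight 0).
#' Sampled clusters separated by at most 2 CpGs are merged.
#'
#' @param pos Site coordinates.
#' @param site_mean_meth Per-site mean methylation (NA allowed).
#' @param n_vmrs Number of clusters to sample.
#' @param min_cpgs,max_cpgs Cluster size bounds (defaults 5, 500).
#' @param max_gap_bp Maximum adjacent-CpG gap inside a cluster (default
#'   500).
#' @param max_width_bp Maximum cluster width (default 10000).
#' @param seed Optional integer seed.
#' @return Tibble of sampled spans: `start_idx`, `end_idx`, `n_cpgs`,
#'   `mean_meth`, `weight`, sorted by position.
#' @export
sample_vmr_clusters <- function(pos, site_mean_meth, n_vmrs,
                                min_cpgs = 5L, max_cpgs = 500L,
                                max_gap_bp = 500, max_width_bp = 10000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(pos)
  stopifnot(length(site_mean_meth) == K)
  gap_break <- which(diff(pos) > max_gap_bp)
  block_start <- c(1L, gap_break + 1L)
  block_end <- c(gap_break, K)
  cand <- list()
  for (b in seq_along(block_start)) {
    st <- block_start[b]
    while (st <= block_end[b]) {
      en <- min(
        block_end[b], st + max_cpgs - 1L,
        findInterval(pos[st] + max_width_bp, pos)
      )
      if (en - st + 1L >= min_cpgs) {
        cand[[length(cand) + 1L]] <- c(st, en)
      }
      st <- en + 1L
    }
  }
  if (length(cand) == 0L) abort("no eligible CpG clusters on this scaffold")
  cand <- do.call(rbind, cand)
  pi_r <- vapply(
    seq_len(nrow(cand)),
    function(r) mean(site_mean_meth[cand[r, 1]:cand[r, 2]], na.rm = TRUE),
    0
  )
  w <- pmax(1 - sqrt(2 * abs(0.5 - pi_r)), 0)
  eligible <- which(w > 0 & !is.na(w))
  if (length(eligible) < n_vmrs) {
    abort(sprintf(
      "only %d eligible cluster(s) with positive weight; %d requested",
      length(eligible), n_vmrs
    ))
  }
  pick <- eligible[sample.int(
    length(eligible), n_vmrs,
    prob = w[eligible]
  )]
  pick <- sort(pick)
  out <- tibble(
    start_idx = cand[pick, 1], end_idx = cand[pick, 2],
    mean_meth = pi_r[pick], weight = w[pick]
  )
  # merge sampled clusters with <= 2 CpGs in between (only when the bridge
  # itself respects the gap constraint, so merged spans stay CR-eligible)
  if (nrow(out) > 1) {
    n_between <- out$start_idx[-1] - out$end_idx[-nrow(out)] - 1L
    bridge_ok <- vapply(seq_len(nrow(out) - 1L), function(i) {
      idx <- out$end_idx[i]:out$start_idx[i + 1L]
      all(diff(pos[idx]) <= max_gap_bp)
    }, TRUE)
    close_next <- n_between <= 2L & bridge_ok
    grp <- cumsum(c(TRUE, !close_next))
    out <- out |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(
        start_idx = min(.data$start_idx), end_idx = max(.data$end_idx),
        mean_meth = mean(.data$mean_meth), weight = mean(.data$weight)
      ) |>
      ungroup() |>
      select(-"grp")
  }
  out$n_cpgs <- out$end_idx - out$start_idx + 1L
  out[c("start_idx", "end_idx", "n_cpgs", "mean_meth", "weight")]
}

#' Sample the VMR prevalence from the subpopulation distribution
#'
#' With `rho` cell subpopulations, the number `rho_r` of subpopulations
#' forming the unmethylated grouping of a VMR is drawn from
#' `P(rho_r) = choose(rho, rho_r) / sum_{1}^{rho - 1} choose(rho, j)` for
#' `rho_r` in `1, ..., rho - 1`, and the U-grouping prevalence is
#' `pi0 = rho_r / rho`.
#'
#' @param rho Number of subpopulations (>= 2).
#' @param n Number of independent draws.
#' @param seed Optional integer seed.
#' @return Tibble with `rho_r`, `pi0`, `pi1` (one row per draw).
#' @export
sample_prevalence <- function(rho, n = 1L, seed = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 2) {
    abort("rho must be an integer >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  support <- seq_len(rho - 1)
  pr <- choose(rho, support)
  rho_r <- support[sample.int(
    length(support), n,
    replace = TRUE, prob = pr
  )]
  tibble(rho_r = rho_r, pi0 = rho_r / rho, pi1 = 1 - rho_r / rho)
}

#' Overwrite VMR spans with two-grouping signal
#'
#' For every site of every planted VMR, the covered cells of the
#' unmethylated grouping receive a methylated-call quota drawn from the
#' zero-inflated beta-binomial emission component and the methylated
#' grouping a quota from the beta-binomial component; quotas are assigned
#' uniformly at random among the covered cells of each grouping. Sites
#' outside VMRs keep their background values.
#'
#' @param mat Background [meth_mat()] (binarized).
#' @param truth A `synthetic_truth` from [build_synthetic_truth()].
#' @param emission An [emission_params()].
#' @param seed Optional integer seed.
#' @return The modified [meth_mat()].
#' @export
inject_vmr_signal <- function(mat, truth, emission, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  value <- mat_value(mat)
  site <- mat_site(mat)
  cell <- mat_cell(mat)
  vm <- truth$vmrs
  vm_sites <- unlist(
    mapply(seq.int, vm$start_idx, vm$end_idx, SIMPLIFY = FALSE),
    use.names = FALSE
  )
  sel <- which(site %in% vm_sites)
  idx_by_site <- split(sel, site[sel])
  for (r in seq_len(nrow(vm))) {
    grp <- truth$group_of(vm$vmr_id[r]) # per-cell "U"/"M"
    for (k in vm$start_idx[r]:vm$end_idx[r]) {
      ix <- idx_by_site[[as.character(k)]]
      if (is.null(ix)) next
      g <- grp[cell[ix]]
      iu <- ix[g == "U"]
      im <- ix[g == "M"]
      mu <- rzibb(
        1L, length(iu), emission$alpha_u, emission$beta_u, emission$w0_u
      )
      mm <- rbb(1L, length(im), emission$alpha_m, emission$beta_m)
      stopifnot(mu <= length(iu), mm <= length(im))
      value[iu] <- 0
      value[im] <- 0
      if (mu > 0) value[iu[sample.int(length(iu), mu)]] <- 1
      if (mm > 0) value[im[sample.int(length(im), mm)]] <- 1
    }
  }
  entries <- tibble(site = site, cell = cell, value = value)
  out <- meth_mat(mat$chrom, mat$pos, mat$cell_ids, entries)
  attr(out, "hidden_states") <- attr(mat, "hidden_states")
  out
}

#' Build the ground truth for planted VMRs
#'
#' Partitions the cells into `rho` equal-sized subpopulations, then for
#' each span draws the prevalence via [sample_prevalence()] and assigns
#' `rho_r` randomly chosen subpopulations to the unmethylated grouping.
#'
#' @param spans Tibble from [sample_vmr_clusters()].
#' @param pos Site coordinates.
#' @param n_cells Number of cells.
#' @param rho Number of subpopulations (>= 2).
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_truth`: list with `vmrs`
#'   (tibble: `vmr_id`, span columns, `rho_r`, `pi0`, `pi1`),
#'   `subpop` (per-cell subpopulation index), `n_subpop`, `assignment`
#'   (tibble `vmr_id`, `cell`, `group`) and the accessor `group_of(id)`.
#' @export
build_synthetic_truth <- function(spans, pos, n_cells, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_vmrs <- nrow(spans)
  subpop <- sample(rep_len(seq_len(rho), n_cells))
  prev <- sample_prevalence(rho, n = n_vmrs)
  groups <- vector("list", n_vmrs)
  for (r in seq_len(n_vmrs)) {
    u_pops <- sample.int(rho, prev$rho_r[r])
    groups[[r]] <- ifelse(subpop %in% u_pops, "U", "M")
  }
  vmrs <- tibble(
    vmr_id = seq_len(n_vmrs),
    start_idx = spans$start_idx, end_idx = spans$end_idx,
    start_pos = pos[spans$start_idx], end_pos = pos[spans$end_idx],
    n_cpgs = spans$n_cpgs,
    rho_r = prev$rho_r, pi0 = prev$pi0, pi1 = prev$pi1
  )
  assignment <- tibble(
    vmr_id = rep(seq_len(n_vmrs), each = n_cells),
    cell = rep(seq_len(n_cells), n_vmrs),
    group = unlist(groups, use.names = FALSE)
  )
  structure(
    list(
      vmrs = vmrs, subpop = subpop, n_subpop = rho,
      assignment = assignment,
      group_of = function(id) groups[[id]]
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d planted VMR(s), %d subpopulation(s)\n",
    nrow(x$vmrs), x$n_subpop
  ))
  invisible(x)
}

#' Simulate a full dataset with planted VMRs and known truth
#'
#' Convenience wrapper over the generator pipeline: scaffold, homogeneous
#' HMM background, eligible-cluster sampling, subpopulation-based
#' prevalence draws and signal injection.
#'
#' @inheritParams simulate_scaffold
#' @param n_vmrs Number of planted VMRs.
#' @param rho Number of cell subpopulations.
#' @param table,emission Parameter tables (defaults shipped).
#' @param min_cpgs,max_cpgs,max_gap_bp,max_width_bp Cluster constraints,
#'   see [sample_vmr_clusters()].
#' @param seed Integer seed controlling the whole generation.
#' @return List with `mat` (a [meth_mat()]), `truth`
#'   (a `synthetic_truth`) and `scaffold`.
#' @export
simulate_dataset <- function(n_sites, n_cells, sparsity, n_vmrs, rho,
                             table = default_transition_table(),
                             emission = default_emission_params(),
                             min_cpgs = 5L, max_cpgs = 500L,
                             max_gap_bp = 500, max_width_bp = 10000,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scaffold <- simulate_scaffold(n_sites, n_cells, sparsity)
  mat <- simulate_hmm_chromosome(scaffold, table, emission)
  summ <- site_summaries(mat)
  spans <- sample_vmr_clusters(
    mat$pos, summ$mean_meth, n_vmrs,
    min_cpgs = min_cpgs, max_cpgs = max_cpgs,
    max_gap_bp = max_gap_bp, max_width_bp = max_width_bp
  )
  truth <- build_synthetic_truth(spans, mat$pos, n_cells, rho)
  mat <- inject_vmr_signal(mat, truth, emission)
  list(mat = mat, truth = truth, scaffold = scaffold)
}
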