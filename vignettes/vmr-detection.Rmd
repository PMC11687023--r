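---
title: "Detecting variably methylated regions in single-cell bisulfite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variably methylated regions in single-cell bisulfite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(vmrscan)
library(dplyr)
```

## The problem

Single-cell bisulfite sequencing (scBS-seq) measures CpG methylation in
individual cells, but the data are extreme: 80--95+% of CpG sites are
unobserved in any given cell, and observed sites are covered by one or two
reads, so each observation is effectively a binary methylated/unmethylated
call. A *variably methylated region* (VMR) is a run of CpGs at which the
cell population splits into a methylated and an unmethylated subpopulation
— the epigenetic analogue of a marker gene. vmrscan detects and ranks such
regions genome-wide, at CpG-site resolution, without requiring cell labels
or predefined windows.

## The model

Input is a sparse site-by-cell binary matrix per chromosome (`meth_mat`):
entry \(x_{kc} \in \{0,1\}\) where cell \(c\) covers site \(k\), missing
otherwise. Sites record the methylated cell count \(m_k\) and covered cell
count \(n_k\).

**Stage 1 — candidate regions.** Relative methylation
\(x^*_{kc} = x_{kc} - \bar x_{k\cdot}\) is smoothed per cell with a box
kernel (2000 bp total window), and the across-cell variance
\(\hat\sigma^2_k = \sum_c \hat x_{kc}^2 / (n_k - 1)\) is screened against a
null threshold: the \(1-\alpha\) quantile of the variance under a
simulated homogeneous population with the input's own coverage and spacing
distributions. Runs of at least 5 consecutive sites above the threshold
(no adjacent-CpG gap above 2000 bp) become candidate regions (CRs).

**Stage 2 — HMM decoding.** Within each CR two hidden Markov models are
decoded with the Viterbi algorithm.

* *One grouping*: hidden state \(s_k \in \{0,1\}\); emission of \(m_k\)
  out of \(n_k\) is beta-binomial \(p_M\) under \(s_k = 1\) and
  zero-inflated beta-binomial \(p_U\) under \(s_k = 0\) (the zero
  inflation absorbs the excess of all-unmethylated sites seen in real
  data). Transitions depend on the previous state and the inter-CpG
  distance through a binned table that plateaus at large distances.
* *Two groupings*: bivariate state
  \(s_k = (s^{(0)}_k, s^{(1)}_k) \in \{(0,0), (0,1), (1,1)\}\) for an
  unmethylated (U) and methylated (M) cell grouping with prevalences
  \(\pi = (\pi^{(0)}, \pi^{(1)})\), \(\pi^{(0)} + \pi^{(1)} = 1\). State
  \((1,0)\) is excluded — the M grouping must be methylated wherever the
  groupings differ — so the one-grouping model is *not* nested in the
  two-grouping model. The emission convolves a binomial split of the
  \(n_k\) covered cells into the M grouping (rate
  \(r = s^{(0)}\pi^{(0)} + s^{(1)}\pi^{(1)}\)) with \(p_M\) and \(p_U\)
  observation components; transitions factorize over the two chains and
  are renormalized over the three allowed states.

The prevalence is estimated by alternating Viterbi decoding at fixed
\(\pi\) with exponentiated-gradient (EG) minimization of the negative
emission log likelihood at a fixed path, from the initial values
\(\pi^{(0)} \in \{0.2, 0.5, 0.8\}\); the best final joint likelihood wins.
A CR contains a VMR only if the two-grouping model scores strictly higher
than the one-grouping model; the VMR is the envelope of the \((0,1)\)-runs
of length at least 5, trimmed at the edges and merged into at most one VMR
per CR. VMRs are ranked by the log-likelihood increment of the
two-grouping over the one-grouping model.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | significance level of the stage-1 variance threshold; the main sensitivity dial |
| `bandwidth_bp` | 2000 | total box-kernel window; matches the distance at which CpG-CpG methylation correlation plateaus |
| `max_gap_bp` | 2000 | maximum adjacent-CpG distance inside a CR, same rationale |
| `min_cr_cpgs`, `min_vmr_cpgs` | 5 | minimum CpG counts; raise for broad domains, keep low for fine regulatory elements |
| `min_cells` | 3 | minimum covered cells per retained site |
| `null_sim_sites` | 1e5 | null-simulation size behind the threshold |
| `pi_inits`, `eta`, `tol`, `max_iter` | {0.2, 0.5, 0.8}, 0.05, 1e-4, 100 | EG/alternation controls |

The shipped parameter tables are configuration, not ground truth: the
transition probability toward the methylated state follows
\(p_\infty + (\mathbf{1}\{s=1\} - p_\infty) e^{-d/\lambda}\) with
\(p_\infty = 0.8\) (the typical global CpG methylation plateau) and
\(\lambda = 700\) bp, tabulated in 20-bp bins to 2000 bp; emissions default
to \(p_M = \mathrm{BB}(19, 1)\) (prior mean 0.95) and
\(p_U = \mathrm{ZIBB}(1, 19)\) (prior mean 0.05) with zero-inflation 0.3.
Both can be re-estimated from annotated data with
`estimate_transition_table()` / `estimate_emission_priors()` via
pseudo-bulk aggregation, using mean-methylation state calls at 0.5,
add-one smoothing for transition tallies, and method-of-moments
beta-binomial fits with a fixed-point excess-zero estimator for the zero
inflation — simple, documented estimators chosen for robustness over
efficiency.

## Numerical choices

All probability arithmetic is in log space; the two-grouping emission's
double sum uses log-sum-exp with per-site normalization. Viterbi ties are
broken toward the lexicographically smaller state sequence (backward
dynamic programming with greedy forward selection), so decoding is fully
deterministic. The initial state distribution is the proper uniform
(1/2 or 1/3), so one- and two-grouping scores are genuine joint log
probabilities and comparable. EG updates center the gradient before
exponentiation (mathematically a no-op on the simplex, numerically
overflow-proof), renormalize so \(\pi\) sums to one exactly, and
backtrack (halving the step) whenever a proposed step would increase the
objective — each optimization phase therefore never degrades the joint
likelihood, and the alternation's joint log likelihood is monotone by
construction. Sites decoded \((0,0)\) or \((1,1)\) have the split rate
pinned at 0 or 1 on the simplex and contribute nothing to the prevalence
gradient. Model comparison uses the Viterbi max-path score by default;
the forward marginal likelihood is available via `score = "forward"`.
A score tie yields no VMR (conservative, given the non-nesting).

## What the generator emulates — and what it does not

`simulate_dataset()` builds a scaffold with geometric-like inter-CpG gaps
(median 120 bp, the genome-wide CpG spacing scale), lognormal per-cell
depth multipliers, and Bernoulli missingness at a target sparsity
(defaults mirror high-throughput scBS-seq at 90--95% missing). Background
methylation is simulated from the one-grouping HMM itself; planted VMRs
are CpG clusters (5--500 CpGs, gaps ≤ 500 bp, width ≤ 10 kb) sampled with
weight \(1 - \sqrt{2\,|0.5 - \pi_r|}\) favoring intermediate methylation,
with prevalences drawn from the binomial-coefficient distribution over
\(\rho\) equal cell subpopulations and counts injected from the emission
components. Because background and emissions come from the same model
family the scan decodes, passing tests demonstrate *self-consistency and
calibration*, not robustness to real-data pathologies: uneven
amplification, residual heterogeneity in "homogeneous" populations,
non-CpG contamination and chromosome-scale covariates are not emulated.
Real-data thresholds should therefore be read as approximate.

## A worked example

```{r example}
sim <- simulate_dataset(
  n_sites = 4000, n_cells = 300, sparsity = 0.9,
  n_vmrs = 15, rho = 2, max_cpgs = 50, seed = 7
)
res <- detect_vmrs(sim$mat, null_sim_sites = 5000, seed = 11)
glance(res)
tidy(res) |> head(3)
rm <- region_match(res$vmr, sim$truth$vmrs, res$variance$pos)
c(precision = rm$precision, recall = rm$recall)
```

```{r plot, fig.width = 7, fig.height = 3}
autoplot(res)
```

## Problem sizes used in the test suite

The package's statistical checks run on scaled-down designs chosen to
keep the suite fast while leaving the conclusions intact: null
calibration on a 50,000-site × 500-cell homogeneous chromosome
(null simulation 1e5 sites), planted-VMR power on 12,000-site
chromosomes with 50 VMRs at sparsities 0.90/0.95 and
\(\rho \in \{2, 4\}\) over 3 seeds, prevalence recovery on 50-site ×
500-cell regions, and estimator closure on 10,000 sites × 300 cells.
These sizes are the package's own validation design.

## Known limitations

* No p-values or FDR control for VMRs: the ranking is by likelihood
  increment, and the stage-1 \(\alpha\) controls only the per-site null
  variance exceedance.
* At most one VMR per CR by design (U/M-grouping assumption); interleaved
  multi-grouping structure is collapsed to the envelope span.
* Two-grouping emission cost is quadratic in covered cells per site, so
  runtime grows quadratically with the number of cells; for very large
  atlases, stage 1 alone is a useful pre-screen.
* The merge rule for clusters/VMRs can produce spans wider than the
  cluster-sampling caps; spans are reported as-is.
* Hemimethylation and intermediate methylation are filtered, not modeled.
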