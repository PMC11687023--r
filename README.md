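# vmrscan

Detection of **variably methylated regions (VMRs)** from single-cell
bisulfite sequencing (scBS-seq) data, at CpG-site resolution.

scBS-seq yields near-binary per-CpG methylation calls per cell with
80–95+% of sites unobserved in any one cell. A VMR is a run of CpGs at
which the cells split into a methylated and an unmethylated
subpopulation — regions that act as epigenetic markers of cell identity.
vmrscan finds them genome-wide without cell labels or fixed windows, for
anyone analysing single-cell methylomes (cell-type discovery, epigenetic
heterogeneity in development or cancer).

## Method in brief

Let \(x_{kc} \in \{0,1\}\) be the methylation call of CpG \(k\) in cell
\(c\), with \(m_k\) methylated of \(n_k\) covered cells per site.

1. **Candidate regions.** Per-cell relative methylation
   \(x^*_{kc} = x_{kc} - \bar x_{k\cdot}\) is box-kernel smoothed (2000 bp
   window) and the across-cell variance
   \(\hat\sigma_k^2 = \sum_c \hat x_{kc}^2/(n_k-1)\) is compared with the
   \(1-\alpha\) quantile of a coverage-matched homogeneous null
   simulation; runs of ≥ 5 above-threshold CpGs (gaps ≤ 2000 bp) are
   candidate regions.
2. **HMM decoding.** Each candidate region is decoded under a
   one-grouping HMM (states \(s_k \in \{0,1\}\); beta-binomial emission
   for methylated states, zero-inflated beta-binomial for unmethylated)
   and a two-grouping HMM (states \((s^{(0)}, s^{(1)}) \in
   \{(0,0),(0,1),(1,1)\}\), prevalence \(\pi\) on the simplex, emissions
   convolving a binomial cell split with the two observation
   components). \(\pi\) is estimated by exponentiated-gradient ascent
   alternating with Viterbi decoding, from starts {0.2, 0.5, 0.8}.
3. **Calling and ranking.** If the two-grouping model scores strictly
   higher, the ≥ 5-CpG runs of state \((0,1)\) are trimmed, merged and
   reported as one VMR per candidate region, ranked by the
   log-likelihood increment between the two models.

The package also ships the synthetic-data generator (planted VMRs with
known prevalence and grouping truth over an HMM-simulated background),
estimators for the transition/emission parameter tables from annotated
data, and the evaluation metrics (region/CpG precision–recall, restricted
PR area, Manhattan cell dissimilarity, nearest-neighbor count score).

## Worked example

```r
library(vmrscan)

sim <- simulate_dataset(
  n_sites = 4000, n_cells = 300, sparsity = 0.9,
  n_vmrs = 15, rho = 2, max_cpgs = 50, seed = 7
)
res <- detect_vmrs(sim$mat, null_sim_sites = 5000, seed = 11)
glance(res)
#> # A tibble: 1 × 8
#>   chrom  n_cells n_sites n_crs n_vmrs n_cpgs_in_vmrs alpha threshold
#>   <chr>    <int>   <int> <int>  <int>          <int> <dbl>     <dbl>
#> 1 chrSim     300    4000    15     15            354  0.05    0.0770

tidy(res) |> head(3)
#> # A tibble: 3 × 11
#>   chrom  cr_id start_idx end_idx start_pos end_pos n_cpgs loglik_increment
#>   <chr>  <int>     <int>   <int>     <int>   <int>  <int>            <dbl>
#> 1 chrSim     8      1505    1554    264487  270931     50             338.
#> 2 chrSim     6      1167    1216    207743  214647     50             330.
#> 3 chrSim    11      2690    2739    463054  470258     50             315.

rm <- region_match(res$vmr, sim$truth$vmrs, res$variance$pos)
c(precision = rm$precision, recall = rm$recall)
#> precision    recall
#>         1         1
```

Reading the output: a 4000-CpG chromosome with 15 planted VMRs among 300
cells at 90% sparsity yields a variance threshold of 0.077 at
\(\alpha = 0.05\); 15 candidate regions all pass the two-grouping test,
each VMR span, prevalence estimate (`pi0_hat`) and likelihood increment
is reported, and every planted region is recovered with no false
positives. `autoplot(res)` draws the variance track with candidate
regions and VMRs shaded; `write_regions_bed()` exports BED + TSV.

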