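Package: vmrscan
Title: Detection of Variably Methylated Regions from Single-Cell Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of variably methylated regions (VMRs) from
    sparse single-cell bisulfite sequencing data at CpG-site resolution. A
    two-stage scan first screens for candidate regions whose kernel-smoothed
    across-cell methylation variance exceeds a simulation-derived null
    threshold, then decodes one-grouping and two-grouping hidden Markov models
    with beta-binomial and zero-inflated beta-binomial emissions inside each
    candidate region; the prevalence of the methylated cell grouping is
    estimated by exponentiated-gradient optimization on the probability
    simplex. Includes a synthetic-data generator with planted VMRs and known
    truth, empirical estimators for the transition and emission parameter
    tables, and region- and CpG-level evaluation metrics (precision, recall,
    restricted precision-recall area, nearest-neighbor count score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
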