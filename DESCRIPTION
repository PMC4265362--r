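Package: mstgsa
Title: Multivariate Gene Set Analysis for RNA-Seq Counts with Minimum
    Spanning Tree Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Self-contained gene set analysis for two-phenotype RNA-Seq
    count data. Implements the minimum-spanning-tree generalizations of
    the Kolmogorov-Smirnov and Wald-Wolfowitz two-sample tests and the
    energy-type N-statistic with sample-permutation P-values, gene-level
    P-value combination by Fisher's, Stouffer's and the soft-truncation
    Gamma method, four count normalizations (RPKM, TMM followed by RPKM,
    quantile normalization followed by RPKM, and an offset log-CPM
    transform followed by RPKM), and a negative-binomial simulation
    harness for Type I error and power studies of gene-set tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
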