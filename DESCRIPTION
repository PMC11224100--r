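Package: liquidfrac
Title: Tumor Fraction Estimation from Low-Pass Whole-Genome cfDNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the circulating tumor DNA (ctDNA) fraction of plasma
    cell-free DNA from low-pass whole-genome sequencing read counts in fixed
    500 kb genomic bins. Bin counts are normalized for library size and GC
    content, an initial tumor fraction is read off the density of normalized
    copy ratios, and copy-number states are decoded with a negative-binomial
    hidden Markov model whose emission means mix diploid and tumor copies at
    the candidate fraction; copy-number calls and the fraction are refined by
    coordinate ascent. Calls are gated by a Kolmogorov-Smirnov comparison of
    model residuals against a permuted-bin noise model and by a
    peri-centromeric deletion artifact filter. The package also ships a
    synthetic-data generator (segmental copy-number profiles, overdispersed
    bin counts under GC bias, and a clinical cohort with coupled biomarker
    and survival structure) and the comparative statistics used in liquid
    biopsy biomarker studies: contingency-table tests, odds ratios,
    Kruskal-Wallis with Dunn post-hoc tests, Spearman correlation, ROC with
    Youden thresholds, Kaplan-Meier/logrank, and Cox regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    survival,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
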