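Package: teqtl
Title: Temporal eQTL Mapping and Temporal Genetic Causality Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping temporal expression quantitative trait loci
    (teQTLs) in time-course expression data from genotyped populations, and
    for inferring causal direction between pairs of traits that share a
    locus. Implements a multivariate polynomial temporal genetic association
    test (per-genotype cubic mean trajectories with AR(1)-correlated
    residuals, profiled maximum likelihood and a likelihood-ratio test),
    six comparator association methods (single-timepoint Wilcoxon, union and
    Fisher-product combinations of per-timepoint tests, MANOVA, stacked
    cubic regression, and a lag-one autoregressive F-test), and a temporal
    genetic causality test that selects among causal, reactive, independent
    and partial-causal autoregressive structures by likelihood and BIC.
    Includes simulation generators for all study designs, permutation-based
    FDR estimation, eQTL hotspot detection with binomial thresholds,
    chi-square quantile confidence intervals for QTL location, QQ-based
    calibration checks, a neighbouring-marker overfitting diagnostic,
    hypergeometric gene-set enrichment, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
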