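Package: bivargwas
Title: Shared Genetic Architecture of Two Case-Control GWAS Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the shared genetic architecture of two
    genetically correlated case-control GWAS traits from summary statistics
    alone. Implements LD score regression for SNP heritability, genetic
    covariance/correlation and sample-overlap intercepts with block-jackknife
    standard errors; a per-SNP bivariate common-factor (common pathway) model
    with a heterogeneity statistic Qb obtained as the chi-squared difference
    against the saturated independent pathway model; N-weighted meta-analysis
    and the homogeneous-effect cross-phenotype statistic Shom as cross-method
    validation; a block-bootstrap Spearman correlation of blockwise association
    signal for unsigned statistics; Ward clustering of genetic-correlation
    matrices with elbow-based cluster count and principal-component
    representative selection; and a moment-matched synthetic summary-statistics
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
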