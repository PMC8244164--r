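Package: mrphewas
Title: Sex-Specific Drug-Target Mendelian Randomization Phenome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running sex-stratified drug-target Mendelian
    randomization (MR) phenome-wide association scans over GWAS summary
    statistics. Provides tab-separated summary-statistic readers with
    configurable column dialects, allele harmonization with palindromic-variant
    handling, r-squared based instrument pruning, Wald-ratio and
    correlated-instrument inverse-variance-weighted estimation with
    multiplicative random effects, MR-Egger with the directional-pleiotropy
    intercept test, multivariable MR, conversion of linear-probability betas
    for binary traits to odds ratios via the case-fraction approximation,
    phenome filtering with Bonferroni family-wise control, effect sizes scaled
    relative to an LDL-cholesterol anchor, two-sided z-tests for
    sex differences and replication, and a seeded generator of two-sample
    summary statistics with known ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
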