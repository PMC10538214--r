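Package: mrmediate
Title: Two-Sample and Two-Step Mediation Mendelian Randomization from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    mediation MR from genome-wide association study (GWAS) summary
    statistics. Reads and harmonizes summary-statistics tables to a common
    effect-allele orientation, selects independent genome-wide-significant
    instruments with confounder exclusion and greedy distance/LD pruning,
    and computes inverse-variance-weighted (fixed and multiplicative
    random-effects), MR-Egger, weighted-median, maximum-likelihood and
    robust adjusted profile score (Huber loss) causal estimates together
    with Cochran's Q heterogeneity, Egger-intercept pleiotropy and
    leave-one-out diagnostics. Multivariable MR yields direct effects and
    the product-method mediation decomposition with the proportion
    mediated. A synthetic summary-statistics generator with known causal
    truths supports calibration and parameter-recovery testing, and a
    pipeline runner reproduces the full analysis layout end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
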