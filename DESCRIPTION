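Package: lipidmr
Title: Prioritizing Causal Lipoprotein Risk Factors with Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing causal lipoprotein-related risk factors for
    atherosclerotic disease from GWAS summary statistics. Implements allele
    harmonization, instrument selection and LD pruning; univariable and
    multivariable Mendelian randomization (Wald ratio, fixed- and random-effects
    inverse-variance weighted, MR-Egger) with generalized least squares support
    for linkage-disequilibrium-correlated instruments; Bayesian model averaging
    over multivariable MR models with marginal inclusion probabilities,
    empirical permutation p-values, Benjamini-Hochberg FDR and the Nyholt
    effective-tests correction; gene-region (drug-target) instrument selection
    with a bootstrap ratio-of-effects comparison between outcomes; a
    summary-based transcriptome-wide association statistic with a between-trait
    differential-effect test; and a seeded generator of factor-structured
    synthetic GWAS summary statistics with known causal truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
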