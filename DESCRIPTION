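Package: telomr
Title: Two-Sample Mendelian Randomization of Telomere Length on Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: allele harmonization of exposure and outcome associations,
    greedy p-value-ordered linkage-disequilibrium clumping, five summary-data
    causal estimators (inverse-variance weighted, maximum likelihood, MR-Egger,
    weighted median, weighted mode) and the accompanying sensitivity suite
    (Cochran/Ruecker Q heterogeneity statistics, the Egger intercept test,
    leave-one-SNP-out analysis, and an MR-PRESSO style residual-sum-of-squares
    outlier test). Ships the 16 published telomere-length instruments with
    their Alzheimer's disease outcome associations as a worked case study, and
    a synthetic-data generator with known causal effect and pleiotropy regime
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
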