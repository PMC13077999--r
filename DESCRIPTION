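Package: mrscreen
Title: Metabolome-Wide Two-Sample Mendelian Randomisation Screening
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for metabolome-wide two-sample Mendelian
    randomisation screens from GWAS summary statistics: adaptive p-value
    instrument selection with greedy LD clumping and proxy substitution,
    allele harmonisation with palindrome and strand handling, a
    five-estimator causal-inference battery (Wald ratio, fixed and
    multiplicative random-effects inverse-variance weighting, MR-Egger,
    weighted median, weighted mode), heterogeneity and pleiotropy
    diagnostics (Cochran's Q, I2 for the instrument-exposure association,
    radial MR outlier removal, leave-one-out, q-q inflation), and
    family-wise or FDR multiple-testing control. Includes a closed-form
    generator of two-sample GWAS summary statistics with known causal
    effects, pleiotropy, LD structure and harmonisation stressors, so
    every stage is verifiable without external GWAS downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
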