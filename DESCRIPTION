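Package: mrsummary
Title: Two-Sample Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization from GWAS
    summary statistics: reading and harmonizing per-variant association
    tables, unit and scale conversion (percent change to log units,
    per-log-unit to per-standard-deviation), causal estimation by Wald
    ratio, inverse-variance weighting, MR-Egger regression and the
    weighted median, instrument diagnostics (F-statistics, variance
    explained, Cochran's Q, the I-squared statistic for the
    no-measurement-error assumption, funnel and forest plot data),
    analytic power calculation for binary outcomes, and a synthetic
    summary-statistics generator with known ground truth for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
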