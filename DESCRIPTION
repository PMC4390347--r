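Package: trapscreen
Title: Hit Calling for Gene-Trap Embryonic Stem Cell Radiation-Response Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of dual-assay radiation-response screens of
    gene-trapped mutant embryonic stem cell clones. Computes plate-level percent
    viability from dead-cell and total-cell luminescence, dose-contrast changes in
    viability with Z-scores against a wild-type replicate null, beta-galactosidase
    reporter expression per living cell with dose log-ratios scored against a
    robust RANSAC-style null estimated from the clone population, two-tailed
    normal p-values with directional hit calling, filtered hypergeometric
    gene-set over-representation with Benjamini-Hochberg q-values, replicate
    concordance QC, and delta-delta-Ct fold changes. Includes a seeded synthetic
    screen generator with planted hits for power and type-I-error validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
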