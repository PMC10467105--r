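Package: sigconnect
Title: Connectivity and Master-Regulator Analysis of Perturbational
    Expression Signatures
Version: 0.1.0
Authors@R:
    person("VenomSig", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A workflow for screening crude natural-product perturbagens
    (e.g. animal venoms) against reference compendia of drug-induced
    expression profiles. Covers dose-response calibration by Hill-curve
    fitting with GI20 extraction, negative-binomial Wald differential
    expression with BH-FDR signature construction, Connectivity-Map style
    scoring (signed Kolmogorov-Smirnov-like enrichment, weighted
    connectivity, group-normalised scores, signed quantile tau, and
    perturbagen-class aggregation by a maximum-quantile rule),
    regulon-based master-regulator analysis with permutation nulls and
    transcription-factor to disease mapping with ICD-9 chapter rollup,
    technical-validation statistics, seeded synthetic-data generators for
    every input, and a command-line pipeline driver.
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
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
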