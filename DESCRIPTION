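Package: archipelago
Title: Layered Manhattan-Style Visualisation of Variant-Set Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns interpretable genomic x-coordinates to variant-set
    association test (VSAT) P values by averaging the cumulative genomic
    coordinates of each set's constituent variants, and renders set-level and
    single-variant association signals together in one layered Manhattan-style
    "archipelago" plot. Includes ranked dispersion to resolve overlapping set
    anchors, Bonferroni thresholds by number of set tests, an ACAT
    (Cauchy-combination) annotation layer with per-layer contribution
    summaries, a seeded synthetic-data generator for GWAS and VSAT summary
    statistics, tolerant readers for common summary-statistics dialects, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    patchwork,
    rlang,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    ragg,
    withr
Config/testthat/edition: 3
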