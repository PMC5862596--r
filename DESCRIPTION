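Package: proteopanel
Title: iTRAQ Consensus Differential Expression, Network Propagation and
    MRM Panel Validation for Tissue Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for tumor/matched-control tissue
    proteomics built around pooled-reference iTRAQ 4-plex designs. Rolls
    peptide-spectrum-match reporter intensities up to per-patient protein
    fold changes against a pooled control channel, applies a multi-stage
    consensus differential-expression filter (unique-peptide rule,
    multi-set detection, average fold change, per-patient trend agreement,
    two-search-engine intersection), scores concordance with external
    reference datasets, prioritizes disease-associated interactors by
    diffusing the consensus list over a confidence-weighted
    protein-protein interaction network, and validates candidate panels
    from multiple-reaction-monitoring transition peak areas with paired
    tests. Ships a synthetic-data generator that emulates the full study
    design (plex layout, two engines with overlapping detection,
    log-normal reporter noise, scale-free weighted networks, triplicate
    MRM injections) so every stage is testable without raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
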