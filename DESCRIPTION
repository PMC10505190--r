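Package: cleavr
Title: Cleavage-Rule Analysis for Increased-Fidelity Cas9 Variant Selection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of variant-by-target cleavage-activity matrices for
    increased-fidelity SpCas9 nucleases. Normalizes raw EGFP-disruption or
    amplicon-indel activity tables to wild type, orders nuclease variants by
    fidelity and targets by cleavability, fits the monotone staircase boundary
    implied by a latent-threshold cleavage rule, and scores the fit with the
    geometric mean of sensitivity and specificity and per-variant ROC/AUC.
    Includes a latent-threshold synthetic data generator with parameter
    recovery, a two-step screen that selects the target-matched variant while
    minimizing assays, one-phase exponential decay fitting for in vitro
    cleavage kinetics, and amplicon indel/tag/edit quantification from aligned
    reads.
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
    optparse,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
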