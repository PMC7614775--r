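Package: abppquant
Title: Cysteine Engagement Quantification for TMT-Based Activity-Based
    Protein Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies covalent-inhibitor engagement of proteomic cysteines
    from multiplexed (TMT) activity-based protein profiling experiments.
    Converts peptide-spectrum-match reporter-ion intensities into
    per-cysteine competition ratios and engagement calls with the standard
    quality-control filters, fits four-parameter logistic dose-response
    curves to recover TE50/IC50 values with bootstrap confidence intervals,
    supports targeted quantification (parallel reaction monitoring and
    targeted TMT with a control-channel signal-to-noise gate), and
    implements the companion functional-assay normalizations (HTRF
    phospho-STAT plates, western densitometry, delta-delta-Ct expression,
    JAK1 trans-phosphorylation efficiency). A synthetic-data generator
    plants known covalent-occupancy kinetics (k_inact/K_I) so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
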