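Package: synquant
Title: Quantitative Analysis of Inhibitory Synaptic Boutons and IPSC Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inhibitory synaptic transmission from
    fluorescence microscopy and voltage-clamp electrophysiology. Implements
    per-bouton 3D co-localization scoring of presynaptic markers by
    regression R-squared with edge masking and an anticorrelation floor,
    bouton classification and regional composition summaries; kinetic
    analysis of evoked inhibitory postsynaptic currents (trial jitter,
    half-rise time, decay time constant, charge transfer, pharmacological
    component subtraction, gap-junction burst rejection and subtraction,
    stimulus-train dynamics); and miniature-event detection by combined
    first-derivative and integration thresholds. Includes synthetic-data
    generators for multichannel confocal bouton volumes and quantal IPSC
    recordings with known ground truth, so every analysis stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
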