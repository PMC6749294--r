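Package: rptlc
Title: Lipophilicity Descriptors from Reversed-Phase Thin-Layer Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates chromatographic lipophilicity descriptors from
    reversed-phase thin-layer chromatography (RP-TLC) retention data.
    Converts retardation factors to RM values, fits the
    Soczewinski-Wachtmeister linear retention model to obtain RMW and the
    isocratic hydrophobicity index phi0, and fits the Oscik excess-retention
    model on the mole-fraction scale to obtain RMWO. Includes cross-scale
    ordinary least squares regression of computed and experimental
    octanol-water partition coefficients (logP) on chromatographic
    descriptors, prediction of missing experimental logP values,
    hierarchical clustering of descriptor profiles, a synthetic retention
    data generator for validation studies, and bundled descriptor tables
    for fifteen antiparasitic, antihypertensive and anti-inflammatory
    drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
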