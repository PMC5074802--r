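Package: scracmap
Title: Interareal Circuit Mapping: sCRACM Input Maps, Laminar Density
    Ratios and Feedforward Inhibition
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for optogenetic interareal circuit
    mapping in mouse visual cortex. Converts gridded subcellular
    channelrhodopsin-assisted circuit mapping (sCRACM) photostimulation
    recordings into per-cell input maps and PV/Pyr excitation-ratio
    statistics, computes layer 2-4 to layer 1 axonal density ratios and
    the resulting cortical hierarchy ordering from projection images, and
    quantifies PV-to-pyramidal feedforward inhibition from paired
    recordings. Includes a synthetic-data generator with planted ground
    truth for end-to-end validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
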