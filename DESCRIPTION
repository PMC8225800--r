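Package: cycim
Title: Analysis of Cyclic Multiplexed Immunofluorescence Imaging of Neural Cultures
Version: 0.1.0
Authors@R:
    person("cycim", "maintainers", email = "cycim@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of sequential-round (cyclic) multiplexed
    fluorescence imaging of iPSC-derived neural cultures: fiducial-channel
    registration of imaging rounds by phase correlation, nuclei and cell-body
    segmentation with cross-round cell tracking, per-cell marker
    quantification with puncta and filament structural scoring, rule-based
    all-markers-positive gating into cell classes with composition tables,
    QC statistics (signal-to-noise ratio, Pearson correlation, washout
    residual), and design of orthogonal DNA docking/imager strand pairs under
    length, GC-content and melting-temperature constraints. Includes a
    ground-truthed synthetic image-stack generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
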