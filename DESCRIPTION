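Package: netflux
Title: Information Flow and Transductivity in Cellular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of linear state-space models of coupling signal
    transduction pathways and gene regulatory networks from expression data by
    recursive least squares, and estimation of information flow through them.
    Signal transductivity (extracellular signal to protein or transcription
    factor) and information transductivity (gene to gene) are computed as
    system gains: for temporal data via the discrete-time bounded real lemma,
    minimizing the L2-gain bound subject to a linear matrix inequality in a
    Lyapunov matrix; for single-time-point sample data via the static
    transfer matrix (I - C)^-1 B and its singular values. Includes extraction
    of single-input/single-output channels from full networks, an independent
    frequency-sweep gain oracle, two-condition differential comparison of
    transductivity tables, and a synthetic-data module generating ground-truth
    networks and datasets for parameter- and gain-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'identify.R'
    'interface.R'
    'linalg.R'
    'methods.R'
    'netmodel.R'
    'synthdata.R'
    'transduct.R'
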