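Package: hippoquant
Title: Per-Cell Immunofluorescence, Calcium Transient and LTP Series
    Quantification for Hippocampal Plasticity Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for hippocampal synaptic
    plasticity experiments: nuclear-seeded watershed segmentation of
    multichannel confocal micrographs with per-cell mean marker intensity
    extraction, f/f0 normalisation and shape-based classification of
    glutamate-evoked calcium transients, theta-burst stimulation protocol
    bookkeeping with percent-of-baseline fEPSP/LTP window analysis, and the
    accompanying rank-based statistics (Kruskal-Wallis with Dunn's post hoc
    comparisons, exact Mann-Whitney U, one-way ANOVA with Bonferroni
    correction). A ground-truthed synthetic-data generator emulates the
    microscopy, calcium-imaging and electrophysiology inputs so that every
    stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
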