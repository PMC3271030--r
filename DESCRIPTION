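Package: healthspace
Title: Health Space Models for Multi-Omics Intervention Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects subjects of a placebo-controlled cross-over intervention
    study into a low-dimensional "health space" whose axes are predefined
    biological processes (e.g. oxidation, inflammation, metabolism). Each axis
    is parameterized by its own autoscaled, double (nested) cross-validated
    PLS-DA model built from the process's significantly changed plasma
    parameters; out-of-fold prediction scores are scaled so the treated-group
    mean is 0 and the control-group mean is 1 on every axis. Per-subject
    treatment-response vectors (control minus treated score per axis) are
    clustered hierarchically (Euclidean distance, average linkage) to find
    responder subgroups, which are characterized parameter-by-parameter with
    interaction-first two-way ANOVA under Benjamini-Hochberg FDR control.
    Includes a synthetic cross-over study generator with planted responder
    subgroups so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    car,
    ape,
    ggplot2,
    lattice
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
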