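Package: droughtwall
Title: Drought Time-Course Differential Expression and Cell Wall Chemistry
    for Sorghum Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for field drought experiments on Sorghum
    bicolor: filtering and upper-quartile normalization of RNA-seq count
    matrices, per-gene natural-cubic-spline time-course models with
    empirical-Bayes variance moderation and moderated-F tests contrasting
    drought conditions against a watered control, Fisher's-method
    combination of per-genotype p-values with Benjamini-Hochberg
    correction, selection of highly variable genes (top and bottom 5% by
    overall log-fold change) and merging of the eight condition/period
    lists, restriction to cell-wall-related genes via gene-ontology terms
    and a curated list with biosynthesis/modification/signaling
    classification, plus the companion cell-wall chemistry layer:
    calibration-curve quantification of monosaccharides and
    hydroxycinnamates, acetyl-bromide soluble lignin, DNS saccharification
    efficiency, and treatment-versus-control t-test contrasts with FDR
    control. A seeded synthetic-data generator reproduces the field
    design (two genotypes, three irrigation regimes, seventeen weekly
    time points, three replicate plots) with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
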