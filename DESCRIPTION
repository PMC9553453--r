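Package: lrxtalk
Title: Ligand-Receptor Crosstalk Analysis Between Tumor Cells and Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for inferring autocrine and paracrine
    ligand-receptor communication between tumor cells and tumor-associated
    macrophages from coupled single-cell and bulk transcriptomic cohorts.
    Provides marker-based cell-type annotation, a two-part hurdle
    differential-expression test with Benjamini-Hochberg correction,
    concordant ligand-receptor pair screening with bulk Spearman
    coexpression filtering, crosstalk network and hub construction,
    macrophage polarization and permutation-null interaction scoring,
    Kaplan-Meier/log-rank prognostic screening, a gradient-boosted-tree
    stage-risk classifier, and a synthetic-data generator that plants
    recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
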