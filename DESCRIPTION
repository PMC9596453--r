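Package: raftscreen
Title: Pooled Microraft Image-Based Screening with Model-Guided Cell Picking
    and Single-Cell Amplicon Genotyping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled optical screening on microraft plates:
    simulation of per-cell imaging feature tables, two-channel fluorescence
    fields and single-cell amplicon reads; record-level quality gates,
    per-plate robust normalization and leaky-feature exclusion; ensembles of
    binary genotype classifiers with mixture-proportion (meta-feature)
    validation and deterministic pick-model selection; anomaly-detection
    ensembles for CRISPR tiling screens; raft pick-list generation with
    confidence bands; k-mer fragment counting and genotype calling from
    paired amplicon reads; and the evaluation battery joining predictions to
    genotypes (ROC with shuffled-label noise, confidence-threshold metrics,
    Kruskal-Wallis feature ranking, gRNA significance and reproducibility).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    EBImage,
    glmnet,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
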