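Package: protgnn
Title: Protein Abundance Prediction from Single-Cell RNA with
    PPI-Informed Graph Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts surface protein abundances from single-cell RNA
    expression (CITE-seq style paired data) using a graph neural network
    whose protein nodes carry prior knowledge embedded from
    protein-protein interaction score matrices through a two-stage
    attention mechanism.  Provides quality-control filtering and
    train/test splitting of paired matrices, readers for dense and
    MatrixMarket expression files and STRING-style edge lists, a
    synthetic paired multi-omics simulator with known ground truth,
    mean-squared-error training with best-epoch checkpointing, a
    per-protein evaluation protocol (MSE and Pearson correlation,
    best-of-k runs), and prior-knowledge ablation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
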