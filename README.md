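# protgnn

Predicting surface-protein abundance from single-cell RNA expression with a
graph neural network that embeds protein–protein interaction (PPI) prior
knowledge.

## Who this is for

CITE-seq measures RNA and a panel of N surface proteins in the same cells;
most single-cell experiments measure RNA only. `protgnn` learns the mapping
from a cell's (denoised) transcriptome to the protein panel on paired data,
so protein abundances can be imputed for RNA-only cells. Because target
proteins share regulatory mechanisms, the task is treated as multi-label
regression over a protein graph rather than N independent regressions.

## The model

Per cell with G genes and N proteins:

* an RNA encoder (two affine layers G → 1024 → 128, PReLU slope 0.25);
* N per-protein heads 128 → d_r giving V_r ∈ R^{N×d_r} (d_r = 64);
* a knowledge embedding V_k ∈ R^{N×d_k}, d_k = N·d_c (d_c = 32), built from
  M prior score matrices (e.g. STRING evidence channels) by per-protein
  affine encoding, a softmax attention across the M features, a second
  softmax re-weighting across the N proteins, and per-protein concatenation;
* nodes v_i = v_{r_i} ⊕ v_{k_i} ∈ R^d, d = d_r + d_k;
* one propagation round V^e = σ(A·V·W) with trainable dense A ∈ R^{N×N} and
  W ∈ R^{d×d};
* a shared predictor Ŷ = PReLU(FF(V^e)) with negative slope 0.25, so
  negative (CLR-like log-scale) abundances are reachable.

Training minimises the per-cell sum over proteins of squared error
(batch-averaged) with Adam, and keeps the parameters of the epoch with the
smallest training loss (best-epoch checkpointing). Evaluation reports
per-protein MSE and Pearson correlation with mean/SD across proteins, plus a
best-of-k-runs protocol. Forward pass, backpropagation and Adam are written
in base R and verified against finite differences and an independent
transcription of the model equations.

The package also provides: readers for dense CSV/TSV and MatrixMarket
expression files and STRING-style edge lists; cell quality control
(mitochondrial fraction ≥ 20% removed, then cells with ≤ 250 expressed
genes); seeded 70:30 splitting; a synthetic paired-data generator with known
ground truth; prior-knowledge ablations; and a command-line interface
(`inst/cli/protgnn`: `simulate`, `train`, `evaluate`, `predict`, `ablate`).

## Worked example

```r
library(protgnn)

sim <- simulate_citeseq(sim_config(n_cells = 1000, n_genes = 200, seed = 42))
split <- split_cells(rownames(sim$rna), 0.7, seed = 42)
fit <- protein_gnn(sim$rna[split$train, ], sim$protein[split$train, ],
                   priors = sim$priors, config = benchmark_config(epochs = 60),
                   seed = 1)
print(fit)
#> PPI-informed graph neural network for RNA-to-protein prediction
#>   genes: 200  proteins: 10  prior features: 5
#>   encoder 200 -> 128 -> 64; d_r = 16, d_c = 8, d_k = 80, d = 96
#>   checkpoint: epoch 59 of 60 (training loss 2.2236)

evaluate_model(fit, sim$rna[split$test, ], sim$protein[split$test, ])
#> Evaluation over 300 cells, 10 proteins
#>  protein    mse    pcc
#>      P01 0.3329 0.6078
#>      P02 0.2737 0.6387
#>      ...
#>      P10 0.2691 0.6081
#>   MSE  mean 0.2795 (SD 0.0272)
#>   PCC  mean 0.6639 (SD 0.0423)
```

The fit is a classed object with the usual methods — `summary()`, `coef()`,
`predict(fit, new_rna)`, `fitted()`, `residuals()`, `plot()` (loss history
with the checkpointed epoch marked) — plus `save_checkpoint()` /
`load_checkpoint()` for bit-identical reuse. Here the per-protein Pearson
correlations (~0.6–0.7) sit close to the oracle ceiling implied by the
simulation's noise level (`oracle_predictions()` computes it), and the MSE
(~0.28) is near the squared noise SD — the model has extracted most of the
recoverable signal.

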