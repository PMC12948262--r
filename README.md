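# dualDTA

Drug-target binding affinity (DTA) prediction from **paired molecular and
protein graphs** with dynamic graph attention, for computational chemists
and machine-learning practitioners who want a fully inspectable, offline
reference implementation of this architecture family — including its
validation protocol (cross-validation, ablations, Y-scrambling) — in R.

## The model

For a drug–protein pair the package builds two graphs:

* a **molecular graph**: heavy atoms as nodes with provider-supplied
  embeddings (512-D reference), bonds as directed edge pairs with 6-D
  one-hot features `[single, double, triple, aromatic, conjugated,
  hybridization]`;
* a **residue contact graph**: residues as nodes (2560-D reference
  embeddings), edges between Cα pairs within 8 Å (inclusive) weighted by
  the inverse distance 1/d.

Each graph is encoded by a three-layer GATv2 stack. The attention of node
*i* over neighbour *j* (self-loops included) is

    α_ij = softmax_j [ aᵀ LeakyReLU(W¹ [h_i ‖ h_j ‖ e_ij] + b¹) / √d_k ]

and the message update is `h′_i = σ( Σ_j α_ij W² h_j )` with σ = ELU and
mean-pool readout. Static attention (GAT) and attention-free (GCN) layers
are available as ablation variants, as is the literal linear score form
(`as_printed_linear`).

The two graph-level vectors are fused by 8-head self-attention over a
2-token (drug, protein) sequence and concatenated back to 3072-D, then
passed through fully connected layers 3072 → 1280 → 320 → 1 with batch
normalization `x̂ = (x − μ_B)/√(σ_B² + ε)·γ + β` and ReLU after each hidden
projection; the output is linear for regression (pKd, KIBA score) or
sigmoid for classification.

Embeddings and structures come from pluggable **providers**: deterministic
mock providers make the whole pipeline run offline, and
`precomputedProvider()` injects matrices from real pretrained embedders.
Evaluation uses MSE, MAE, Pearson r, the concordance index (CI), and
rm² = r²(1 − √|r² − r0²|); classification adds ACC/AUC/BA/MCC/F1. ECFP4
(2048-bit) Tanimoto similarity is included for scaffold-novelty scoring.

## Worked example

```r
library(dualDTA)

# a synthetic study set: 500 pairs from a 150-drug x 30-protein grid with
# a planted aromaticity x hydrophobicity signal on a pKd-like scale
ds <- generateSyntheticDataset(nPairs = 500, seed = 11)
ds
#> AffinityDataset: 500 records, 147 drugs, 30 proteins; label kinds: pKd

ft <- featurizeDataset(ds, mockAtomProvider(dim = 8, seed = 3),
                       mockResidueProvider(dim = 12, seed = 4))
ft$drugGraphs[[1]]
#> MolecularGraph: C(C)Cc1ccoc1CNNCCO
#>   14 heavy atoms, 28 directed edges, 8-D node features

rep <- crossValidate(ft, k = 5,
                     config = trainConfig(epochs = 60, learningRate = 2e-2,
                                          seed = 1),
                     seed = 1, heads = 2, dModel = 8, nFusionHeads = 2,
                     fclDims = c(24, 12))
rep
#> MetricsReport (regression), 5 folds
#>   fold        2.0000 +- 1.5811
#>   mse         0.1458 +- 0.0218
#>   mae         0.2993 +- 0.0273
#>   pearson_r   0.9525 +- 0.0090
#>   ci          0.9090 +- 0.0114
#>   rm2         0.8439 +- 0.0760
```

The mean test MSE of 0.15 is about 10% of the label variance (1.40), and a
CI of 0.91 means the model orders ~91% of differing-affinity pairs
correctly — the planted two-modality signal is recovered. Scaffold novelty:

```r
tanimotoEcfp4("c1ccccc1", "c1ccccc1C")
#> [1] 0.25
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/dta-cli.R generate --n 500 --seed 7 --out runs/data
Rscript inst/cli/dta-cli.R cv --data runs/data --k 5 --epochs 60 --out runs/cv
Rscript inst/cli/dta-cli.R yscramble --data runs/data --seeds 1..10 --out runs/ys
```

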