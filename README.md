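# stromalcensus

Single-cell census analysis of fibrotic stromal tissue, paired with traction
force cytometry of the same cells' contractility.

Fibrotic lesions such as Dupuytren's nodules are dense ecosystems of
fibroblasts and myofibroblasts. Two questions drive their single-cell
analysis: *which stromal cell types and states are present*, and *whether
myofibroblasts form discrete states or a continuous activation path* between
a resting-like (ACTA2-low) and a fully activated, contractile (CD82-high)
program. Because myofibroblast activation is ultimately mechanical, the
transcriptomic readout is complemented by traction force microscopy (TFM):
inferring the forces single cells exert on a soft substrate from the motion
of embedded fluorescent beads.

`stromalcensus` implements both arms as a tested R/Bioconductor-style
pipeline, together with synthetic-data generators that plant known ground
truth (cell types, a latent activation coordinate, doublets, known traction
fields), so every stage can be validated end to end without any external
data.

## What the package computes

**Expression arm** (on a `SingleCellExperiment`):

- two-round quality control: cells with fewer than 200 detected genes, more
  than 4500 genes, or >10% mitochondrial UMIs are removed; after cell types
  are assigned, cells co-detecting canonical markers of two or more types or
  with a total UMI count above `median + 3 sd` of their type are removed;
- library-size log-normalization
  `x_gc = ln(1 + 10^4 * n_gc / sum_g n_gc)`;
- variable-gene selection by binned dispersion z-scores, exact PCA, and
  **permutation parallel analysis**: component *k* is significant when its
  variance explained exceeds the 95th percentile of the spectra of matrices
  with every gene's values permuted across cells;
- shared nearest-neighbour graph (Jaccard weights on kNN sets) with Louvain
  community detection, and one-vs-rest two-sided Wilcoxon rank-sum marker
  statistics with Benjamini–Hochberg correction;
- **binned control-gene module scores**: the mean expression of a gene set
  minus the mean of a 100-fold larger control set drawn from the same
  expression bins, and the Pearson correlation of those scores with PC1;
- **pseudotime**: a diffusion map over the significant PCs, a
  Hastie–Stuetzle principal curve (lowess smoother, span 1/3) through
  DC1–DC2, per-cell arc-length lambda oriented so the activation module
  increases, and loess-smoothed gene dynamics with standard-error bands.

**Mechanics arm**:

- a Boussinesq elastic half-space forward model producing displacement
  fields from known traction fields (the synthetic ground truth), plus bead
  image rendering;
- particle image velocimetry (window cross-correlation, parabolic sub-pixel
  refinement, peak-ratio validation);
- Fourier-transform traction cytometry (FTTC): per-wavevector inversion of
  `u_hat = G(k) t_hat` with zeroth-order Tikhonov regularization, zero-mean
  force constraint, and an L-curve helper for choosing the regularization
  level (defaults: E = 2550 Pa polyacrylamide, Poisson ratio 0.5);
- per-cell force statistics (mean/max traction, area) and force-signature
  embedding: area-normalized force maps on a common grid, PCA with
  parallel-analysis component selection, SNN/Louvain phenotype labels.

## Worked example

```r
library(stromalcensus)
library(SingleCellExperiment)

# simulate a small fibrotic stromal census with a planted activation continuum
cfg <- simConfig(nCells = 800, nGenes = 1500, continuumFraction = 0.6,
                 doubletRate = 0.05, seed = 42)
sce <- simulateStromalCounts(cfg)

# two-round QC and library-size log-normalization
sce <- filterCells(sce)$sce
sce <- secondRoundQc(sce, markerSets = metadata(sce)$marker_sets)$sce
sce <- logNormalizeCounts(sce)

# variable genes -> PCA -> permutation parallel analysis
emb <- reduceExpression(sce, seed = stageSeed(42, "reduce"))
emb
#> EmbeddingResult: 756 cells x 50 components
#>   variance explained (first 5): 0.234 0.111 0.066 0.062 0.012
#>   significant components: 4

# graph clustering of the major cell types
g  <- buildSnnGraph(pcScores(emb)[, 1:max(2, nSignificant(emb))], k = 30)
cl <- louvainCluster(g, resolution = 0.1, seed = stageSeed(42, "cluster"))
table(clusterLabels(cl), colData(sce)$cell_type)
#>     endothelial fibroblast immune myofibroblast
#>   0          63          0      0             0
#>   1           0        148      0             0
#>   2           0          0      0           237
#>   3           0          0      0           243
#>   4           0          0     65             0

# pseudotime along the myofibroblast activation continuum
idx <- which(colData(sce)$cell_type == "myofibroblast")
sub <- sce[, idx]
subEmb <- reduceExpression(sub, seed = stageSeed(42, "trajectory"))
dm <- diffusionMap(pcScores(subEmb)[, 1:max(2, nSignificant(subEmb))])
tr <- fitPrincipalCurve(dm, span = 1/3)
actB <- moduleScore(sub, intersect(metadata(sce)$generative$programB,
                                   rownames(sub)),
                    seed = stageSeed(42, "score"))
tr <- orientPseudotime(tr, actB)
cor(pseudotime(tr), colData(sub)$activation_t, method = "spearman")
#> [1] 0.9804251
```

Each planted type is recovered as a pure cluster; the myofibroblast
continuum splits into two halves (clusters 2 and 3) exactly as a continuum
must under discrete clustering, and the fitted arc-length pseudotime ranks
cells almost identically to the hidden activation coordinate
(Spearman rho = 0.98).

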