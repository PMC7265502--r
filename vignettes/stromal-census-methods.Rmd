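---
title: "Models and methods behind the stromal census pipeline"
author: "stromalcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the stromal census pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each stage
assumes, the tunable parameters and why their defaults are what they are,
what the synthetic-data generators do and do not emulate, and the numerical
choices that matter when reproducing results.

# The biological setting

Fibrotic stromal tissue houses fibroblasts, myofibroblasts, immune and
endothelial cells. Myofibroblasts — contractile, matrix-producing cells
marked by alpha-smooth-muscle actin (ACTA2) — are the main effectors of
fibrosis, and a central question is whether they occupy discrete states or a
one-dimensional *activation continuum* running from an ACTA2-low,
fibroblast-like program to a CD82-high, strongly contractile program. The
package analyses this question on two coupled levels: transcriptome
(droplet scRNA-seq counts) and mechanics (traction force cytometry).

# The synthetic census generator

`simulateStromalCounts()` draws each cell's UMI vector multinomially:

* library size `L ~ round(LogNormal(log 2500, 0.35))` — a typical droplet
  channel depth;
* per-cell gene probabilities come from the cell type's expression profile,
  built from a heavy-tailed Gamma(0.45) baseline;
* each type owns a small panel of canonical markers (10 genes, boosted
  12-fold in the owning type and suppressed to 0.1% of baseline elsewhere —
  canonical markers are informative for doublet detection precisely because
  they are selectively expressed);
* continuum cells draw a latent activation coordinate `t ~ Uniform(0, 1)`
  and use `p(t) = (1 - t) pA + t pB`, the convex combination of the two
  terminal program profiles (75 genes each, boosted 10-fold). Linear
  interpolation in probability space is the simplest generative model whose
  per-gene expected counts are monotone in `t`, which is the property the
  trajectory stage is meant to recover;
* mitochondrial genes (1.5% of genes) carry 5% of every cell's expression
  mass; doublets (5% of barcodes) are sums of two randomly chosen parents'
  count vectors, the standard simulation convention.

Default composition mirrors a fibrotic nodule: ~60% myofibroblasts
(the continuum type) with fibroblast, immune and endothelial cells filling
the remainder; 3000 cells per simulated channel, within the 1500–6000 range
a droplet channel recovers.

What the generator does **not** emulate: batch effects (batch correction is
out of scope), ambient RNA, cell-cycle structure, overdispersion beyond the
multinomial, or gene–gene correlation within a program beyond the shared
`t`. Passing tests therefore certify the pipeline's algorithmic behaviour
on data satisfying its own model assumptions, not robustness to every
artifact of real tissue.

All randomness flows from one root seed through fixed per-stage substreams
(`stageSeed()`), so a pipeline run is reproducible from a single integer.

# Quality control and normalization

First-round QC removes cells detecting fewer than 200 genes (strict), more
than 4500 genes (strict), or with a mitochondrial UMI fraction above 10%
(strict) — boundary cells are kept. Second-round QC runs after cell types
are assigned: a cell is removed when markers of at least two types are
detected (at least 1 UMI each, the detection threshold being an exposed
parameter), or when its total UMI count exceeds the type median by more
than three within-type sample standard deviations. Marker sets must be
disjoint across types, otherwise the co-detection rule is ill-posed and the
function refuses to run.

Normalization is `ln(1 + 10^4 * count / total)` — natural log, scale factor
representing a median library complexity of 10,000. Zeros map to zeros, so
sparsity is preserved. Scaling for PCA is per-gene z-scoring with the
sample-variance convention, zero-variance genes mapped to zero rows, and
values clipped at ±10 SD to bound outlier leverage.

# Dimension reduction

Variable genes: per-gene mean and variance/mean dispersion are computed on
back-transformed (`expm1`) values, then moved to the log scale
(`log1p(mean)`, `log(var/mean)`) — the scale on which the conventional
admissible-mean window (0.1, 8) and the within-bin dispersion z-score
cutoff (z >= 1, 20 equal-width bins) are defined. Bins with fewer than two
genes are merged downward so every z-score exists.

PCA is an exact truncated SVD of the centred cells-by-genes matrix.
Component signs are fixed by making each component's largest-magnitude
loading positive; reported variance fractions are relative to total
variance, so they sum to 1 at full rank.

Parallel analysis permutes each gene's values across cells (preserving
per-gene marginals, destroying all correlation), recomputes the
variance-explained spectrum `nPerm` times, and declares component *k*
significant when its observed variance explained exceeds the permuted 95th
percentile for component *k*. The returned count is the longest prefix of
consecutive significant components, because downstream stages consume the
significant components as a leading block. Two calibration facts worth
knowing: on exchangeable noise each run has roughly an `alpha` chance of
flagging one spurious component (the observed top eigenvalue is
exchangeable with the permuted ones), and on strongly low-rank data the
*trailing* observed components legitimately fall below the permuted
spectrum, so "alpha to 1 makes everything significant" holds only for
noise-like data.

# Clustering and markers

The shared nearest-neighbour graph uses Euclidean kNN (k = 30, neighbour
sets including the cell itself, ties broken by index) with Jaccard-overlap
edge weights pruned below 1/15. Louvain community detection maximizes
resolution-parameterized modularity; the package default resolution is 0.8,
the common tool default. Resolution controls granularity by design: at 0.8
large homogeneous populations subdivide (useful for state discovery), while
the *major-type* pass of a two-level analysis — delineate major types
first, then subcluster each — is run at a coarse resolution (0.1 in the
package's own end-to-end checks), which recovers well-separated planted
types essentially perfectly at n = 2000.

Markers use the two-sided Wilcoxon rank-sum test, one cluster against the
rest: the exact distribution when both groups have at most 25 cells and the
gene is tie-free, otherwise the tie-corrected normal approximation with
continuity correction. BH adjustment is applied across genes within each
cluster contrast. The reported log fold-change is the difference of
`ln(mean(expm1(x)) + 1)` between cluster and rest, so its sign always
matches the difference of back-transformed means.

# Module scores and the PC1 correlation

A gene module (e.g. the 100 genes most Spearman-correlated with an anchor
such as ACTA2 or CXCL14; the anchor trivially included at rho = 1, ties
broken by gene id) is scored per cell as mean module expression minus the
mean of an expression-matched control set: genes are binned into 25
equal-frequency bins of mean expression, and for each module gene 100
control genes are drawn uniformly from its bin. Equal-frequency binning
guarantees non-empty bins; control draws exclude the module genes
themselves, which keeps the score an exact linear functional of the data
(shifting all module genes by delta shifts the score by exactly delta) and
avoids diluting the contrast; draws are without replacement unless a bin is
too small, and the fallback is recorded. The control set is 100-fold larger
than the module, so its mean behaves like an average over 100 random
size-matched sets and removes library-complexity effects.

`pc1ModuleCorrelation()` is a plain Pearson correlation between per-cell
PC1 scores and module scores. Its sign is only meaningful jointly with the
PC sign convention; the scientifically stable statement is the *opposite
signs* of the activation-program and resting-program modules when PC1 is
the activation axis, which the synthetic continuum reproduces.

# Trajectory inference

The diffusion map builds a Gaussian kernel on Euclidean distances between
cells in significant-PC space. The bandwidth defaults to the median
distance to the 10th nearest neighbour — a global median heuristic chosen
over per-cell adaptive bandwidths for simplicity and determinism (a
documented deviation from tools with local sigmas). Density normalization
uses the anisotropic alpha = 1 convention, removing sampling-density
effects; the trivial constant eigenvector is dropped; diffusion components
are eigenvalue-scaled eigenvectors. All eigenvalues of this construction
lie in (0, 1], and the embedding depends on the input only through
distances, hence is invariant to rigid motions.

The principal curve follows Hastie–Stuetzle: initialize lambda on the first
principal component of the DC1–DC2 cloud, then alternate projection onto
the current polyline with per-coordinate `lowess` smoothing against lambda
at span 1/3, until the total squared projection distance changes by less
than `tol = 1e-4` (relative, with an absolute floor of 1e-12 times the
total variance so that interpolating fits terminate) or 50 iterations
(returning the best fit with a warning — oscillation at the fourth decimal
of the residual is common and harmless). Pseudotime lambda is the
arc-length of each cell's projection foot from the curve start.

Orientation is arbitrary for any fitted curve, so `orientPseudotime()`
flips lambda when its Spearman correlation with an activation module score
is negative; |rho| < 0.1 is flagged ambiguous rather than silently chosen.
Gene dynamics along pseudotime are loess fits (quadratic, span 0.5) with
pointwise standard errors on a 100-point uniform grid; one smoother is
supported and documented rather than mixing alternatives.

# Traction force cytometry

The mechanical forward model is the Boussinesq elastic half-space: in
Fourier space the surface displacement and traction fields are related per
wavevector by the 2x2 tensor

```
G(k) = 2 (1 + nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky
                                -nu kx ky,              (1-nu) k^2 + nu kx^2 ]
```

Defaults are E = 2550 Pa (soft polyacrylamide TFM gel) and nu = 0.5 — the
incompressible limit, the standard assumption for polyacrylamide when only
E is known. Synthetic scenes build tractions as sums of Gaussian force
foci; physically meaningful scenes are force-balanced (cells exert zero net
force), and the package's reference benchmark is a contraction dipole
(two opposed 400 Pa foci, sigma 3 px, 10 px apart on a 128 px field at
1 um/px). Both forward and inverse transforms zero-pad by a factor of 2 to
suppress periodic wrap-around, and the zero-frequency component is set to
zero, which removes rigid drift and enforces force balance exactly on the
padded grid (a small residual survives the crop). The forward model was
validated against direct real-space summation of the Cerruti surface
Green's function.

FTTC inversion applies the Tikhonov-regularized inverse
`(G'G + lambda^2 I)^{-1} G'` per wavevector. With `lambda = 0` the
inversion recovers the reference scene's tractions to ~5% relative L2
error; the residual comes from displacement truncation at the field of
view, not from the inversion itself. Under heavy noise (SD 10% of the peak
displacement) an optimal lambda on a log grid restores the masked mean
cell traction to within 20%; `fttcLcurve()` implements the conventional
L-curve corner (triangle method) as a default chooser, which lands in the
interior of the scanned range but is not guaranteed optimal.

PIV uses square interrogation windows (32 px, 50% overlap by default),
circular cross-correlation via FFT, and three-point parabolic sub-pixel
refinement per axis. Windows whose correlation peak is not at least 1.5
times the second peak (outside the peak's 3x3 neighbourhood) are masked
invalid and gap-filled by neighbour averaging before inversion. A global
circular shift with a whole-image window is recovered exactly (the
cross-correlation of a signal with its shift is even around the true lag);
windowed tracking of rendered bead scenes achieves median vector errors of
a few hundredths of a pixel.

Force signatures divide each cell's traction-magnitude map by its area,
resample to a common 32x32 grid (the feature vector being otherwise
underdetermined, this is a declared choice), z-score features, run PCA with
the same permutation parallel analysis, and label phenotypes by
SNN/Louvain on the significant components. The 2-D display embedding is
the first two components.

# Problem sizes in the shipped checks

The package's own test suite runs the full census at 2000 cells x 2000
genes (cluster recovery, three seeds), the continuum recovery at ~500
continuum cells (three seeds), parallel-analysis calibration at 200 genes x
300 cells with 100 permutations, and the TFM benchmarks on 128 px fields
with ~1200 beads — sizes chosen so the complete suite runs in about a
minute on one core while keeping every estimate's sampling error well below
the tested margins.

# Known limitations

* The generator's multinomial noise is thinner-tailed than real droplet
  data; dispersion-based gene selection is therefore easier than in
  practice.
* Pseudotime assumes a single non-branching path; branching topologies and
  RNA-velocity directionality are out of scope.
* The FTTC model assumes an infinitely thick, linear, homogeneous
  substrate; finite-thickness corrections and 3-D tractions are not
  implemented.
* Second-round QC requires genuinely disjoint canonical marker panels;
  overlapping panels must be resolved by the analyst beforehand.
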