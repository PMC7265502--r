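# shared fixture builders; everything is generated in code at test time

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# SCE from a dense counts matrix, with optional mito flags
makeCountSce <- function(counts, mitoGenes = character(0)) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  sce <- SingleCellExperiment(
    assays = list(counts = as(as.matrix(counts), "CsparseMatrix")))
  rowData(sce)$is_mito <- rownames(sce) %in% mitoGenes
  sce
}

# SCE with a logcounts assay set directly
makeLogSce <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  sce <- SingleCellExperiment(assays = list(logcounts = as.matrix(values)))
  sce
}

# Poisson background SCE, log-normalized
poissonSce <- function(nGenes, nCells, lambda = 2, seed = 1) {
  counts <- withr::with_seed(seed,
    matrix(rpois(nGenes * nCells, lambda), nGenes, nCells))
  counts[, colSums(counts) == 0] <- 1  # guard empty cells at tiny sizes
  logNormalizeCounts(makeCountSce(counts))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# construct a single cell column with a stated detected-gene count,
# total UMIs and mitochondrial UMIs; mito pool = genes 1..40
constructedCell <- function(nGenesTotal, detected, totalUmi, mitoUmi) {
  col <- integer(nGenesTotal)
  if (detected == 0) return(col)
  nMitoGenes <- min(mitoUmi, 40)
  if (nMitoGenes > 0) {
    col[seq_len(nMitoGenes)] <- 1L
    col[1] <- col[1] + (mitoUmi - nMitoGenes)
  }
  nOther <- detected - nMitoGenes
  rest <- totalUmi - mitoUmi
  stopifnot(rest >= nOther, nOther >= 1)
  idx <- 41:(40 + nOther)
  col[idx] <- 1L
  col[idx[1]] <- rest - (nOther - 1L)
  col
}

# standard synthetic TFM benchmark: contraction dipole on a 128 px field
referenceScene <- function(noiseSdUm = 0, seed = 1) {
  fs <- data.frame(row = c(59, 69), col = c(64, 64), sigma = 3,
                   peakPa = 400, dirX = 0, dirY = c(1, -1))
  simulateTractionScene(c(128, 128), pixelSizeUm = 1, youngsModulusPa = 2550,
                        poissonRatio = 0.5, forceSpec = fs,
                        noiseSdUm = noiseSdUm, seed = seed)
}

# planted force phenotypes: focal high-force vs diffuse low-force cells
phenotypeForceMap <- function(phenotype, seed) {
  withr::with_seed(seed, {
    if (phenotype == "focal") {
      nf <- sample(3:5, 1)
      fs <- data.frame(row = runif(nf, 20, 44), col = runif(nf, 20, 44),
                       sigma = runif(nf, 1.5, 2.5),
                       peakPa = runif(nf, 500, 900),
                       dirX = rnorm(nf), dirY = rnorm(nf))
    } else {
      nf <- sample(6:9, 1)
      fs <- data.frame(row = runif(nf, 16, 48), col = runif(nf, 16, 48),
                       sigma = runif(nf, 4, 6),
                       peakPa = runif(nf, 80, 150),
                       dirX = rnorm(nf), dirY = rnorm(nf))
    }
    sc <- simulateTractionScene(c(64, 64), forceSpec = fs,
                                noiseSdUm = 0.005, seed = seed)
    tractionMagnitude(sc)
  })
}
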