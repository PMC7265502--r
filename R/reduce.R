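#' Select highly variable genes by binned dispersion
#'
#' Computes per-gene mean and dispersion (variance / mean) on the
#' back-transformed (`expm1`) log-normalized values, then works on the log
#' scale -- mean metric `log1p(mean)` and dispersion metric `log(var/mean)`,
#' the scale on which the conventional cutoffs (0.1, 8) are defined. Genes
#' are binned into `nBins` equal-width bins of the mean metric, dispersions
#' are z-scored within each bin, and genes with a dispersion z-score of at
#' least `dispersionZMin` and mean metric strictly inside
#' `(meanLow, meanHigh)` are returned. Bins holding fewer than two genes are
#' merged into their lower neighbour so every z-score is defined.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay.
#' @param nBins number of mean-expression bins (default 20).
#' @param dispersionZMin dispersion z-score cutoff (default 1).
#' @param meanLow,meanHigh open interval of admissible mean expression
#'   (defaults 0.1 and 8).
#' @return character vector of selected gene ids.
#' @export
findVariableGenes <- function(sce, nBins = 20, dispersionZMin = 1,
                              meanLow = 0.1, meanHigh = 8) {
  if (ncol(sce) < 2) stop("at least two cells are required")
  vals <- expm1(SummarizedExperiment::assay(sce, "logcounts"))
  muRaw <- Matrix::rowMeans(vals)
  v <- rowVarsSparse(vals)
  mu <- log1p(muRaw)
  disp <- ifelse(muRaw > 0 & v > 0, log(v / muRaw), NA_real_)
  ok <- which(!is.na(disp))
  if (!length(ok)) return(character(0))

  bins <- as.integer(cut(mu[ok], breaks = nBins, include.lowest = TRUE))
  # merge undersized bins downward so each bin supports a z-score
  repeat {
    tab <- table(factor(bins, levels = sort(unique(bins))))
    small <- as.integer(names(tab)[tab < 2])
    if (!length(small)) break
    b <- small[1]
    lower <- max(c(unique(bins)[unique(bins) < b], -Inf))
    target <- if (is.finite(lower)) lower else min(unique(bins)[unique(bins) > b])
    bins[bins == b] <- target
  }

  z <- rep(NA_real_, length(ok))
  for (b in unique(bins)) {
    i <- bins == b
    m <- mean(disp[ok][i])
    s <- stats::sd(disp[ok][i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[ok][i] - m) / s
  }
  sel <- ok[z >= dispersionZMin & mu[ok] > meanLow & mu[ok] < meanHigh]
  rownames(sce)[sel]
}

#' Principal component analysis of a scaled expression matrix
#'
#' Exact truncated singular value decomposition of the (column-centred)
#' cells x genes matrix. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are fully deterministic.
#'
#' @param scaled genes x cells matrix from [scaleGenes()].
#' @param nComponents number of components to retain (default 50, capped at
#'   `min(cells - 1, genes)`).
#' @return an [EmbeddingResult-class]; `varianceExplained` is relative to the
#'   total variance of the input, so it sums to 1 when the full rank is kept.
#' @export
runPCA <- function(scaled, nComponents = 50) {
  x <- t(as.matrix(scaled))  # cells x genes
  if (nrow(x) < 2) stop("at least two cells are required for PCA")
  x <- sweep(x, 2, colMeans(x))
  k <- min(nComponents, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  d2 <- sv$d^2
  if (sum(d2) == 0) stop("input matrix has no variance")
  ve <- (d2 / sum(d2))[seq_len(k)]
  u <- sv$u
  v <- sv$v
  for (j in seq_len(k)) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(k)))
  new("EmbeddingResult", scores = scores, loadings = v,
      varianceExplained = ve, nSignificant = NA_integer_,
      genesUsed = colnames(x) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# variance-explained spectrum (all components) of a genes x cells matrix
pcaSpectrum <- function(scaled) {
  x <- t(scaled)
  x <- sweep(x, 2, colMeans(x))
  d2 <- svd(x, nu = 0, nv = 0)$d^2
  d2 / sum(d2)
}

#' Permutation parallel analysis for significant components
#'
#' For each of `nPerm` permutations, the entries of every gene row are
#' independently permuted across cells -- preserving each gene's marginal
#' distribution while destroying gene-gene and cell-cell structure -- and the
#' variance-explained spectrum is recomputed. Component k is significant when
#' its observed variance explained exceeds the `(1 - alpha)` quantile of the
#' permuted values for component k. The returned count is the length of the
#' leading run of consecutive significant components, since downstream steps
#' consume the significant components as a prefix block.
#'
#' @param scaled genes x cells matrix from [scaleGenes()].
#' @param nPerm number of permutations (default 100, minimum 20).
#' @param alpha tail probability (default 0.05); larger alpha can only
#'   increase the count.
#' @param seed RNG seed.
#' @param nComponents cap on the number of components tested (default: all).
#' @return integer number of significant leading components (possibly 0).
#' @export
permutationPA <- function(scaled, nPerm = 100, alpha = 0.05, seed = 1,
                          nComponents = NULL) {
  if (nPerm < 20) stop("at least 20 permutations are required")
  obs <- pcaSpectrum(scaled)
  k <- min(length(obs), nComponents %||% length(obs))
  obs <- obs[seq_len(k)]
  perm <- withr::with_seed(seed, {
    vapply(seq_len(nPerm), function(b) {
      xp <- scaled
      for (g in seq_len(nrow(xp))) xp[g, ] <- xp[g, sample.int(ncol(xp))]
      pcaSpectrum(xp)[seq_len(k)]
    }, numeric(k))
  })
  if (k == 1) perm <- matrix(perm, nrow = 1)
  thr <- apply(perm, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  sig <- obs > thr
  firstFail <- match(FALSE, sig)
  if (is.na(firstFail)) k else firstFail - 1L
}
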