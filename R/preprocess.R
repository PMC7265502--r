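#' First-round cell quality control
#'
#' Removes poor-quality cells: those detecting fewer than `minGenes` genes,
#' more than `maxGenes` genes (putative doublets), or with more than
#' `maxMitoFrac` of their UMIs mapping to mitochondrial genes. All three
#' bounds are strict on the removal side, so a cell detecting exactly
#' `minGenes` genes, or with a mitochondrial fraction exactly at the cap,
#' is kept.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay and an `is_mito`
#'   logical column in `rowData`.
#' @param minGenes,maxGenes detected-gene bounds (defaults 200 and 4500).
#' @param maxMitoFrac mitochondrial UMI fraction cap (default 0.10).
#' @return list with the filtered `sce` and a [QcReport-class].
#' @export
filterCells <- function(sce, minGenes = 200, maxGenes = 4500,
                        maxMitoFrac = 0.10) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  rd <- SummarizedExperiment::rowData(sce)
  if (!"is_mito" %in% colnames(rd) || !any(rd$is_mito))
    stop("no mitochondrial genes are flagged; mitochondrial QC cannot run")
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[rd$is_mito, , drop = FALSE])
  mitoFrac <- ifelse(total > 0, mito / total, 0)

  lowGenes <- detected < minGenes
  highGenes <- detected > maxGenes
  highMito <- mitoFrac > maxMitoFrac
  keep <- !(lowGenes | highGenes | highMito)

  report <- new("QcReport",
    nIn = ncol(sce), nOut = sum(keep),
    rules = data.frame(
      rule = c("fewer than minGenes detected", "more than maxGenes detected",
               "mitochondrial fraction above cap"),
      flagged = c(sum(lowGenes), sum(highGenes), sum(highMito))),
    thresholds = list(minGenes = minGenes, maxGenes = maxGenes,
                      maxMitoFrac = maxMitoFrac))
  list(sce = sce[, keep], report = report)
}

#' Second-round, within-cell-type quality control
#'
#' After cell types have been assigned, removes (a) cells co-detecting
#' canonical markers of two or more distinct cell types (putative doublets or
#' contaminants) and (b) cells whose total UMI count exceeds the cell-type
#' median by more than `sdMult` within-type standard deviations.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param labels per-cell type labels; defaults to `colData(sce)$cell_type`.
#' @param markerSets named list (one entry per type, >= 2 types) of canonical
#'   marker gene ids; sets must be disjoint across types.
#' @param sdMult multiplier on the within-type standard deviation (default 3).
#' @param minCount UMI count at which a marker counts as detected (default 1).
#' @return list with the filtered `sce` and a [QcReport-class].
#' @export
secondRoundQc <- function(sce, labels = NULL, markerSets, sdMult = 3,
                          minCount = 1) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (is.null(labels)) labels <- SummarizedExperiment::colData(sce)$cell_type
  if (length(labels) != ncol(sce) || anyNA(labels))
    stop("every cell must carry a type label")
  if (length(markerSets) < 2)
    stop("at least two cell-type marker sets are required")
  allMk <- unlist(markerSets)
  if (anyDuplicated(allMk))
    stop("marker sets overlap across types; the co-detection rule is ambiguous")
  missing <- setdiff(allMk, rownames(sce))
  if (length(missing))
    stop("marker genes absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "))

  detectedSets <- vapply(markerSets, function(mk) {
    Matrix::colSums(counts[mk, , drop = FALSE] >= minCount) > 0
  }, logical(ncol(sce)))
  if (is.null(dim(detectedSets)))  # single cell edge case
    detectedSets <- matrix(detectedSets, nrow = 1)
  multiMarker <- rowSums(detectedSets) >= 2

  total <- Matrix::colSums(counts)
  highUmi <- rep(FALSE, ncol(sce))
  for (ty in unique(labels)) {
    idx <- which(labels == ty)
    s <- stats::sd(total[idx])
    if (is.na(s)) s <- 0  # single-cell type
    thr <- stats::median(total[idx]) + sdMult * s
    highUmi[idx] <- total[idx] > thr
  }

  keep <- !(multiMarker | highUmi)
  report <- new("QcReport",
    nIn = ncol(sce), nOut = sum(keep),
    rules = data.frame(
      rule = c("markers of >= 2 cell types detected",
               "total UMI above median + sdMult * sd of cell type"),
      flagged = c(sum(multiMarker), sum(highUmi))),
    thresholds = list(sdMult = sdMult, minCount = minCount))
  list(sce = sce[, keep], report = report)
}

#' Library-size log-normalization
#'
#' Divides each cell's UMI counts by its total, multiplies by a scale factor
#' representing the median library complexity, and takes the natural log of
#' one plus the result: `value = ln(1 + scaleFactor * count / total)`.
#' Zeros map to zeros, so the sparsity pattern is preserved.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay; all cells must
#'   have positive totals (run [filterCells()] first).
#' @param scaleFactor scaling constant (default 10000).
#' @return the object with a `logcounts` assay added.
#' @export
logNormalizeCounts <- function(sce, scaleFactor = 10000) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  total <- Matrix::colSums(counts)
  if (any(total == 0))
    stop("cells with zero total UMI present; filter cells before normalizing")
  norm <- counts %*% Matrix::Diagonal(x = scaleFactor / total)
  lc <- log1p(norm)
  dimnames(lc) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  S4Vectors::metadata(sce)$normalization <-
    list(scheme = "log1p(scaleFactor * count / total)",
         scaleFactor = scaleFactor, log_base = exp(1))
  sce
}

#' Centre and scale genes for PCA
#'
#' Per-gene z-scoring of the log-normalized values (sample-variance
#' convention), with zero-variance genes mapped to all-zero rows and values
#' clipped at `+/- maxAbs` to bound the leverage of outlier cells.
#'
#' @param x `SingleCellExperiment` with a `logcounts` assay, or a genes x
#'   cells numeric matrix.
#' @param genes optional subset of gene ids (e.g. the variable genes).
#' @param maxAbs clip bound in SD units (default 10).
#' @return dense genes x cells matrix of scaled values.
#' @export
scaleGenes <- function(x, genes = NULL, maxAbs = 10) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "logcounts") else x
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 2) stop("at least two cells are required for scaling")
  m <- as.matrix(m)
  mu <- rowMeans(m)
  s <- sqrt(rowVarsSparse(m))
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out[out > maxAbs] <- maxAbs
  out[out < -maxAbs] <- -maxAbs
  out
}
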