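#' Build a gene module from correlation with an anchor gene
#'
#' Ranks all genes by their Spearman (or Pearson) correlation with the anchor
#' gene's per-cell log-normalized values and returns the top `nTop`,
#' tie-broken by gene id. The anchor is trivially its own best correlate
#' (rho = 1) and is always a member.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay.
#' @param anchorGene gene id to anchor the module on (e.g. the activation
#'   marker ACTA2 or the fibroblast-like marker CXCL14).
#' @param nTop module size (default 100).
#' @param method "spearman" (default) or "pearson".
#' @param name module name (defaults to the anchor gene).
#' @return a [GeneModule-class].
#' @export
buildCorrelatedModule <- function(sce, anchorGene, nTop = 100,
                                  method = c("spearman", "pearson"),
                                  name = anchorGene) {
  method <- match.arg(method)
  x <- SummarizedExperiment::assay(sce, "logcounts")
  if (!anchorGene %in% rownames(x)) stop("anchor gene not in matrix: ", anchorGene)
  anchor <- as.numeric(x[anchorGene, ])
  if (sum(anchor > 0) < 3)
    stop("anchor gene must be expressed in at least 3 cells")
  if (stats::sd(anchor) == 0)
    stop("anchor gene is constant; correlation is undefined")
  rho <- suppressWarnings(
    as.numeric(stats::cor(t(as.matrix(x)), anchor, method = method)))
  names(rho) <- rownames(x)
  rho[is.na(rho)] <- -Inf  # constant genes can never enter
  ord <- order(-rho, names(rho))
  genes <- names(rho)[ord][seq_len(min(nTop, length(rho)))]
  new("GeneModule", name = name, anchorGene = anchorGene,
      genes = genes, method = method)
}

# equal-frequency expression bins over genes; returns integer bin per gene
expressionBins <- function(mu, nBins) {
  r <- rank(mu, ties.method = "first")
  as.integer(ceiling(nBins * r / length(mu)))
}

#' Binned control-gene module score
#'
#' Scores each cell as the mean log-normalized expression of the module genes
#' minus the mean of an expression-matched control gene set. All genes are
#' binned by average expression into `nBins` equal-frequency bins; for every
#' module gene, `genesPerBin` control genes are drawn uniformly from its bin
#' (module genes excluded; without replacement when the bin is large enough,
#' with replacement otherwise). The control set is therefore `genesPerBin`
#' times larger than the module and has a comparable expression-level
#' distribution, which removes library-complexity effects from the score.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay.
#' @param module a [GeneModule-class] or character vector of gene ids.
#' @param nBins number of expression bins (default 25).
#' @param genesPerBin control genes drawn per module gene (default 100).
#' @param seed RNG seed for the control draw.
#' @param controls optional pre-drawn control gene multiset (character,
#'   possibly with repeats); when supplied, no drawing happens, which makes
#'   the score an exact linear functional of the data.
#' @param returnControls return a list carrying the control draw.
#' @return numeric per-cell score vector; or, when `returnControls = TRUE`,
#'   `list(score, controls, binSummary)`.
#' @export
moduleScore <- function(sce, module, nBins = 25, genesPerBin = 100, seed = 1,
                        controls = NULL, returnControls = FALSE) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  genes <- if (methods::is(module, "GeneModule")) module@genes else module
  absent <- setdiff(genes, rownames(x))
  if (length(absent))
    stop("module gene absent from matrix: ", paste(head(absent, 5), collapse = ", "))

  withReplacement <- FALSE
  if (is.null(controls)) {
    mu <- Matrix::rowMeans(x)
    bins <- expressionBins(mu, nBins)
    names(bins) <- rownames(x)
    controls <- character(0)
    for (g in genes) {
      candidates <- setdiff(names(bins)[bins == bins[[g]]], genes)
      if (!length(candidates))
        stop("no control candidates left in the bin of gene ", g)
      useRep <- length(candidates) < genesPerBin
      withReplacement <- withReplacement || useRep
      drawn <- withr::with_seed(stageSeed(seed, "score") + match(g, genes),
                                sampleExact(candidates, genesPerBin,
                                            replace = useRep))
      controls <- c(controls, drawn)
    }
  }
  idxModule <- match(genes, rownames(x))
  idxControl <- match(controls, rownames(x))
  score <- Matrix::colMeans(x[idxModule, , drop = FALSE]) -
           Matrix::colMeans(x[idxControl, , drop = FALSE])
  score <- as.numeric(score)
  names(score) <- colnames(x)
  if (returnControls)
    list(score = score, controls = controls,
         binSummary = list(nBins = nBins, genesPerBin = genesPerBin,
                           withReplacement = withReplacement))
  else score
}

#' Pearson correlation between PC1 and a module score
#'
#' The per-cell first principal component score is correlated against the
#' module score. The sign is meaningful only jointly with the PC sign
#' convention (largest-magnitude loading positive, see [runPCA()]): an
#' activation module and a resting-state module are expected to correlate
#' with PC1 with opposite signs when the leading axis of variation is the
#' activation continuum.
#'
#' @param embedding an [EmbeddingResult-class] (or cells x k score matrix).
#' @param score per-cell module score from [moduleScore()].
#' @return Pearson correlation coefficient.
#' @export
pc1ModuleCorrelation <- function(embedding, score) {
  s <- if (methods::is(embedding, "EmbeddingResult"))
    pcScores(embedding)[, 1] else embedding[, 1]
  if (length(s) != length(score)) stop("score and embedding cover different cells")
  if (stats::sd(s) == 0 || stats::sd(score) == 0)
    stop("zero-variance input; correlation is undefined")
  stats::cor(s, score)
}
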