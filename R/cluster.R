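#' Shared nearest-neighbour graph with Jaccard edge weights
#'
#' Builds the k-nearest-neighbour graph (Euclidean distance, each cell's
#' neighbour set including itself; ties broken by cell index) and weights the
#' edge between two cells by the Jaccard index of their neighbour sets.
#' Edges with weight below `pruneThreshold` are removed.
#'
#' @param scores cells x components matrix, typically the significant-PC
#'   block of an [EmbeddingResult-class].
#' @param k neighbourhood size (default 30).
#' @param pruneThreshold minimum retained Jaccard weight (default 1/15).
#' @return an undirected weighted [igraph::graph] with one vertex per cell.
#' @export
buildSnnGraph <- function(scores, k = 30, pruneThreshold = 1 / 15) {
  n <- nrow(scores)
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(scores))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    # order() is stable, so equidistant points resolve by index
    nn[i, ] <- order(d[i, ])[seq_len(k)]
  }
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(t(nn)), x = 1,
                              dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)       # |N(i) intersect N(j)|
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)        # |A n B| / |A u B|, |A|=|B|=k
  jac@x[jac@x < pruneThreshold] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  if (!is.null(rownames(scores)))
    igraph::V(g)$name <- rownames(scores)
  g
}

#' Louvain community detection on an SNN graph
#'
#' Modularity maximization by iterated local moving and graph aggregation,
#' with a resolution parameter scaling the null-model term. Disconnected
#' components are partitioned independently. Deterministic given the seed.
#'
#' @param graph weighted graph from [buildSnnGraph()].
#' @param resolution modularity resolution (default 0.8); larger values give
#'   more, smaller clusters.
#' @param seed RNG seed for the node sweep order.
#' @return a [ClusterResult-class] with 0-based contiguous labels.
#' @export
louvainCluster <- function(graph, resolution = 0.8, seed = 1) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(graph, resolution = resolution))
  memb <- as.integer(igraph::membership(cl))
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  new("ClusterResult",
      labels = labels,
      modularity = max(igraph::modularity(cl)),
      resolution = resolution,
      nEdges = as.integer(igraph::ecount(graph)))
}

# Two-sided Wilcoxon rank-sum p-value for one gene given precomputed ranks
# over all cells. Exact distribution when both groups are small and tie-free
# (the classical tables); tie-corrected normal approximation with continuity
# correction otherwise.
rankSumP <- function(r, inGroup, tieTerm, exactOk) {
  n <- length(r)
  n1 <- sum(inGroup)
  n2 <- n - n1
  W <- sum(r[inGroup])
  U <- W - n1 * (n1 + 1) / 2
  if (exactOk && n1 <= 25 && n2 <= 25) {
    if (U > n1 * n2 / 2) {
      p <- 2 * (1 - stats::pwilcox(U - 1, n1, n2))
    } else {
      p <- 2 * stats::pwilcox(U, n1, n2)
    }
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' One-vs-rest Wilcoxon marker statistics
#'
#' For each cluster, tests every gene with a two-sided Wilcoxon rank-sum test
#' of that cluster's cells against all others, applies Benjamini-Hochberg
#' adjustment across genes within the cluster contrast, and reports genes
#' passing the adjusted-p and expression-fraction filters. The log
#' fold-change is the difference of `ln(mean(expm1(values)) + 1)` between the
#' cluster and the rest, so its sign always agrees with the difference of
#' back-transformed cluster means.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay, or a genes x
#'   cells matrix of log-normalized values.
#' @param labels per-cell cluster labels (any atomic type).
#' @param minPct minimum expressing fraction in the target cluster
#'   (default 0.1).
#' @param pAdjustMax adjusted-p cutoff (default 0.01); use 1 to keep all rows.
#' @param minClusterSize clusters below this size are skipped with a warning
#'   (default 3).
#' @return `data.frame` with columns gene, cluster, avg_log_fc, pct_in,
#'   pct_out, p_value, p_adjusted.
#' @export
findMarkers <- function(sce, labels, minPct = 0.1, pAdjustMax = 0.01,
                        minClusterSize = 3) {
  x <- if (methods::is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene%d", seq_len(nrow(x)))
  if (length(labels) != ncol(x)) stop("one label per cell required")
  labs <- as.character(labels)
  sizes <- table(labs)
  use <- names(sizes)[sizes >= minClusterSize]
  if (length(setdiff(names(sizes), use)))
    warning("clusters smaller than ", minClusterSize, " excluded: ",
            paste(setdiff(names(sizes), use), collapse = ", "))
  if (length(use) < 2) stop("at least two usable clusters are required")

  G <- nrow(x)
  n <- ncol(x)
  ranks <- matrix(0, G, n)
  tieTerm <- numeric(G)
  noTies <- logical(G)
  for (g in seq_len(G)) {
    r <- rank(x[g, ])
    ranks[g, ] <- r
    tt <- table(x[g, ])
    tieTerm[g] <- sum(tt^3 - tt)
    noTies[g] <- all(tt == 1)
  }
  expm1x <- expm1(x)

  out <- vector("list", length(use))
  for (ci in seq_along(use)) {
    cl <- use[ci]
    inG <- labs == cl
    p <- vapply(seq_len(G), function(g) {
      rankSumP(ranks[g, ], inG, tieTerm[g], noTies[g])
    }, numeric(1))
    padj <- stats::p.adjust(p, method = "BH")
    lfc <- log(rowMeans(expm1x[, inG, drop = FALSE]) + 1) -
           log(rowMeans(expm1x[, !inG, drop = FALSE]) + 1)
    pctIn <- rowMeans(x[, inG, drop = FALSE] > 0)
    pctOut <- rowMeans(x[, !inG, drop = FALSE] > 0)
    df <- data.frame(gene = rownames(x), cluster = cl, avg_log_fc = lfc,
                     pct_in = pctIn, pct_out = pctOut, p_value = p,
                     p_adjusted = padj, row.names = NULL)
    out[[ci]] <- df[df$p_adjusted < pAdjustMax & df$pct_in >= minPct, ]
  }
  res <- do.call(rbind, out)
  res[order(res$cluster, res$p_adjusted, -abs(res$avg_log_fc)), ]
}
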