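test_that("SNN Jaccard weights match hand-enumerated neighbour sets", {
  pts <- cbind(c(0, 1, 3, 10, 10.5), 0)
  g <- buildSnnGraph(pts, k = 2, pruneThreshold = 0)
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  # neighbour sets (k = 2, self included): N1={1,2} N2={2,1} N3={3,2}
  # N4={4,5} N5={5,4}; Jaccard by set arithmetic
  expect_equal(w[1, 2], 1)            # {1,2} vs {1,2}
  expect_equal(w[1, 3], 1 / 3)        # {1,2} vs {2,3}: 1 shared of 3
  expect_equal(w[2, 3], 1 / 3)
  expect_equal(w[4, 5], 1)
  expect_equal(w[1, 4], 0)            # disjoint neighbourhoods
  expect_true(isSymmetric(w))
  expect_error(buildSnnGraph(pts, k = 5), "smaller")
})

test_that("two far-separated groups yield no cross edges and two Louvain clusters", {
  set.seed(2)
  blob1 <- matrix(rnorm(10, 0, 0.01), 5, 2)
  blob2 <- matrix(rnorm(10, 50, 0.01), 5, 2)
  g <- buildSnnGraph(rbind(blob1, blob2), k = 4)
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_true(all(w[1:5, 6:10] == 0))
  cl <- louvainCluster(g, resolution = 1, seed = 1)
  expect_equal(length(unique(clusterLabels(cl))), 2)
  expect_equal(length(unique(clusterLabels(cl)[1:5])), 1)
  expect_error(louvainCluster(igraph::make_empty_graph(0)), "empty")
})

test_that("Louvain attains the brute-force modularity optimum on a toy graph", {
  # two triangles joined by a single bridge edge
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4)),
    directed = FALSE)
  igraph::E(g)$weight <- 1
  cl <- louvainCluster(g, resolution = 1, seed = 7)

  # exhaustive oracle: enumerate every partition of 6 nodes
  partitions <- function(n) {
    if (n == 1) return(list(list(1L)))
    out <- list()
    for (p in partitions(n - 1)) {
      for (i in seq_along(p)) {
        q <- p; q[[i]] <- c(q[[i]], n); out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(n))
    }
    out
  }
  best <- -Inf
  for (p in partitions(6)) {
    memb <- integer(6)
    for (i in seq_along(p)) memb[p[[i]]] <- i
    best <- max(best, igraph::modularity(g, memb))
  }
  expect_equal(cl@modularity, best, tolerance = 1e-12)
})

test_that("cluster count does not decrease with resolution", {
  set.seed(3)
  pts <- do.call(rbind, lapply(0:3, function(b) {
    matrix(rnorm(16, mean = 20 * b, sd = 0.5), 8, 2)
  }))
  g <- buildSnnGraph(pts, k = 6)
  nCl <- vapply(c(0.2, 1, 5),
                function(r) length(unique(clusterLabels(
                  louvainCluster(g, resolution = r, seed = 4)))), integer(1))
  expect_true(all(diff(nCl) >= 0))
})

test_that("exact Wilcoxon p matches exhaustive label enumeration", {
  vals <- c(1.3, 2.7, 0.4, 5.1, 3.3, 6.2, 4.8, 7.9)  # tie-free
  labels <- rep(c("A", "B"), each = 4)
  filler <- matrix(rpois(3 * 8, 4), 3, 8)
  x <- rbind(target = vals, filler)
  rownames(x) <- c("target", "f1", "f2", "f3")
  tab <- findMarkers(x, labels, minPct = 0, pAdjustMax = 1.1,
                     minClusterSize = 3)
  got <- tab$p_value[tab$gene == "target" & tab$cluster == "A"]

  # oracle: every C(8,4) assignment of labels, two-sided doubling convention
  r <- rank(vals)
  U <- combn(8, 4, function(i) sum(r[i]) - 4 * 5 / 2)
  u0 <- sum(r[1:4]) - 10
  pLe <- mean(U <= u0); pGe <- mean(U >= u0)
  oracle <- min(1, 2 * min(pLe, pGe))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("null genes show nominal false-positive rates", {
  set.seed(8)
  x <- matrix(rnorm(1000 * 60), 1000, 60)
  labels <- rep(c("A", "B"), each = 30)
  tab <- findMarkers(x, labels, minPct = 0, pAdjustMax = 1.1)
  fpr <- mean(tab$p_value[tab$cluster == "A"] < 0.05)
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  # BH never orders below the raw p
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-15))
})

test_that("a perfectly separating gene is reported with the right sign and BH is order-invariant", {
  set.seed(9)
  x <- matrix(abs(rnorm(40 * 30)), 40, 30)
  rownames(x) <- sprintf("g%02d", 1:40)
  labels <- rep(c("A", "B"), each = 15)
  x["g05", ] <- c(rep(5, 15), rep(0, 15))  # only in cluster A
  tab <- findMarkers(x, labels, minPct = 0.1, pAdjustMax = 0.01)
  rowA <- tab[tab$cluster == "A" & tab$gene == "g05", ]
  expect_equal(nrow(rowA), 1)
  expect_gt(rowA$avg_log_fc, 0)
  # permuting gene order leaves the passing set unchanged
  perm <- sample(nrow(x))
  tab2 <- findMarkers(x[perm, ], labels, minPct = 0.1, pAdjustMax = 0.01)
  expect_setequal(paste(tab$gene, tab$cluster),
                  paste(tab2$gene, tab2$cluster))
  # lfc sign agrees with the difference of cluster means
  for (i in seq_len(nrow(tab))) {
    d <- mean(x[tab$gene[i], labels == tab$cluster[i]]) -
         mean(x[tab$gene[i], labels != tab$cluster[i]])
    expect_equal(sign(tab$avg_log_fc[i]), sign(d))
  }
  # undersized clusters are refused
  expect_warning(
    expect_error(findMarkers(x, c(rep("A", 28), "B", "B")), "two usable"),
    "excluded")
})
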