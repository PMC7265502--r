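#' Diffusion-map embedding of cells
#'
#' Spectral embedding of the density-normalized Gaussian-kernel diffusion
#' operator on pairwise Euclidean distances, here between cells in the
#' reduced space of the significant principal components. The kernel
#' bandwidth defaults to the median distance to the `kSigma`-th nearest
#' neighbour (a global median heuristic). Density normalization uses the
#' anisotropic alpha = 1 convention, which removes sampling-density effects
#' so the embedding reflects geometry rather than cell abundance. The
#' trivial constant eigenvector (eigenvalue 1) is dropped; the returned
#' diffusion components are the operator's right eigenvectors scaled by
#' their eigenvalues, ordered by decreasing eigenvalue.
#'
#' @param scores cells x components matrix (significant-PC block).
#' @param nComponents number of diffusion components (default 10).
#' @param kSigma neighbour index for the bandwidth heuristic (default 10).
#' @param sigma optional explicit kernel bandwidth overriding the heuristic.
#' @return a [Trajectory-class] holding the embedding.
#' @export
diffusionMap <- function(scores, nComponents = 10, kSigma = 10, sigma = NULL) {
  n <- nrow(scores)
  if (n < nComponents + 2)
    stop("need at least nComponents + 2 cells")
  d <- as.matrix(stats::dist(scores))
  if (is.null(sigma)) {
    kth <- apply(d, 1, function(r) sort(r)[min(kSigma + 1, n)])
    sigma <- stats::median(kth)
    if (sigma == 0) sigma <- mean(d[d > 0])
  }
  W <- exp(-d^2 / (2 * sigma^2))
  q <- rowSums(W)
  W1 <- W / outer(q, q)          # alpha = 1 density normalization
  d1 <- rowSums(W1)
  A <- W1 / sqrt(outer(d1, d1))  # symmetric conjugate of the Markov operator
  eig <- eigen(A, symmetric = TRUE)
  ev <- eig$values
  keep <- seq(2, nComponents + 1)
  psi <- eig$vectors / sqrt(d1)  # right eigenvectors of the Markov operator
  # unit-normalize then scale by eigenvalue
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  dcs <- sweep(psi[, keep, drop = FALSE], 2, ev[keep], "*")
  colnames(dcs) <- paste0("DC", seq_len(ncol(dcs)))
  rownames(dcs) <- rownames(scores)
  lam <- pmin(1, ev[keep])
  if (any(lam <= 0))
    stop("non-positive diffusion eigenvalues; kernel bandwidth too small")
  new("Trajectory", dcs = dcs, eigenvalues = lam)
}

# distance from points to a polyline plus arc-length of the projection foot
projectToPolyline <- function(points, curve) {
  nSeg <- nrow(curve) - 1
  segStart <- curve[seq_len(nSeg), , drop = FALSE]
  segVec <- curve[seq_len(nSeg) + 1, , drop = FALSE] - segStart
  segLen2 <- rowSums(segVec^2)
  segLen2[segLen2 == 0] <- 1e-300
  cumLen <- c(0, cumsum(sqrt(rowSums(segVec^2))))
  n <- nrow(points)
  lambda <- numeric(n)
  dist2 <- numeric(n)
  for (i in seq_len(n)) {
    rel <- sweep(segStart, 2, points[i, ], "-")
    tpar <- pmin(1, pmax(0, -rowSums(rel * segVec) / segLen2))
    foot <- segStart + segVec * tpar
    d2 <- rowSums((foot - matrix(points[i, ], nSeg, 2, byrow = TRUE))^2)
    j <- which.min(d2)
    dist2[i] <- d2[j]
    lambda[i] <- cumLen[j] + tpar[j] * sqrt(segLen2[j])
  }
  list(lambda = lambda, dist2 = dist2)
}

#' Hastie-Stuetzle principal curve in two dimensions
#'
#' Fits a smooth one-dimensional curve through a 2-D point cloud by
#' alternating projection and smoothing: cells are projected onto the
#' current curve to obtain arc-length positions lambda, then each coordinate
#' is smoothed against lambda with `lowess` at span `span`. The iteration
#' starts from the first principal component line and stops when the total
#' squared projection distance changes by less than `tol` (relative) or
#' after `maxIter` passes (returning the best fit with a warning).
#'
#' @param x cells x 2 matrix (e.g. DC1-DC2).
#' @param span lowess span f (default 1/3).
#' @param maxIter,tol iteration controls.
#' @return list with `curve` (ordered polyline), `lambda` (per-cell
#'   arc-length from the curve start, >= 0), `converged`, `dist` (total
#'   squared projection distance).
#' @export
fitPrincipalCurveMatrix <- function(x, span = 1 / 3, maxIter = 50, tol = 1e-4) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("at least 10 points are required")
  if (ncol(x) != 2) stop("a two-column matrix is required")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  v <- svd(xc, nu = 0, nv = 1)$v[, 1]
  lambda <- as.numeric(xc %*% v)
  lastDist <- Inf
  converged <- FALSE
  curve <- NULL
  for (it in seq_len(maxIter)) {
    ord <- order(lambda)
    fitted <- matrix(0, nrow(x), 2)
    for (j in 1:2) {
      lo <- stats::lowess(lambda[ord], x[ord, j], f = span)
      fitted[ord, j] <- lo$y
    }
    curve <- fitted[ord, , drop = FALSE]
    # collapse duplicate consecutive vertices
    keep <- c(TRUE, rowSums(abs(diff(curve))) > 0)
    curve <- curve[keep, , drop = FALSE]
    if (nrow(curve) < 2) {  # degenerate: all points smooth to one location
      lambda <- rep(0, nrow(x))
      return(list(curve = rbind(curve, curve), lambda = lambda,
                  converged = TRUE, dist = sum(xc^2)))
    }
    pr <- projectToPolyline(x, curve)
    newDist <- sum(pr$dist2)
    lambda <- pr$lambda
    # absolute floor: an (almost) interpolating curve has converged even
    # though the relative change of a ~0 residual never stabilizes
    floorDist <- 1e-12 * sum(xc^2)
    if (is.finite(lastDist) &&
        abs(lastDist - newDist) <= tol * max(newDist, floorDist)) {
      converged <- TRUE
      break
    }
    lastDist <- newDist
  }
  if (!converged)
    warning("principal curve did not converge in ", maxIter, " iterations")
  list(curve = curve, lambda = lambda - min(lambda) + 0,
       converged = converged, dist = newDist)
}

#' @rdname fitPrincipalCurve
#' @export
setMethod("fitPrincipalCurve", "matrix", function(x, ...) {
  fitPrincipalCurveMatrix(x, ...)
})

#' @rdname fitPrincipalCurve
#' @export
setMethod("fitPrincipalCurve", "Trajectory", function(x, ...) {
  fit <- fitPrincipalCurveMatrix(diffusionComponents(x)[, 1:2, drop = FALSE], ...)
  x@curve <- fit$curve
  x@lambda <- fit$lambda
  x@orientation <- "as-fitted"
  x@converged <- fit$converged
  validObject(x)
  x
})

#' Orient pseudotime along increasing activation
#'
#' The arc-length pseudotime of a principal curve has an arbitrary
#' direction. This flips lambda to `max(lambda) - lambda` whenever the
#' Spearman correlation between lambda and the supplied activation module
#' score is negative, so that the activation program increases along
#' pseudotime. A near-zero correlation (|rho| < `ambiguousBelow`) leaves the
#' direction unchanged but flags the orientation as ambiguous.
#'
#' @param traj a [Trajectory-class] with lambda filled in.
#' @param activationScore per-cell activation module score
#'   (same cells, same order).
#' @param ambiguousBelow |rho| threshold below which orientation is flagged
#'   ambiguous (default 0.1).
#' @return the trajectory with oriented lambda and the orientation recorded.
#' @export
orientPseudotime <- function(traj, activationScore, ambiguousBelow = 0.1) {
  lam <- pseudotime(traj)
  if (!length(lam)) stop("fit a principal curve before orienting")
  if (length(activationScore) != length(lam))
    stop("activation score and lambda cover different cells")
  rho <- spearman(lam, activationScore)
  if (is.na(rho) || abs(rho) < ambiguousBelow) {
    traj@orientation <- "ambiguous"
    warning("pseudotime orientation is ambiguous (|rho| = ",
            sprintf("%.3f", abs(rho)), ")")
  } else if (rho < 0) {
    traj@lambda <- max(lam) - lam
    traj@curve <- traj@curve[rev(seq_len(nrow(traj@curve))), , drop = FALSE]
    traj@orientation <- "flipped"
  } else {
    traj@orientation <- "as-fitted"
  }
  traj
}

#' Smooth gene expression along pseudotime
#'
#' Locally weighted regression (`loess`, quadratic) of each gene's
#' log-normalized expression on pseudotime, evaluated with pointwise
#' standard errors on a uniform grid across the observed pseudotime range.
#'
#' @param sce `SingleCellExperiment` with `logcounts`, or genes x cells
#'   matrix.
#' @param lambda per-cell pseudotime.
#' @param genes genes to smooth.
#' @param span loess span (default 0.5).
#' @param gridN grid resolution (default 100).
#' @return long-format `data.frame` (gene, lambda, fit, se).
#' @export
smoothAlongPseudotime <- function(sce, lambda, genes, span = 0.5, gridN = 100) {
  x <- if (methods::is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  if (any(!is.finite(lambda))) stop("lambda must be finite for all cells")
  absent <- setdiff(genes, rownames(x))
  if (length(absent)) stop("gene absent: ", paste(absent, collapse = ", "))
  grid <- seq(min(lambda), max(lambda), length.out = gridN)
  out <- lapply(genes, function(g) {
    y <- as.numeric(x[g, ])
    if (stats::sd(y) == 0) {
      fit <- rep(y[1], gridN)
      se <- rep(0, gridN)
    } else {
      lo <- stats::loess(y ~ lambda, span = span, degree = 2,
                         control = stats::loess.control(surface = "direct"))
      pr <- stats::predict(lo, newdata = data.frame(lambda = grid), se = TRUE)
      fit <- as.numeric(pr$fit)
      se <- as.numeric(pr$se.fit)
    }
    data.frame(gene = g, lambda = grid, fit = fit, se = se)
  })
  do.call(rbind, out)
}
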