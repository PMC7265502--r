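## Fourier-transform traction cytometry on an elastic half-space.
##
## Displacements of the free surface of a thick linear-elastic substrate
## (Young's modulus E, Poisson ratio nu) relate to the surface traction field
## through the Boussinesq Green's tensor. In Fourier space the convolution
## becomes a per-wavevector 2x2 linear map u_hat = G(k) t_hat with
##   G(k) = 2 (1 + nu) / (E k^3) *
##          [ (1-nu) k^2 + nu ky^2,   -nu kx ky
##            -nu kx ky,              (1-nu) k^2 + nu kx^2 ]
## Forward simulation multiplies by G; inversion applies the Tikhonov
## regularized inverse (G'G + lambda^2 I)^-1 G'. The zero-frequency traction
## is set to 0, which removes rigid drift and enforces global force balance.

# Green's tensor components on the FFT grid of an n1 x n2 field with
# spacing h (um). Returns list(gxx, gyy, gxy) in um/Pa; entries at k = 0
# are zero (handled separately).
greensTensorFT <- function(n1, n2, h, E, nu) {
  ky <- fftWavenumbers(n1, h)           # rows
  kx <- fftWavenumbers(n2, h)           # columns
  KY <- matrix(ky, n1, n2)
  KX <- matrix(kx, n1, n2, byrow = TRUE)
  k2 <- KX^2 + KY^2
  k <- sqrt(k2)
  k[1, 1] <- Inf                        # kill the DC term
  A <- 2 * (1 + nu) / (E * k^3)
  list(gxx = A * ((1 - nu) * k2 + nu * KY^2),
       gyy = A * ((1 - nu) * k2 + nu * KX^2),
       gxy = -A * nu * KX * KY)
}

padField <- function(m, n1, n2) {
  out <- matrix(0, n1, n2)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# forward elastic solve: traction (Pa) -> displacement (um); pad = factor
forwardElastic <- function(tx, ty, h, E, nu, pad = 2) {
  n1 <- nrow(tx) * pad
  n2 <- ncol(tx) * pad
  G <- greensTensorFT(n1, n2, h, E, nu)
  txh <- stats::fft(padField(tx, n1, n2))
  tyh <- stats::fft(padField(ty, n1, n2))
  uh <- G$gxx * txh + G$gxy * tyh
  vh <- G$gxy * txh + G$gyy * tyh
  u <- Re(stats::fft(uh, inverse = TRUE)) / (n1 * n2)
  v <- Re(stats::fft(vh, inverse = TRUE)) / (n1 * n2)
  list(u = u[seq_len(nrow(tx)), seq_len(ncol(tx))],
       v = v[seq_len(nrow(tx)), seq_len(ncol(tx))])
}

#' Simulate a traction scene with known ground truth
#'
#' Builds a traction field as a sum of Gaussian force foci, computes the
#' resulting substrate surface displacement with the Boussinesq half-space
#' forward model evaluated in Fourier space (zero-padded by `pad` to
#' suppress periodic wrap-around), and adds i.i.d. Gaussian measurement
#' noise to the displacements. Defaults match a polyacrylamide TFM gel of
#' Young's modulus 2550 Pa; nu = 0.5 models the incompressible limit.
#'
#' @param gridShape integer length-2 (rows, cols); powers of two recommended.
#' @param pixelSizeUm grid spacing (um).
#' @param youngsModulusPa,poissonRatio elastic constants.
#' @param forceSpec data.frame with columns `row`, `col` (focus centre, grid
#'   units), `sigma` (focus width, grid units), `peakPa`, `dirX`, `dirY`
#'   (direction, normalized internally). Empty for a quiet substrate.
#' @param noiseSdUm displacement noise SD (um).
#' @param seed RNG seed for the noise.
#' @param pad zero-padding factor for the forward FFT (default 2).
#' @return a [TractionScene-class].
#' @export
simulateTractionScene <- function(gridShape = c(64, 64), pixelSizeUm = 1,
                                  youngsModulusPa = 2550, poissonRatio = 0.5,
                                  forceSpec = NULL, noiseSdUm = 0,
                                  seed = 1, pad = 2) {
  if (any(gridShape < 2)) stop("zero or degenerate grid")
  if (youngsModulusPa <= 0) stop("Young's modulus must be positive")
  if (poissonRatio < 0 || poissonRatio > 0.5)
    stop("Poisson ratio must lie in [0, 0.5]")
  n1 <- gridShape[1]; n2 <- gridShape[2]
  tx <- matrix(0, n1, n2)
  ty <- matrix(0, n1, n2)
  if (is.null(forceSpec))
    forceSpec <- data.frame(row = numeric(0), col = numeric(0),
                            sigma = numeric(0), peakPa = numeric(0),
                            dirX = numeric(0), dirY = numeric(0))
  R <- matrix(seq_len(n1), n1, n2)
  C <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  for (i in seq_len(nrow(forceSpec))) {
    f <- forceSpec[i, ]
    g <- exp(-((R - f$row)^2 + (C - f$col)^2) / (2 * f$sigma^2))
    nrm <- sqrt(f$dirX^2 + f$dirY^2)
    tx <- tx + f$peakPa * g * f$dirX / nrm
    ty <- ty + f$peakPa * g * f$dirY / nrm
  }
  disp <- forwardElastic(tx, ty, pixelSizeUm, youngsModulusPa, poissonRatio,
                         pad = pad)
  if (noiseSdUm > 0) {
    noise <- withr::with_seed(seed, list(
      u = matrix(rnorm(n1 * n2, 0, noiseSdUm), n1, n2),
      v = matrix(rnorm(n1 * n2, 0, noiseSdUm), n1, n2)))
    disp$u <- disp$u + noise$u
    disp$v <- disp$v + noise$v
  }
  new("TractionScene", tx = tx, ty = ty, u = disp$u, v = disp$v,
      pixelSizeUm = pixelSizeUm, youngsModulusPa = youngsModulusPa,
      poissonRatio = poissonRatio, noiseSdUm = noiseSdUm,
      forceSpec = as.data.frame(forceSpec))
}

#' Render fluorescent bead images before and after relaxation
#'
#' Places `nBeads` beads uniformly at random, renders each as an isotropic
#' Gaussian spot, and produces a second image in which every bead is moved
#' by the scene's displacement field interpolated (bilinearly) at the bead
#' position -- emulating bead images taken with the cell attached and after
#' trypsin release. Intensities are normalized to [0, 1].
#'
#' @param scene a [TractionScene-class].
#' @param nBeads number of beads (>= 1).
#' @param beadSigmaPx Gaussian spot SD in pixels (default 1).
#' @param seed RNG seed for bead placement.
#' @return list with matrices `before`, `after` and the bead table
#'   `beads` (row, col, displaced row/col).
#' @export
renderBeadImages <- function(scene, nBeads, beadSigmaPx = 1, seed = 1) {
  if (nBeads < 1) stop("at least one bead is required")
  n1 <- nrow(scene@u); n2 <- ncol(scene@u)
  pos <- withr::with_seed(seed, cbind(runif(nBeads, 1, n1),
                                      runif(nBeads, 1, n2)))
  dupx <- bilinearAt(scene@u, pos) / scene@pixelSizeUm
  dvpx <- bilinearAt(scene@v, pos) / scene@pixelSizeUm
  # u drives column (x) displacement, v row (y) displacement
  posAfter <- cbind(pos[, 1] + dvpx, pos[, 2] + dupx)
  before <- renderSpots(pos, n1, n2, beadSigmaPx)
  after <- renderSpots(posAfter, n1, n2, beadSigmaPx)
  covered <- mean(before > 0.05)
  if (covered > 0.9)
    warning("bead density very high: spots cover ",
            sprintf("%.0f%%", 100 * covered), " of pixels")
  list(before = before, after = after,
       beads = data.frame(row = pos[, 1], col = pos[, 2],
                          rowAfter = posAfter[, 1], colAfter = posAfter[, 2]))
}

bilinearAt <- function(m, pos) {
  n1 <- nrow(m); n2 <- ncol(m)
  r <- pmin(pmax(pos[, 1], 1), n1)
  c <- pmin(pmax(pos[, 2], 1), n2)
  r0 <- pmin(floor(r), n1 - 1); c0 <- pmin(floor(c), n2 - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

renderSpots <- function(pos, n1, n2, sigma) {
  img <- matrix(0, n1, n2)
  half <- ceiling(4 * sigma)
  for (i in seq_len(nrow(pos))) {
    r <- pos[i, 1]; c <- pos[i, 2]
    rr <- max(1, floor(r) - half):min(n1, ceiling(r) + half)
    cc <- max(1, floor(c) - half):min(n2, ceiling(c) + half)
    img[rr, cc] <- img[rr, cc] +
      outer(exp(-(rr - r)^2 / (2 * sigma^2)),
            exp(-(cc - c)^2 / (2 * sigma^2)))
  }
  if (max(img) > 0) img <- img / max(img)
  img
}

#' Particle image velocimetry by window cross-correlation
#'
#' Splits the image pair into square interrogation windows (half-overlapping
#' by default), locates the peak of the windowed cross-correlation, and
#' refines it to sub-pixel precision with a three-point parabolic fit in
#' each axis. Windows whose correlation peak is not clearly dominant
#' (peak-to-second-peak ratio below `minPeakRatio`) are masked invalid.
#'
#' @param before,after single-channel image matrices of identical shape.
#' @param windowPx interrogation window size (default 32).
#' @param overlap window overlap fraction (default 0.5).
#' @param minPeakRatio validity threshold on the peak ratio (default 1.5).
#' @param pixelSizeUm physical pixel size recorded in the result (default 1).
#' @return a [DisplacementField-class]; `u` is the column (x) displacement
#'   and `v` the row (y) displacement, in pixels.
#' @export
pivTrack <- function(before, after, windowPx = 32, overlap = 0.5,
                     minPeakRatio = 1.5, pixelSizeUm = 1) {
  if (!all(dim(before) == dim(after)))
    stop("images must have identical shape")
  n1 <- nrow(before); n2 <- ncol(before)
  if (windowPx > min(n1, n2)) stop("window larger than image")
  step <- max(1, round(windowPx * (1 - overlap)))
  rows <- seq(1, n1 - windowPx + 1, by = step)
  cols <- seq(1, n2 - windowPx + 1, by = step)
  u <- v <- matrix(NA_real_, length(rows), length(cols))
  valid <- matrix(FALSE, length(rows), length(cols))
  for (ri in seq_along(rows)) {
    for (ci in seq_along(cols)) {
      rr <- rows[ri]:(rows[ri] + windowPx - 1)
      cc <- cols[ci]:(cols[ci] + windowPx - 1)
      res <- windowShift(before[rr, cc], after[rr, cc], minPeakRatio)
      v[ri, ci] <- res$dr
      u[ri, ci] <- res$dc
      valid[ri, ci] <- res$valid
    }
  }
  new("DisplacementField", u = u, v = v, valid = valid,
      gridRow = rows + (windowPx - 1) / 2, gridCol = cols + (windowPx - 1) / 2,
      windowPx = as.integer(windowPx), pixelSizeUm = pixelSizeUm)
}

# displacement of b relative to a via circular cross-correlation
windowShift <- function(a, b, minPeakRatio) {
  n <- nrow(a)
  a <- a - mean(a)
  b <- b - mean(b)
  if (sum(a^2) == 0 || sum(b^2) == 0)
    return(list(dr = 0, dc = 0, valid = FALSE))
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) /
    (n * n)
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # second peak outside a 3x3 neighbourhood of the first
  mask <- cc
  rr <- ((peak[1] - 2):(peak[1] + 0)) %% n + 1
  ccq <- ((peak[2] - 2):(peak[2] + 0)) %% n + 1
  mask[rr, ccq] <- -Inf
  second <- max(mask)
  ratio <- if (second > 0) max(cc) / second else Inf
  idxShift <- function(i) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  sub <- function(mat, dr, dc) {
    mat[(peak[1] + dr - 1) %% n + 1, (peak[2] + dc - 1) %% n + 1]
  }
  para <- function(l, c0, r) {
    den <- l - 2 * c0 + r
    if (den >= 0) 0 else (l - r) / (2 * den)
  }
  dr <- idxShift(peak[1]) + para(sub(cc, -1, 0), cc[peak[1], peak[2]], sub(cc, 1, 0))
  dc <- idxShift(peak[2]) + para(sub(cc, 0, -1), cc[peak[1], peak[2]], sub(cc, 0, 1))
  list(dr = dr, dc = dc, valid = is.finite(ratio) && ratio >= minPeakRatio)
}

# bilinear gap fill of invalid vectors (mean of valid neighbours, iterated)
fillGaps <- function(m, valid) {
  while (any(!valid)) {
    filledAny <- FALSE
    idx <- which(!valid, arr.ind = TRUE)
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, 1]; j <- idx[q, 2]
      ri <- max(1, i - 1):min(nrow(m), i + 1)
      cj <- max(1, j - 1):min(ncol(m), j + 1)
      nb <- m[ri, cj][valid[ri, cj]]
      if (length(nb)) {
        m[i, j] <- mean(nb)
        valid[i, j] <- TRUE
        filledAny <- TRUE
      }
    }
    if (!filledAny) {
      m[!valid] <- 0
      break
    }
  }
  m
}

#' Fourier-transform traction cytometry inversion
#'
#' Recovers the traction field from a measured displacement field by
#' inverting the Boussinesq half-space relation in Fourier space with
#' zeroth-order Tikhonov regularization. Invalid vectors are gap-filled by
#' neighbour averaging before the FFT; the field is zero-padded by `pad`
#' to suppress periodic wrap-around; the zero-frequency traction is set to
#' zero (removing rigid drift and enforcing force balance).
#'
#' @param field a [DisplacementField-class] (u, v interpreted in pixels and
#'   converted with its pixel size and window spacing), or a list with
#'   matrices `u`, `v` in um.
#' @param spacingUm grid spacing in um (required for a plain list; derived
#'   from the field geometry otherwise).
#' @param youngsModulusPa substrate Young's modulus (default 2550 Pa).
#' @param poissonRatio Poisson ratio (default 0.5).
#' @param regLambda Tikhonov parameter in the Green's-tensor units (um/Pa);
#'   0 gives the unregularized inverse (default 0).
#' @param pad zero-padding factor (default 2).
#' @return a [TractionField-class] in Pa.
#' @export
fttcReconstruct <- function(field, spacingUm = NULL, youngsModulusPa = 2550,
                            poissonRatio = 0.5, regLambda = 0, pad = 2) {
  if (regLambda < 0) stop("regularization parameter must be >= 0")
  if (methods::is(field, "DisplacementField")) {
    spacingPx <- if (length(field@gridRow) > 1)
      diff(field@gridRow[1:2]) else field@windowPx
    spacingUm <- spacingPx * field@pixelSizeUm
    u <- fillGaps(field@u, field@valid) * field@pixelSizeUm
    v <- fillGaps(field@v, field@valid) * field@pixelSizeUm
  } else {
    if (is.null(spacingUm)) stop("spacingUm required for plain fields")
    u <- field$u
    v <- field$v
  }
  n1 <- nrow(u) * pad; n2 <- ncol(u) * pad
  G <- greensTensorFT(n1, n2, spacingUm, youngsModulusPa, poissonRatio)
  uh <- stats::fft(padField(u, n1, n2))
  vh <- stats::fft(padField(v, n1, n2))
  # solve (G'G + lambda^2 I) t = G' u per wavevector; G symmetric 2x2
  a <- G$gxx; b <- G$gxy; c <- G$gyy
  A11 <- a^2 + b^2 + regLambda^2
  A22 <- c^2 + b^2 + regLambda^2
  A12 <- b * (a + c)
  det <- A11 * A22 - A12^2
  det[det == 0] <- Inf
  r1 <- a * uh + b * vh
  r2 <- b * uh + c * vh
  th1 <- (A22 * r1 - A12 * r2) / det
  th2 <- (A11 * r2 - A12 * r1) / det
  th1[1, 1] <- 0 + 0i
  th2[1, 1] <- 0 + 0i
  tx <- Re(stats::fft(th1, inverse = TRUE)) / (n1 * n2)
  ty <- Re(stats::fft(th2, inverse = TRUE)) / (n1 * n2)
  new("TractionField",
      tx = tx[seq_len(nrow(u)), seq_len(ncol(u))],
      ty = ty[seq_len(nrow(u)), seq_len(ncol(u))],
      youngsModulusPa = youngsModulusPa, poissonRatio = poissonRatio,
      regLambda = regLambda, spacingUm = spacingUm)
}

#' L-curve scan for the FTTC regularization parameter
#'
#' Computes the residual norm and solution norm for a grid of Tikhonov
#' parameters and returns the scan together with the corner estimate
#' (maximum curvature of the log-log L-curve), the conventional compromise
#' between data fit and noise amplification.
#'
#' @inheritParams fttcReconstruct
#' @param lambdas vector of candidate parameters (> 0).
#' @return list with `scan` (data.frame lambda, residual, norm) and
#'   `best` (corner lambda).
#' @export
fttcLcurve <- function(field, lambdas, spacingUm = NULL,
                       youngsModulusPa = 2550, poissonRatio = 0.5, pad = 2) {
  res <- vapply(lambdas, function(lm) {
    tf <- fttcReconstruct(field, spacingUm, youngsModulusPa, poissonRatio,
                          regLambda = lm, pad = pad)
    fw <- forwardElastic(tf@tx, tf@ty, tf@spacingUm, youngsModulusPa,
                         poissonRatio, pad = pad)
    if (methods::is(field, "DisplacementField")) {
      u <- fillGaps(field@u, field@valid) * field@pixelSizeUm
      v <- fillGaps(field@v, field@valid) * field@pixelSizeUm
    } else {
      u <- field$u; v <- field$v
    }
    c(residual = sqrt(sum((fw$u - u)^2 + (fw$v - v)^2)),
      norm = sqrt(sum(tf@tx^2 + tf@ty^2)))
  }, numeric(2))
  lr <- log(res["residual", ])
  ln <- log(res["norm", ])
  # corner by the triangle method: the scan point farthest from the chord
  # joining the L-curve endpoints, on normalized log-log axes
  nx <- (lr - min(lr)) / diff(range(lr))
  ny <- (ln - min(ln)) / diff(range(ln))
  a <- c(nx[1], ny[1]); b <- c(nx[length(nx)], ny[length(ny)])
  ab <- b - a
  dist <- abs(ab[2] * (nx - a[1]) - ab[1] * (ny - a[2])) / sqrt(sum(ab^2))
  best <- lambdas[which.max(dist)]
  list(scan = data.frame(lambda = lambdas, residual = res["residual", ],
                         norm = res["norm", ]),
       best = best)
}

#' Per-cell traction statistics
#'
#' @param traction a [TractionField-class] or [TractionScene-class].
#' @param cellMask logical matrix on the traction grid marking the cell.
#' @return list with `mean_pa`, `max_pa`, `area_um2`.
#' @export
forceStats <- function(traction, cellMask) {
  tl <- tractions(traction)
  if (!any(cellMask)) stop("empty cell mask")
  if (!all(dim(cellMask) == dim(tl$tx))) stop("mask does not match grid")
  mag <- sqrt(tl$tx^2 + tl$ty^2)[cellMask]
  h <- if (methods::is(traction, "TractionField")) traction@spacingUm
       else traction@pixelSizeUm
  list(mean_pa = mean(mag), max_pa = max(mag), area_um2 = sum(cellMask) * h^2)
}

# bilinear resample of a matrix to a common feature grid
resampleTo <- function(m, shape) {
  rows <- seq(1, nrow(m), length.out = shape[1])
  cols <- seq(1, ncol(m), length.out = shape[2])
  pos <- cbind(rep(rows, times = shape[2]), rep(cols, each = shape[1]))
  matrix(bilinearAt(m, pos), shape[1], shape[2])
}

#' Embed and cluster single-cell force signatures
#'
#' Each cell's traction-magnitude map is divided by its cell area, resampled
#' to a common feature grid, and flattened; features are centred and scaled
#' (zero-variance features dropped), reduced by PCA, and the significant
#' components selected with the same permutation parallel analysis used for
#' expression data. Cluster labels come from Louvain community detection on
#' the SNN graph of the significant components; the 2-D display embedding is
#' the first two components.
#'
#' @param maps list of traction-magnitude matrices (Pa), one per cell.
#' @param areas numeric vector of cell areas (um^2).
#' @param featureShape common grid (default c(32, 32)).
#' @param nComponents PCA components (default 20).
#' @param nPerm,alpha parallel-analysis parameters (defaults 50, 0.05).
#' @param k SNN neighbourhood size (default: quarter of the cells, capped
#'   at 15).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed.
#' @return list with `embedding` (cells x 2), `labels` (0-based),
#'   `nSignificant`, and the [EmbeddingResult-class] as `pca`.
#' @export
forceSignatureEmbed <- function(maps, areas, featureShape = c(32, 32),
                                nComponents = 20, nPerm = 50, alpha = 0.05,
                                k = NULL, resolution = 0.8, seed = 1) {
  n <- length(maps)
  if (n < 10) stop("at least 10 cells are required")
  if (length(areas) != n) stop("one area per force map required")
  feats <- t(vapply(seq_len(n), function(i) {
    as.vector(resampleTo(maps[[i]] / areas[i], featureShape))
  }, numeric(prod(featureShape))))
  s <- apply(feats, 2, stats::sd)
  feats <- feats[, s > 0, drop = FALSE]
  if (ncol(feats) == 0) {
    # all cells identical after normalization: one cluster, flat embedding
    return(list(embedding = matrix(0, n, 2), labels = rep(0L, n),
                nSignificant = 0L, pca = NULL))
  }
  feats <- scale(feats)
  x <- t(feats)  # features x cells, already centred/scaled per feature
  emb <- runPCA(x, nComponents = min(nComponents, n - 1, nrow(x)))
  ns <- permutationPA(x, nPerm = max(20, nPerm), alpha = alpha,
                      seed = stageSeed(seed, "tfm"),
                      nComponents = ncol(pcScores(emb)))
  nSignificant(emb) <- ns
  nUse <- max(ns, 2)  # always keep a plane to embed/cluster in
  scores <- pcScores(emb)[, seq_len(nUse), drop = FALSE]
  if (is.null(k)) k <- max(3, min(15, floor(n / 4)))
  g <- buildSnnGraph(scores, k = k)
  cl <- louvainCluster(g, resolution = resolution,
                       seed = stageSeed(seed, "cluster"))
  list(embedding = pcScores(emb)[, 1:2, drop = FALSE],
       labels = clusterLabels(cl), nSignificant = ns, pca = emb)
}
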