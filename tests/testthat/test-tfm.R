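test_that("elastic forward model obeys linearity and symmetry", {
  quiet <- simulateTractionScene(c(32, 32), forceSpec = NULL)
  expect_equal(max(abs(quiet@u)), 0)
  expect_equal(max(abs(quiet@v)), 0)

  f1 <- data.frame(row = 16, col = 16, sigma = 2, peakPa = 300,
                   dirX = 1, dirY = 0)
  f2 <- data.frame(row = 10, col = 22, sigma = 3, peakPa = 150,
                   dirX = 0, dirY = 1)
  s1 <- simulateTractionScene(c(32, 32), forceSpec = f1)
  s2 <- simulateTractionScene(c(32, 32), forceSpec = f2)
  s12 <- simulateTractionScene(c(32, 32), forceSpec = rbind(f1, f2))
  scale <- max(abs(s12@u))
  expect_lt(max(abs(s12@u - s1@u - s2@u)) / scale, 1e-10)
  expect_lt(max(abs(s12@v - s1@v - s2@v)) / scale, 1e-10)

  # balanced opposite foci: spatial mean displacement ~ 0
  fb <- data.frame(row = c(12, 20), col = 16, sigma = 2,
                   peakPa = 300, dirX = c(1, -1), dirY = 0)
  sb <- simulateTractionScene(c(32, 32), forceSpec = fb)
  expect_lt(abs(mean(sb@u)), 1e-2 * max(abs(sb@u)))

  expect_error(simulateTractionScene(c(0, 16)), "grid")
  expect_error(simulateTractionScene(c(16, 16), youngsModulusPa = -1),
               "modulus")
  expect_error(simulateTractionScene(c(16, 16), poissonRatio = 0.7),
               "Poisson")
})

test_that("forward displacements match a real-space Green's summation oracle", {
  sc <- referenceScene()
  nu <- sc@poissonRatio; E <- sc@youngsModulusPa
  ty <- sc@ty
  src <- which(abs(ty) > 1e-3, arr.ind = TRUE)
  pts <- expand.grid(r = seq(24, 104, by = 8), c = seq(24, 104, by = 8))
  dFoci <- pmin(sqrt((pts$r - 59)^2 + (pts$c - 64)^2),
                sqrt((pts$r - 69)^2 + (pts$c - 64)^2))
  pts <- pts[dFoci > 18, ]  # outside the (wide-tailed) source support
  oracle <- vapply(seq_len(nrow(pts)), function(q) {
    dy <- pts$r[q] - src[, 1]; dx <- pts$c[q] - src[, 2]
    r <- sqrt(dx^2 + dy^2); r[r == 0] <- Inf
    gyy <- (1 + nu) / (pi * E * r^3) * ((1 - nu) * r^2 + nu * dy^2)
    sum(gyy * ty[src])
  }, numeric(1))
  got <- sc@v[as.matrix(pts)]
  expect_gt(cor(got, oracle), 0.99)
  # agreement up to the constant offset inherent to the periodic solver
  expect_lt(sd(got - oracle) / sd(oracle), 0.15)
})

test_that("bead rendering respects the displacement field", {
  quiet <- simulateTractionScene(c(64, 64), forceSpec = NULL)
  imgs <- renderBeadImages(quiet, nBeads = 200, seed = 5)
  expect_identical(imgs$before, imgs$after)
  expect_true(all(imgs$before >= 0 & imgs$before <= 1))
  expect_error(renderBeadImages(quiet, nBeads = 0), "bead")
  expect_warning(renderBeadImages(quiet, nBeads = 6000, beadSigmaPx = 2,
                                  seed = 1), "density")
})

test_that("PIV recovers zero, integer and smooth displacement fields", {
  quiet <- simulateTractionScene(c(128, 128), forceSpec = NULL)
  img <- renderBeadImages(quiet, nBeads = 600, beadSigmaPx = 1.2,
                          seed = 4)$before
  same <- pivTrack(img, img, windowPx = 32)
  expect_lt(max(abs(same@u[same@valid])), 1e-9)
  expect_lt(max(abs(same@v[same@valid])), 1e-9)

  # circular shift with a whole-image window: exact by the shift theorem
  shifted <- img[, c(126:128, 1:125)]
  pv <- pivTrack(img, shifted, windowPx = 128)
  expect_equal(unname(pv@u[1, 1]), 3)
  expect_lt(abs(pv@v[1, 1]), 1e-12)

  # windowed tracking of the same shift: integer part exact everywhere
  pw <- pivTrack(img, shifted, windowPx = 32, overlap = 0.5)
  expect_true(all(round(pw@u[pw@valid]) == 3))
  expect_true(all(round(pw@v[pw@valid]) == 0))

  # smooth scene: median vector error below 0.2 px against stored truth
  sc <- referenceScene()
  bi <- renderBeadImages(sc, nBeads = 1200, beadSigmaPx = 1.2, seed = 9)
  pv2 <- pivTrack(bi$before, bi$after, windowPx = 32, overlap = 0.75)
  ij <- as.matrix(expand.grid(round(pv2@gridRow), round(pv2@gridCol)))
  tu <- matrix(sc@u[ij], length(pv2@gridRow))
  tv <- matrix(sc@v[ij], length(pv2@gridRow))
  err <- sqrt((pv2@u - tu)^2 + (pv2@v - tv)^2)
  expect_lt(median(err[pv2@valid]), 0.2)

  expect_error(pivTrack(img, img[1:64, ]), "shape")
  expect_error(pivTrack(img[1:16, 1:16], img[1:16, 1:16], windowPx = 32),
               "window")
})

test_that("FTTC inverts the forward model and scales linearly in E", {
  z <- list(u = matrix(0, 32, 32), v = matrix(0, 32, 32))
  tz <- fttcReconstruct(z, spacingUm = 1)
  expect_equal(max(abs(tz@tx)), 0)

  sc <- referenceScene()
  tf <- fttcReconstruct(list(u = sc@u, v = sc@v), spacingUm = 1,
                        youngsModulusPa = 2550, poissonRatio = 0.5)
  rel <- sqrt(sum((tf@tx - sc@tx)^2 + (tf@ty - sc@ty)^2) /
              sum(sc@tx^2 + sc@ty^2))
  expect_lte(rel, 0.10)
  # net recovered force ~ 0 by the zero-frequency rule (exact on the padded
  # grid; the crop retains a small residual)
  expect_lt(abs(sum(tf@tx)) + abs(sum(tf@ty)),
            1e-2 * sum(abs(tf@ty)))

  tf2 <- fttcReconstruct(list(u = sc@u, v = sc@v), spacingUm = 1,
                         youngsModulusPa = 2 * 2550, poissonRatio = 0.5)
  expect_equal(tf2@tx, 2 * tf@tx, tolerance = 1e-10)
  expect_equal(tf2@ty, 2 * tf@ty, tolerance = 1e-10)

  expect_error(fttcReconstruct(z, spacingUm = 1, regLambda = -1), ">= 0")
})

test_that("regularization restores mean cell traction under heavy noise", {
  sc <- referenceScene()
  noiseSd <- 0.1 * max(sqrt(sc@u^2 + sc@v^2))
  noisy <- referenceScene(noiseSdUm = noiseSd, seed = 31)
  mask <- outer(1:128, 1:128, function(r, c)
    pmin((r - 59)^2 + (c - 64)^2, (r - 69)^2 + (c - 64)^2) < 10^2)
  truthMean <- forceStats(sc, mask)$mean_pa
  lams <- 10^seq(-6, -2, length.out = 9)
  relErr <- vapply(lams, function(lm) {
    tf <- fttcReconstruct(list(u = noisy@u, v = noisy@v), spacingUm = 1,
                          regLambda = lm)
    abs(forceStats(tf, mask)$mean_pa - truthMean) / truthMean
  }, numeric(1))
  # at this noise level an optimal regularization level exists that recovers
  # the masked mean traction within 20%
  expect_lt(min(relErr), 0.2)
  # unregularized inversion amplifies the noise badly by comparison
  expect_gt(relErr[1], min(relErr) * 2)
  # the L-curve corner lands in the interior of the scanned range
  lc <- fttcLcurve(list(u = noisy@u, v = noisy@v), lams, spacingUm = 1)
  expect_true(lc$best > lams[1] && lc$best < lams[length(lams)])
})

test_that("force statistics summarize masked tractions", {
  tf <- new("TractionField", tx = matrix(100, 8, 8), ty = matrix(0, 8, 8),
            youngsModulusPa = 2550, poissonRatio = 0.5, regLambda = 0,
            spacingUm = 2)
  mask <- matrix(TRUE, 8, 8)
  st <- forceStats(tf, mask)
  expect_equal(st$mean_pa, 100)
  expect_equal(st$max_pa, 100)
  expect_equal(st$area_um2, 64 * 4)
  expect_error(forceStats(tf, matrix(FALSE, 8, 8)), "empty")

  # a display-convention-scale focal spot: max near the peak, mean far below
  fs <- data.frame(row = 64, col = 64, sigma = 2.5, peakPa = 800,
                   dirX = 1, dirY = 0)
  fs2 <- rbind(fs, within(fs, { row <- 40; dirX <- -1 }))
  sc <- simulateTractionScene(c(128, 128), forceSpec = fs2)
  big <- matrix(TRUE, 128, 128)
  stBig <- forceStats(sc, big)
  expect_gt(stBig$max_pa, 0.95 * 800)
  expect_lt(stBig$mean_pa, 0.2 * stBig$max_pa)
  focus <- (row(big) - 64)^2 + (col(big) - 64)^2 < 5^2
  stFocus <- forceStats(sc, focus)
  expect_gt(stFocus$mean_pa, stBig$mean_pa)   # restriction raises the mean
  expect_equal(stFocus$max_pa, stBig$max_pa)  # max unchanged
})

test_that("planted force phenotypes separate and labels are equivariant", {
  maps <- c(lapply(1:20, function(i) phenotypeForceMap("focal", i)),
            lapply(21:40, function(i) phenotypeForceMap("diffuse", i)))
  areas <- withr::with_seed(2, runif(40, 900, 1600))
  res <- forceSignatureEmbed(maps, areas, seed = 3)
  truth <- rep(0:1, each = 20)
  expect_gte(ari(res$labels, truth), 0.9)

  # permuting the cells permutes the labels identically
  perm <- withr::with_seed(4, sample(40))
  res2 <- forceSignatureEmbed(maps[perm], areas[perm], seed = 3)
  expect_equal(ari(res2$labels, res$labels[perm]), 1)

  # identical maps: zero-variance features dropped, a single cluster remains
  same <- lapply(1:12, function(i) maps[[1]])
  resSame <- forceSignatureEmbed(same, rep(1000, 12), seed = 5)
  expect_equal(length(unique(resSame$labels)), 1)
  expect_error(forceSignatureEmbed(maps[1:5], areas[1:5]), "10 cells")
})
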