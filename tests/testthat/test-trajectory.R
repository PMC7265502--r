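test_that("diffusion eigenvalues are a valid spectrum and blobs split on DC1", {
  set.seed(1)
  blobs <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
                 matrix(rnorm(100, 20, 0.5), 50, 2))
  dm <- diffusionMap(blobs, nComponents = 4)
  ev <- dm@eigenvalues
  expect_true(all(ev > 0 & ev <= 1))
  expect_true(all(diff(ev) <= 1e-10))
  dc1 <- diffusionComponents(dm)[, 1]
  mid <- (mean(dc1[1:50]) + mean(dc1[51:100])) / 2
  side <- dc1 > mid
  expect_true(all(side[1:50]) || all(!side[1:50]))
  expect_true(all(side[1:50] != side[51:100]))
  expect_error(diffusionMap(blobs[1:4, ], nComponents = 4), "cells")
})

test_that("diffusion embedding is invariant to rigid motions of the input", {
  set.seed(2)
  x <- matrix(rnorm(80 * 3), 80, 3)
  th <- 0.7
  rot <- diag(3); rot[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                            -sin(th), cos(th)), 2)
  y <- sweep(x %*% rot, 2, c(5, -3, 10), "+")
  d1 <- diffusionMap(x, nComponents = 3)
  d2 <- diffusionMap(y, nComponents = 3)
  expect_equal(d1@eigenvalues, d2@eigenvalues, tolerance = 1e-8)
  for (j in 1:2)
    expect_equal(abs(cor(diffusionComponents(d1)[, j],
                         diffusionComponents(d2)[, j])), 1, tolerance = 1e-6)
})

test_that("DC1 recovers the latent parameter of a noisy 1-D arc", {
  set.seed(3)
  t <- runif(500)
  arc <- cbind(cos(1.5 * t), sin(1.5 * t)) * 10 + matrix(rnorm(1000, 0, 0.3),
                                                         500, 2)
  dm <- diffusionMap(arc, nComponents = 3)
  expect_gte(abs(cor(diffusionComponents(dm)[, 1], t, method = "spearman")),
             0.9)
})

test_that("principal curve is a fixed point on collinear points", {
  set.seed(4)
  s <- sort(runif(60, -3, 7))
  pts <- cbind(1 + 2 * s, -0.5 * s + 3)  # straight line, non-axis-aligned
  fit <- fitPrincipalCurve(pts)
  speed <- sqrt(4 + 0.25)
  expected <- (s - min(s)) * speed
  expect_true(fit$converged)
  expect_equal(fit$lambda, expected, tolerance = 1e-8)
  expect_error(fitPrincipalCurve(pts[1:5, ]), "10 points")
})

test_that("principal curve recovers a noisy quarter circle", {
  set.seed(5)
  ang <- sort(runif(400, 0, pi / 2))
  noise <- 0.05
  pts <- cbind(cos(ang), sin(ang)) * 5 +
    matrix(rnorm(800, 0, noise), 400, 2)
  fit <- fitPrincipalCurve(pts, span = 1 / 3)
  expect_gte(abs(cor(fit$lambda, ang, method = "spearman")), 0.95)
  expect_lt(fit$dist / 400, 1.5 * noise^2)
  # on noiseless monotone data, sorting by lambda equals sorting by the
  # generative parameter (up to direction)
  clean <- cbind(cos(ang), sin(ang)) * 5
  fc <- suppressWarnings(fitPrincipalCurve(clean, span = 1 / 3))
  rho <- cor(fc$lambda, ang, method = "spearman")
  expect_equal(abs(rho), 1, tolerance = 1e-6)
})

test_that("pseudotime orientation follows the activation score", {
  set.seed(6)
  t <- sort(runif(120))
  pts <- cbind(t * 10, rnorm(120, 0, 0.05))
  dm <- diffusionMap(pts, nComponents = 2)
  tr <- suppressWarnings(fitPrincipalCurve(dm))
  increasing <- pseudotime(tr)          # whatever direction was fitted
  scoreUp <- increasing + rnorm(120, 0, 0.01 * max(increasing))
  up <- orientPseudotime(tr, scoreUp)
  expect_equal(up@orientation, "as-fitted")
  expect_equal(pseudotime(up), increasing)
  down <- orientPseudotime(tr, -scoreUp)
  expect_equal(down@orientation, "flipped")
  expect_equal(pseudotime(down), max(increasing) - increasing)
  expect_equal(spearman(pseudotime(down), -scoreUp),
               -spearman(increasing, -scoreUp), tolerance = 1e-12)
  expect_warning(orientPseudotime(tr, rnorm(120)), "ambiguous")
})

test_that("pseudotime smoothing reproduces flat and linear signals", {
  set.seed(7)
  lam <- sort(runif(200, 0, 4))
  x <- rbind(flat = rep(2.5, 200), ident = lam)
  sm <- smoothAlongPseudotime(x, lam, c("flat", "ident"), gridN = 50)
  flat <- sm[sm$gene == "flat", ]
  expect_equal(flat$fit, rep(2.5, 50), tolerance = 1e-12)
  ident <- sm[sm$gene == "ident", ]
  interior <- ident[ident$lambda > 0.4 & ident$lambda < 3.6, ]
  expect_equal(interior$fit, interior$lambda, tolerance = 1e-6)
  expect_true(all(sm$se >= 0))
  expect_error(smoothAlongPseudotime(x, lam, "missing"), "absent")
  expect_error(smoothAlongPseudotime(x, c(lam[-1], NA), "flat"), "finite")
})

test_that("a planted monotone gene smooths to a monotone curve", {
  set.seed(8)
  lam <- sort(runif(300, 0, 1))
  y <- 3 * lam + rnorm(300, 0, 0.15)
  x <- matrix(y, 1, dimnames = list("mono", NULL))
  sm <- smoothAlongPseudotime(x, lam, "mono", gridN = 60)
  interior <- sm$fit[sm$lambda > 0.1 & sm$lambda < 0.9]
  expect_true(all(diff(interior) > 0))
})
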