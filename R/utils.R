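#' Derive a per-stage seed from one root seed
#'
#' All randomized stages draw their seeds from a single root through fixed
#' per-stage offsets, so a pipeline run is reproducible from one integer while
#' stages remain statistically independent.
#'
#' @param seed integer root seed
#' @param stage one of "simulate", "preprocess", "reduce", "cluster",
#'   "score", "trajectory", "tfm"
#' @return integer seed below 2^31
#' @export
stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, preprocess = 23L, reduce = 37L, cluster = 41L,
               score = 53L, trajectory = 67L, tfm = 79L)
  stage <- match.arg(stage, names(offsets))
  as.integer((abs(as.numeric(seed)) * 7919 + offsets[[stage]]) %% 2147483629)
}

# sample() that never does the length-1 "sample from 1:n" surprise
sampleExact <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Spearman rank correlation; NA-free inputs assumed
spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# wavenumbers (rad / unit length) for an n-point FFT with spacing d
fftWavenumbers <- function(n, d) {
  half <- ceiling(n / 2) - 1L
  2 * pi * c(0:half, -(n - half - 1L):-1L) / (n * d)
}

# row variances of a (possibly sparse) matrix, sample convention
rowVarsSparse <- function(x) {
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  sq <- Matrix::rowMeans(x^2)
  pmax(0, (sq - mu^2) * n / (n - 1))
}
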