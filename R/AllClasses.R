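#' @import methods
#' @importFrom stats cor dist loess lowess median p.adjust pnorm predict
#'   pwilcox quantile rlnorm rmultinom rnorm runif sd var prcomp rgamma kmeans
#' @importFrom utils head read.delim write.csv read.csv
NULL

#' Principal-component embedding with a significance count
#'
#' Container for a truncated PCA of a scaled expression (or force-feature)
#' matrix: per-cell component scores, per-gene loadings, the fraction of total
#' variance carried by each component, and the number of components judged
#' significant by permutation parallel analysis (`NA` until tested).
#'
#' @slot scores numeric matrix, cells x components.
#' @slot loadings numeric matrix, features x components, orthonormal columns.
#' @slot varianceExplained numeric, fraction of total variance per component,
#'   non-increasing.
#' @slot nSignificant integer, number of leading significant components
#'   (`NA_integer_` when parallel analysis has not been run).
#' @slot genesUsed character, features the embedding was computed on.
#' @export
setClass("EmbeddingResult",
  representation(
    scores = "matrix",
    loadings = "matrix",
    varianceExplained = "numeric",
    nSignificant = "integer",
    genesUsed = "character"
  )
)

setValidity("EmbeddingResult", function(object) {
  k <- ncol(object@scores)
  if (ncol(object@loadings) != k)
    return("scores and loadings must have the same number of components")
  if (length(object@varianceExplained) != k)
    return("varianceExplained must have one entry per component")
  ve <- object@varianceExplained
  if (any(ve < -1e-12) || any(diff(ve) > 1e-10))
    return("varianceExplained must be non-negative and non-increasing")
  ns <- object@nSignificant
  if (!is.na(ns) && (ns < 0L || ns > k))
    return("nSignificant must lie in [0, n components]")
  TRUE
})

#' Cluster assignment from graph-based community detection
#'
#' @slot labels integer vector of cluster ids, contiguous from 0.
#' @slot modularity numeric, modularity of the returned partition.
#' @slot resolution numeric, resolution parameter used.
#' @slot nEdges integer, number of edges in the clustered graph.
#' @export
setClass("ClusterResult",
  representation(
    labels = "integer",
    modularity = "numeric",
    resolution = "numeric",
    nEdges = "integer"
  )
)

setValidity("ClusterResult", function(object) {
  lab <- object@labels
  if (length(lab) == 0) return("labels must be non-empty")
  u <- sort(unique(lab))
  if (!identical(u, seq(0L, max(lab))))
    return("cluster ids must be contiguous integers starting at 0")
  TRUE
})

#' Gene module anchored on a reference gene
#'
#' A named gene set, typically the genes most correlated with an anchor
#' marker (e.g. ACTA2 for the activated myofibroblast program).
#'
#' @slot name character scalar.
#' @slot anchorGene character scalar or `NA` for hand-built modules.
#' @slot genes character, unique member gene ids.
#' @slot method character, correlation method used in construction.
#' @export
setClass("GeneModule",
  representation(
    name = "character",
    anchorGene = "character",
    genes = "character",
    method = "character"
  )
)

setValidity("GeneModule", function(object) {
  if (anyDuplicated(object@genes)) return("module genes must be unique")
  if (!is.na(object@anchorGene) && !(object@anchorGene %in% object@genes))
    return("anchor gene must be a module member")
  TRUE
})

#' Diffusion-map and principal-curve trajectory
#'
#' Holds the diffusion components (eigenvectors of the density-normalized
#' diffusion operator scaled by their eigenvalues), the fitted principal
#' curve in the DC1-DC2 plane, and the per-cell arc-length pseudotime lambda.
#'
#' @slot dcs numeric matrix, cells x components.
#' @slot eigenvalues numeric in (0, 1], sorted decreasing.
#' @slot curve numeric matrix, ordered polyline in the DC1-DC2 plane
#'   (0-row matrix until a curve is fitted).
#' @slot lambda numeric, per-cell arc-length pseudotime (>= 0).
#' @slot orientation character: "unoriented", "as-fitted", "flipped" or
#'   "ambiguous".
#' @slot converged logical, principal-curve iteration convergence flag.
#' @export
setClass("Trajectory",
  representation(
    dcs = "matrix",
    eigenvalues = "numeric",
    curve = "matrix",
    lambda = "numeric",
    orientation = "character",
    converged = "logical"
  ),
  prototype(
    curve = matrix(numeric(0), 0, 2),
    lambda = numeric(0),
    orientation = "unoriented",
    converged = NA
  )
)

setValidity("Trajectory", function(object) {
  ev <- object@eigenvalues
  if (length(ev) != ncol(object@dcs))
    return("one eigenvalue per diffusion component required")
  if (any(ev <= 0) || any(ev > 1 + 1e-8))
    return("diffusion eigenvalues must lie in (0, 1]")
  if (any(diff(ev) > 1e-10))
    return("eigenvalues must be sorted decreasing")
  if (length(object@lambda) &&
      (length(object@lambda) != nrow(object@dcs) || any(object@lambda < -1e-12)))
    return("lambda must be non-negative with one value per cell")
  TRUE
})

#' Synthetic traction scene on an elastic substrate
#'
#' Paired traction and displacement fields on a regular grid, generated by the
#' Boussinesq half-space forward model for a gel of stated Young's modulus.
#' Tractions are in Pa, displacements in micrometres.
#'
#' @slot tx,ty numeric matrices, traction components (Pa).
#' @slot u,v numeric matrices, surface displacement components (um),
#'   including any added measurement noise.
#' @slot pixelSizeUm numeric, grid spacing (um).
#' @slot youngsModulusPa numeric, substrate Young's modulus (Pa).
#' @slot poissonRatio numeric in [0, 0.5].
#' @slot noiseSdUm numeric, SD of the Gaussian noise added to displacements.
#' @slot forceSpec data.frame describing the Gaussian force foci.
#' @export
setClass("TractionScene",
  representation(
    tx = "matrix", ty = "matrix",
    u = "matrix", v = "matrix",
    pixelSizeUm = "numeric",
    youngsModulusPa = "numeric",
    poissonRatio = "numeric",
    noiseSdUm = "numeric",
    forceSpec = "data.frame"
  )
)

setValidity("TractionScene", function(object) {
  dm <- dim(object@tx)
  if (!all(dim(object@ty) == dm, dim(object@u) == dm, dim(object@v) == dm))
    return("tx, ty, u, v must share dimensions")
  if (any(dm == 0)) return("zero-sized grid")
  if (object@youngsModulusPa <= 0) return("Young's modulus must be positive")
  if (object@poissonRatio < 0 || object@poissonRatio > 0.5)
    return("Poisson ratio must lie in [0, 0.5]")
  if (object@pixelSizeUm <= 0) return("pixel size must be positive")
  TRUE
})

#' Displacement field measured by particle image velocimetry
#'
#' @slot u,v numeric matrices, displacement components in pixels on the
#'   interrogation-window grid.
#' @slot valid logical matrix, FALSE where the correlation peak was unreliable.
#' @slot gridRow,gridCol numeric, image pixel coordinates of the window centres.
#' @slot windowPx integer interrogation window size.
#' @slot pixelSizeUm numeric, physical size of one image pixel (um).
#' @export
setClass("DisplacementField",
  representation(
    u = "matrix", v = "matrix",
    valid = "matrix",
    gridRow = "numeric", gridCol = "numeric",
    windowPx = "integer",
    pixelSizeUm = "numeric"
  )
)

setValidity("DisplacementField", function(object) {
  dm <- dim(object@u)
  if (!all(dim(object@v) == dm, dim(object@valid) == dm))
    return("u, v, valid must share dimensions")
  if (length(object@gridRow) != dm[1] || length(object@gridCol) != dm[2])
    return("grid coordinate lengths must match field dimensions")
  TRUE
})

#' Reconstructed traction field
#'
#' @slot tx,ty numeric matrices, traction components (Pa).
#' @slot youngsModulusPa,poissonRatio elastic constants used for inversion.
#' @slot regLambda numeric, Tikhonov regularization parameter.
#' @slot spacingUm numeric, grid spacing (um).
#' @export
setClass("TractionField",
  representation(
    tx = "matrix", ty = "matrix",
    youngsModulusPa = "numeric",
    poissonRatio = "numeric",
    regLambda = "numeric",
    spacingUm = "numeric"
  )
)

setValidity("TractionField", function(object) {
  if (!all(dim(object@tx) == dim(object@ty)))
    return("tx and ty must share dimensions")
  if (object@youngsModulusPa <= 0) return("Young's modulus must be positive")
  if (object@regLambda < 0) return("regularization parameter must be >= 0")
  TRUE
})

#' Quality-control report
#'
#' Itemizes how many cells each filtering rule flagged and how many survived.
#' Rule counts may overlap (a cell can fail several rules), so they need not
#' sum to the total removed.
#'
#' @slot nIn,nOut integer, cells before / after filtering.
#' @slot rules data.frame with columns `rule` and `flagged`.
#' @slot thresholds list of thresholds used.
#' @export
setClass("QcReport",
  representation(
    nIn = "integer",
    nOut = "integer",
    rules = "data.frame",
    thresholds = "list"
  )
)

setValidity("QcReport", function(object) {
  if (object@nOut > object@nIn) return("more cells out than in")
  TRUE
})
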