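#' @describeIn EmbeddingResult-class per-cell component scores
#' @param object an object of the documented class
#' @export
setGeneric("pcScores", function(object) standardGeneric("pcScores"))

#' @describeIn EmbeddingResult-class per-feature loadings
#' @export
setGeneric("pcLoadings", function(object) standardGeneric("pcLoadings"))

#' @describeIn EmbeddingResult-class fraction of variance per component
#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))

#' @describeIn EmbeddingResult-class number of significant components
#' @export
setGeneric("nSignificant", function(object) standardGeneric("nSignificant"))

#' @describeIn EmbeddingResult-class set the number of significant components
#' @param value replacement value
#' @export
setGeneric("nSignificant<-", function(object, value) standardGeneric("nSignificant<-"))

#' @describeIn ClusterResult-class per-cell cluster labels (0-based)
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @describeIn GeneModule-class member genes of a module
#' @export
setGeneric("moduleGenes", function(object) standardGeneric("moduleGenes"))

#' @describeIn Trajectory-class diffusion components (cells x components)
#' @export
setGeneric("diffusionComponents", function(object) standardGeneric("diffusionComponents"))

#' @describeIn Trajectory-class per-cell arc-length pseudotime
#' @export
setGeneric("pseudotime", function(object) standardGeneric("pseudotime"))

#' @describeIn Trajectory-class fitted principal-curve polyline
#' @export
setGeneric("curvePoints", function(object) standardGeneric("curvePoints"))

#' @describeIn TractionScene-class displacement components as a list(u, v)
#' @export
setGeneric("displacements", function(object) standardGeneric("displacements"))

#' @describeIn TractionScene-class traction components as a list(tx, ty)
#' @export
setGeneric("tractions", function(object) standardGeneric("tractions"))

#' Fit a principal curve through a two-column point cloud
#'
#' @param x a two-column numeric matrix or a [Trajectory-class] object (in
#'   which case the first two diffusion components are used).
#' @param ... passed to methods; see [fitPrincipalCurveMatrix()] for the
#'   algorithm parameters.
#' @return for a matrix, a list with elements `curve`, `lambda`, `converged`,
#'   `dist`; for a `Trajectory`, the object with curve and lambda filled in.
#' @export
setGeneric("fitPrincipalCurve", function(x, ...) standardGeneric("fitPrincipalCurve"))

setMethod("pcScores", "EmbeddingResult", function(object) object@scores)
setMethod("pcLoadings", "EmbeddingResult", function(object) object@loadings)
setMethod("varianceExplained", "EmbeddingResult", function(object) object@varianceExplained)
setMethod("nSignificant", "EmbeddingResult", function(object) object@nSignificant)
setMethod("nSignificant<-", "EmbeddingResult", function(object, value) {
  object@nSignificant <- as.integer(value)
  validObject(object)
  object
})

setMethod("clusterLabels", "ClusterResult", function(object) object@labels)
setMethod("moduleGenes", "GeneModule", function(object) object@genes)
setMethod("diffusionComponents", "Trajectory", function(object) object@dcs)
setMethod("pseudotime", "Trajectory", function(object) object@lambda)
setMethod("curvePoints", "Trajectory", function(object) object@curve)
setMethod("displacements", "TractionScene", function(object) list(u = object@u, v = object@v))
setMethod("tractions", "TractionScene", function(object) list(tx = object@tx, ty = object@ty))
setMethod("tractions", "TractionField", function(object) list(tx = object@tx, ty = object@ty))

setMethod("show", "EmbeddingResult", function(object) {
  cat("EmbeddingResult:", nrow(object@scores), "cells x", ncol(object@scores),
      "components\n")
  cat("  variance explained (first 5):",
      paste(sprintf("%.3f", head(object@varianceExplained, 5)), collapse = " "), "\n")
  cat("  significant components:",
      ifelse(is.na(object@nSignificant), "not tested", object@nSignificant), "\n")
})

setMethod("show", "ClusterResult", function(object) {
  tab <- table(object@labels)
  cat("ClusterResult:", length(object@labels), "cells in", length(tab),
      "clusters (modularity", sprintf("%.3f", object@modularity), ")\n")
})

setMethod("show", "GeneModule", function(object) {
  cat("GeneModule", sQuote(object@name), "with", length(object@genes), "genes")
  if (!is.na(object@anchorGene))
    cat(" anchored on", object@anchorGene, sprintf("(%s)", object@method))
  cat("\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@dcs), "cells,", ncol(object@dcs),
      "diffusion components\n")
  if (length(object@lambda))
    cat("  pseudotime range [0,", sprintf("%.3f", max(object@lambda)), "],",
        "orientation:", object@orientation, "\n")
})

setMethod("show", "TractionScene", function(object) {
  cat("TractionScene:", nrow(object@tx), "x", ncol(object@tx), "grid,",
      object@pixelSizeUm, "um/px, E =", object@youngsModulusPa, "Pa, nu =",
      object@poissonRatio, "\n")
  cat("  max |traction|:", sprintf("%.1f Pa,", max(tractionMagnitude(object))),
      "max |displacement|:",
      sprintf("%.3f um\n", max(sqrt(object@u^2 + object@v^2))))
})

setMethod("show", "DisplacementField", function(object) {
  cat("DisplacementField:", nrow(object@u), "x", ncol(object@u),
      "vectors,", sum(object@valid), "valid\n")
})

setMethod("show", "TractionField", function(object) {
  cat("TractionField:", nrow(object@tx), "x", ncol(object@tx), "grid, E =",
      object@youngsModulusPa, "Pa, lambda =", object@regLambda, "\n")
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", object@nIn, "cells in,", object@nOut, "kept,",
      object@nIn - object@nOut, "removed\n")
  for (i in seq_len(nrow(object@rules)))
    cat("  ", object@rules$rule[i], ":", object@rules$flagged[i], "flagged\n")
})

#' Traction magnitude map of a scene or reconstructed field
#'
#' @param object a [TractionScene-class] or [TractionField-class]
#' @return numeric matrix of traction magnitudes (Pa)
#' @export
setGeneric("tractionMagnitude", function(object) standardGeneric("tractionMagnitude"))
setMethod("tractionMagnitude", "TractionScene", function(object) sqrt(object@tx^2 + object@ty^2))
setMethod("tractionMagnitude", "TractionField", function(object) sqrt(object@tx^2 + object@ty^2))
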