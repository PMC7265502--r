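#' Default run configuration
#'
#' Nested per-stage parameter list mirroring every documented stage default.
#' The single root seed feeds all stages through fixed named substreams
#' (see [stageSeed()]).
#'
#' @param seed root seed.
#' @return nested list of class `RunConfig`.
#' @export
defaultRunConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = c("simulate", "preprocess", "reduce", "cluster", "score",
               "trajectory"),
    simulate = list(nCells = 3000L, nGenes = 2000L, continuumFraction = 0.6,
                    doubletRate = 0.05),
    preprocess = list(minGenes = 200, maxGenes = 4500, maxMitoFrac = 0.10,
                      scaleFactor = 10000, sdMult = 3),
    reduce = list(nBins = 20, dispersionZMin = 1, meanLow = 0.1, meanHigh = 8,
                  nComponents = 50, nPerm = 100, alpha = 0.05),
    cluster = list(k = 30, pruneThreshold = 1 / 15, resolution = 0.8,
                   minPct = 0.1, pAdjustMax = 0.01),
    score = list(nTop = 100, nBins = 25, genesPerBin = 100),
    trajectory = list(nComponents = 10, span = 1 / 3, smoothSpan = 0.5,
                      gridN = 100)
  ), class = "RunConfig")
}

#' Read / write a run configuration
#'
#' YAML round-trip of a [defaultRunConfig()] object. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return the configuration list, with defaults filled in.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  checkKeys <- function(given, template, where) {
    unknown <- setdiff(names(given), names(template))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", " in ", where,
           ": ", paste(unknown, collapse = ", "))
  }
  checkKeys(raw, def, "top level")
  out <- def
  for (nm in names(raw)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      checkKeys(raw[[nm]], def[[nm]], nm)
      out[[nm]][names(raw[[nm]])] <- raw[[nm]]
    } else {
      out[[nm]] <- raw[[nm]]
    }
  }
  out$seed <- as.integer(out$seed)
  class(out) <- "RunConfig"
  out
}

#' @rdname readRunConfig
#' @param config a `RunConfig` list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Variable genes, PCA and parallel analysis in one step
#'
#' Convenience wrapper chaining [findVariableGenes()], [scaleGenes()],
#' [runPCA()] and [permutationPA()], the reduction applied both to the full
#' census and, independently, to each cell-type subset under study.
#'
#' @param sce `SingleCellExperiment` with a `logcounts` assay.
#' @param params list with the reduce-stage parameters of
#'   [defaultRunConfig()].
#' @param seed RNG seed for the permutation test.
#' @return an [EmbeddingResult-class] with `nSignificant` filled in.
#' @export
reduceExpression <- function(sce, params = defaultRunConfig()$reduce,
                             seed = 1) {
  hvg <- findVariableGenes(sce, params$nBins, params$dispersionZMin,
                           params$meanLow, params$meanHigh)
  if (length(hvg) < 2)
    stop("fewer than two variable genes selected")
  scaled <- scaleGenes(sce, genes = hvg)
  emb <- runPCA(scaled, params$nComponents)
  ns <- permutationPA(scaled, params$nPerm, params$alpha, seed = seed,
                      nComponents = ncol(pcScores(emb)))
  nSignificant(emb) <- ns
  emb
}

#' Run the stromal census pipeline
#'
#' Executes the configured stages -- simulate (or load), first- and
#' second-round QC with log-normalization, variable genes / PCA / parallel
#' analysis, SNN-Louvain clustering with markers, module scoring, and
#' diffusion-map principal-curve pseudotime on the continuum cell type --
#' writing each stage's outputs and a manifest of parameters and seeds to
#' `outDir`. Reruns with the same config are bit-identical for the
#' deterministic stages.
#'
#' @param config a [defaultRunConfig()]-style list.
#' @param outDir output directory.
#' @param sce optional input `SingleCellExperiment`; when supplied the
#'   simulate stage is skipped.
#' @return (invisibly) a list with the key in-memory results.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir, sce = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  stages <- config$stages

  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (is.null(sce) && "simulate" %in% stages) {
    sce <- step("simulate", {
      cfg <- do.call(simConfig, c(config$simulate,
                                  list(seed = stageSeed(seed, "simulate"))))
      simulateStromalCounts(cfg)
    })
    writeCounts10x(sce, file.path(outDir, "counts"))
    utils::write.csv(as.data.frame(groundTruth(sce)),
                     file.path(outDir, "ground_truth.csv"))
  }
  if (is.null(sce)) stop("no input data: supply sce or enable simulate")

  if ("preprocess" %in% stages) {
    pp <- config$preprocess
    f1 <- step("preprocess", filterCells(sce, pp$minGenes, pp$maxGenes,
                                         pp$maxMitoFrac))
    sce <- f1$sce
    mk <- S4Vectors::metadata(sce)$marker_sets
    rep2 <- NULL
    if (!is.null(mk) && "cell_type" %in%
        colnames(SummarizedExperiment::colData(sce))) {
      f2 <- step("preprocess", secondRoundQc(sce, markerSets = mk,
                                             sdMult = pp$sdMult))
      sce <- f2$sce
      rep2 <- f2$report
    }
    sce <- step("preprocess", logNormalizeCounts(sce, pp$scaleFactor))
    qc <- data.frame(rule = f1$report@rules$rule,
                     flagged = f1$report@rules$flagged)
    if (!is.null(rep2)) qc <- rbind(qc, rep2@rules)
    utils::write.csv(qc, file.path(outDir, "qc_report.csv"), row.names = FALSE)
    results$sce <- sce
  }

  emb <- NULL
  if ("reduce" %in% stages) {
    emb <- step("reduce", reduceExpression(sce, config$reduce,
                                           seed = stageSeed(seed, "reduce")))
    utils::write.csv(pcScores(emb), file.path(outDir, "pca_scores.csv"))
    writeLines(attr(emb, "variableGenes") %||% emb@genesUsed,
               file.path(outDir, "variable_genes.txt"))
    results$embedding <- emb
    results$variableGenes <- emb@genesUsed
  }

  if ("cluster" %in% stages && !is.null(emb)) {
    cf <- config$cluster
    nUse <- max(2, nSignificant(emb))
    g <- step("cluster", buildSnnGraph(
      pcScores(emb)[, seq_len(nUse), drop = FALSE],
      k = min(cf$k, ncol(sce) - 1), pruneThreshold = cf$pruneThreshold))
    cl <- step("cluster", louvainCluster(g, cf$resolution,
                                         seed = stageSeed(seed, "cluster")))
    markers <- step("cluster", findMarkers(sce, clusterLabels(cl),
                                           cf$minPct, cf$pAdjustMax))
    utils::write.csv(data.frame(cell = colnames(sce),
                                cluster = clusterLabels(cl)),
                     file.path(outDir, "clusters.csv"), row.names = FALSE)
    utils::write.table(markers, file.path(outDir, "markers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$clusters <- cl
    results$markers <- markers
  }

  if ("trajectory" %in% stages) {
    tj <- config$trajectory
    md <- S4Vectors::metadata(sce)
    ct <- SummarizedExperiment::colData(sce)$cell_type
    cont <- md$config$continuumType %||% "myofibroblast"
    onCurve <- which(!is.na(ct) & ct == cont)
    if (length(onCurve) >= tj$nComponents + 2) {
      traj <- step("trajectory", {
        # the subset gets its own variable genes / PCA / parallel analysis,
        # mirroring the per-cell-type re-analysis of the census workflow
        subEmb <- reduceExpression(sce[, onCurve], config$reduce,
                                   seed = stageSeed(seed, "trajectory"))
        dm <- diffusionMap(pcScores(subEmb)[,
                  seq_len(max(2, nSignificant(subEmb))), drop = FALSE],
                  nComponents = min(tj$nComponents, length(onCurve) - 2))
        fitPrincipalCurve(dm, span = tj$span)
      })
      progB <- md$generative$programB
      if (!is.null(progB)) {
        sceSub <- sce[, onCurve]
        sc <- step("score", moduleScore(sceSub,
                     intersect(progB, rownames(sceSub)),
                     nBins = config$score$nBins,
                     genesPerBin = config$score$genesPerBin,
                     seed = stageSeed(seed, "score")))
        traj <- step("trajectory", orientPseudotime(traj, sc))
      }
      utils::write.csv(data.frame(cell = colnames(sce)[onCurve],
                                  diffusionComponents(traj)[, 1:2],
                                  lambda = pseudotime(traj)),
                       file.path(outDir, "pseudotime.csv"), row.names = FALSE)
      results$trajectory <- traj
      results$trajectoryCells <- onCurve
    }
  }

  manifest <- list(
    package = "stromalcensus",
    version = as.character(utils::packageVersion("stromalcensus")),
    seed = seed,
    stageSeeds = lapply(stats::setNames(nm = c("simulate", "preprocess",
        "reduce", "cluster", "score", "trajectory", "tfm")),
        function(s) stageSeed(seed, s)),
    config = unclass(config))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(results)
}
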