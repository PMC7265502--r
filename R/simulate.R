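#' Configuration for the synthetic stromal-census generator
#'
#' Defines a multi-cell-type droplet scRNA-seq experiment in which one cell
#' type (by default the myofibroblast) lies on a one-dimensional activation
#' continuum between two terminal expression programs -- an analogue of the
#' ACTA2-low and CD82-high myofibroblast states -- while the remaining types
#' are discrete. Library sizes are log-normal, mitochondrial genes carry a
#' stated share of expression, and a fraction of barcodes are doublets.
#'
#' Default sizes reflect a typical droplet channel: 3000 cells recovered,
#' 2000 genes retained, myofibroblasts ~60% of the stroma, median library
#' ~2500 UMIs.
#'
#' @param nCells,nGenes experiment dimensions.
#' @param cellTypeProportions named numeric summing to 1; when `NULL` a
#'   default stroma of myofibroblast (= `continuumFraction`), fibroblast,
#'   immune and endothelial cells is used.
#' @param continuumFraction fraction of cells on the activation continuum
#'   (ignored when `cellTypeProportions` is supplied).
#' @param continuumType name of the continuum cell type.
#' @param librarySizeLogMean,librarySizeLogSd log-normal library-size
#'   parameters (natural log of UMIs).
#' @param nProgramGenes genes in each terminal program.
#' @param programAGenes,programBGenes optional explicit disjoint gene index
#'   sets for the terminal programs.
#' @param markerGenesPerType canonical marker genes planted per cell type.
#' @param markerFold,programFold expression fold-up applied to marker /
#'   program genes in the type that owns them.
#' @param markerSuppression multiplier on a marker gene's baseline weight in
#'   every other cell type (default 0.001): canonical markers are selectively
#'   expressed, which is what makes marker co-detection informative about
#'   doublets.
#' @param mitoGeneFraction fraction of genes flagged mitochondrial.
#' @param mitoMass share of each cell's expression carried by mitochondrial
#'   genes.
#' @param doubletRate fraction of barcodes that are doublets.
#' @param seed integer RNG seed.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nCells = 3000L, nGenes = 2000L,
                      cellTypeProportions = NULL,
                      continuumFraction = 0.6,
                      continuumType = "myofibroblast",
                      librarySizeLogMean = log(2500),
                      librarySizeLogSd = 0.35,
                      nProgramGenes = 75L,
                      programAGenes = NULL, programBGenes = NULL,
                      markerGenesPerType = 10L,
                      markerFold = 12, programFold = 10,
                      markerSuppression = 0.001,
                      mitoGeneFraction = 0.015,
                      mitoMass = 0.05,
                      doubletRate = 0.05,
                      seed = 1L) {
  if (is.null(cellTypeProportions)) {
    rest <- 1 - continuumFraction
    cellTypeProportions <- c(continuumFraction,
                             rest * c(0.55, 0.25, 0.20))
    names(cellTypeProportions) <- c(continuumType, "fibroblast", "immune",
                                    "endothelial")
    if (continuumFraction == 0)
      cellTypeProportions <- cellTypeProportions[-1]
  } else {
    continuumFraction <- if (continuumType %in% names(cellTypeProportions))
      unname(cellTypeProportions[continuumType]) else 0
  }
  cfg <- structure(list(
    nCells = as.integer(nCells), nGenes = as.integer(nGenes),
    cellTypeProportions = cellTypeProportions,
    continuumFraction = continuumFraction,
    continuumType = continuumType,
    librarySizeLogMean = librarySizeLogMean,
    librarySizeLogSd = librarySizeLogSd,
    nProgramGenes = as.integer(nProgramGenes),
    programAGenes = programAGenes, programBGenes = programBGenes,
    markerGenesPerType = as.integer(markerGenesPerType),
    markerFold = markerFold, programFold = programFold,
    markerSuppression = markerSuppression,
    mitoGeneFraction = mitoGeneFraction, mitoMass = mitoMass,
    doubletRate = doubletRate, seed = as.integer(seed)
  ), class = "SimConfig")
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  p <- cfg$cellTypeProportions
  if (is.null(names(p)) || any(!nzchar(names(p))))
    stop("cell type proportions must be named")
  if (abs(sum(p) - 1) > 1e-9)
    stop("cell type proportions must sum to 1 (got ", sum(p), ")")
  fr <- c(cfg$continuumFraction, cfg$mitoGeneFraction, cfg$mitoMass,
          cfg$doubletRate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$nCells < 1 || cfg$nGenes < 10)
    stop("nCells must be >= 1 and nGenes >= 10")
  if (!is.null(cfg$programAGenes) && !is.null(cfg$programBGenes) &&
      length(intersect(cfg$programAGenes, cfg$programBGenes)))
    stop("program gene sets must be disjoint")
  invisible(TRUE)
}

#' Simulate a ground-truthed stromal UMI count matrix
#'
#' Draws each cell's counts multinomially given a log-normal library size and
#' a cell-type expression profile. Continuum cells use the convex combination
#' `p(t) = (1 - t) * programA + t * programB` of the two terminal program
#' profiles with latent `t ~ Uniform(0, 1)`, so every program gene's expected
#' count is linear (hence monotone) in `t`. Doublets are sums of two randomly
#' chosen parent cells' draws. Deterministic given the config seed.
#'
#' @param config a [simConfig()] object.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay
#'   `counts` (genes x cells, sparse), ground truth in `colData`
#'   (`cell_type`, `activation_t`, `is_doublet`, `library_size`),
#'   gene annotation in `rowData` (`is_mito`, `program`, `marker_of`) and
#'   generator metadata (`marker_sets`, generative profiles) in `metadata`.
#' @export
simulateStromalCounts <- function(config) {
  validateSimConfig(config)
  withr::with_seed(config$seed, simulateStromalCountsImpl(config))
}

simulateStromalCountsImpl <- function(cfg) {
  G <- cfg$nGenes
  n <- cfg$nCells
  types <- names(cfg$cellTypeProportions)
  geneIds <- sprintf("gene%04d", seq_len(G))

  nMito <- round(cfg$mitoGeneFraction * G)
  mitoIdx <- if (nMito > 0) sampleExact(seq_len(G), nMito) else integer(0)
  isMito <- seq_len(G) %in% mitoIdx
  geneIds[mitoIdx] <- sprintf("MT-gene%04d", mitoIdx)

  # baseline expression weights, heavy-tailed as in droplet data
  w <- rgamma(G, shape = 0.45, rate = 1) + 1e-6
  if (nMito > 0) {
    w[isMito] <- w[isMito] / sum(w[isMito]) * cfg$mitoMass
    w[!isMito] <- w[!isMito] / sum(w[!isMito]) * (1 - cfg$mitoMass)
  } else {
    w <- w / sum(w)
  }

  # reserve disjoint gene pools: terminal programs, then per-type markers
  pool <- setdiff(seq_len(G), mitoIdx)
  progA <- cfg$programAGenes
  progB <- cfg$programBGenes
  hasContinuum <- cfg$continuumType %in% types
  if (hasContinuum) {
    nProg <- min(cfg$nProgramGenes, floor(length(pool) / 4))
    if (is.null(progA)) {
      progA <- sampleExact(pool, nProg)
      pool <- setdiff(pool, progA)
    } else pool <- setdiff(pool, progA)
    if (is.null(progB)) {
      progB <- sampleExact(pool, nProg)
      pool <- setdiff(pool, progB)
    } else pool <- setdiff(pool, progB)
    if (length(intersect(progA, progB)))
      stop("program gene sets must be disjoint")
  } else {
    progA <- progB <- integer(0)
  }
  markerSets <- list()
  for (ty in types) {
    mk <- sampleExact(pool, min(cfg$markerGenesPerType, length(pool)))
    pool <- setdiff(pool, mk)
    markerSets[[ty]] <- mk
  }

  # per-type expression profiles (probability vectors over genes)
  profiles <- matrix(0, G, length(types), dimnames = list(geneIds, types))
  pA <- pB <- NULL
  for (ty in types) {
    p <- w
    # canonical markers: boosted in their own type, suppressed elsewhere
    for (other in setdiff(types, ty))
      p[markerSets[[other]]] <- p[markerSets[[other]]] * cfg$markerSuppression
    p[markerSets[[ty]]] <- p[markerSets[[ty]]] * cfg$markerFold
    if (ty == cfg$continuumType) {
      a <- p; a[progA] <- a[progA] * cfg$programFold
      b <- p; b[progB] <- b[progB] * cfg$programFold
      pA <- stats::setNames(a / sum(a), geneIds)
      pB <- stats::setNames(b / sum(b), geneIds)
      profiles[, ty] <- (pA + pB) / 2
    } else {
      profiles[, ty] <- p / sum(p)
    }
  }

  cellType <- types[sample.int(length(types), n, replace = TRUE,
                               prob = cfg$cellTypeProportions)]
  activationT <- ifelse(cellType == cfg$continuumType, runif(n), NA_real_)
  libSize <- pmax(1, round(rlnorm(n, cfg$librarySizeLogMean,
                                  cfg$librarySizeLogSd)))

  counts <- matrix(0L, G, n)
  for (i in seq_len(n)) {
    p <- if (!is.na(activationT[i]))
      (1 - activationT[i]) * pA + activationT[i] * pB
    else profiles[, cellType[i]]
    counts[, i] <- rmultinom(1, libSize[i], p)
  }

  isDoublet <- rep(FALSE, n)
  nDoub <- round(cfg$doubletRate * n)
  if (nDoub > 0 && n >= 3) {
    slots <- sampleExact(seq_len(n), nDoub)
    isDoublet[slots] <- TRUE
    parentsPool <- which(!isDoublet)
    for (i in slots) {
      par <- sampleExact(parentsPool, 2)
      counts[, i] <- counts[, par[1]] + counts[, par[2]]
      libSize[i] <- sum(counts[, i])
      cellType[i] <- cellType[par[1]]
      activationT[i] <- activationT[par[1]]
    }
  }

  cellIds <- sprintf("cell%05d", seq_len(n))
  dimnames(counts) <- list(geneIds, cellIds)
  csp <- as(as(counts, "CsparseMatrix"), "dMatrix")

  program <- rep(NA_character_, G)
  program[progA] <- "A"
  program[progB] <- "B"
  markerOf <- rep(NA_character_, G)
  for (ty in types) markerOf[markerSets[[ty]]] <- ty

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = csp),
    colData = S4Vectors::DataFrame(
      cell_type = cellType, activation_t = activationT,
      is_doublet = isDoublet, library_size = as.numeric(libSize),
      row.names = cellIds),
    rowData = S4Vectors::DataFrame(
      gene_id = geneIds, is_mito = isMito, program = program,
      marker_of = markerOf, row.names = geneIds)
  )
  S4Vectors::metadata(sce) <- list(
    config = cfg,
    marker_sets = lapply(markerSets, function(i) geneIds[i]),
    generative = list(profiles = profiles, pA = pA, pB = pB,
                      programA = geneIds[progA], programB = geneIds[progB])
  )
  sce
}

#' Ground-truth table of a simulated experiment
#'
#' @param sce a `SingleCellExperiment` from [simulateStromalCounts()].
#' @return `DataFrame` with `cell_type`, `activation_t`, `is_doublet`.
#' @export
groundTruth <- function(sce) {
  cd <- SummarizedExperiment::colData(sce)
  need <- c("cell_type", "activation_t", "is_doublet")
  if (!all(need %in% colnames(cd)))
    stop("object carries no ground-truth columns")
  cd[, need]
}
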