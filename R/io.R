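#' Read a 10x-style count directory
#'
#' Reads `matrix.mtx` (1-based matrix-market triplets), `barcodes.tsv` and
#' `features.tsv` (or `genes.tsv`; columns: id, symbol, optionally type).
#' The genes-as-rows dialect is auto-detected against the table lengths.
#'
#' @param dir path containing the three files.
#' @return a `SingleCellExperiment` with a sparse `counts` assay
#'   (genes x cells).
#' @export
readCounts10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bc <- file.path(dir, "barcodes.tsv")
  ft <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  for (f in c(mtx, bc, ft))
    if (!file.exists(f)) stop("missing file: ", f)
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) stop("cannot parse ", mtx, ": ",
                                         conditionMessage(e)))
  barcodes <- readLines(bc)
  features <- read.delim(ft, header = FALSE, stringsAsFactors = FALSE)
  nG <- nrow(features); nC <- length(barcodes)
  if (nrow(m) == nG && ncol(m) == nC) {
    # genes-as-rows, the 10x dialect
  } else if (nrow(m) == nC && ncol(m) == nG) {
    m <- Matrix::t(m)
  } else {
    stop("matrix dimensions ", nrow(m), "x", ncol(m),
         " match neither features (", nG, ") nor barcodes (", nC, ")")
  }
  m <- as(m, "CsparseMatrix")
  geneIds <- features[[1]]
  dimnames(m) <- list(geneIds, barcodes)
  rd <- S4Vectors::DataFrame(gene_id = geneIds, row.names = geneIds)
  if (ncol(features) >= 2) rd$symbol <- features[[2]]
  rd$is_mito <- grepl("^MT-", geneIds, ignore.case = TRUE)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), rowData = rd,
    colData = S4Vectors::DataFrame(row.names = barcodes))
}

#' Write a count matrix in the 10x directory layout
#'
#' @param sce `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeCounts10x <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  rd <- SummarizedExperiment::rowData(sce)
  symbol <- if ("symbol" %in% colnames(rd)) rd$symbol else rownames(sce)
  utils::write.table(data.frame(rownames(sce), symbol),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a vector field as a tidy CSV grid
#'
#' @param x,y component matrices.
#' @param spacing grid spacing (um), used for the coordinate columns.
#' @param path output file.
#' @param names column names for the two components.
#' @export
writeFieldCsv <- function(x, y, spacing, path, names = c("u", "v")) {
  df <- data.frame(
    x_um = rep((seq_len(ncol(x)) - 1) * spacing, each = nrow(x)),
    y_um = rep((seq_len(nrow(x)) - 1) * spacing, times = ncol(x)),
    a = as.vector(x), b = as.vector(y))
  colnames(df)[3:4] <- names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
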