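#' Library-size normalization of nucleus counts
#'
#' Per-cell size factors are total counts divided by the mean total count
#' (so factors average 1), and the normalized value is
#' \code{log(1 + count / sizeFactor)}.  Factors are stored in
#' \code{colData(cells)$sizeFactor} and the normalized matrix in the
#' \code{"lognorm"} assay.  Doubling every count doubles the factors and
#' leaves normalized values unchanged.
#'
#' @param cells a \code{SingleCellExperiment} with nonnegative counts and
#'   no all-zero cells.
#' @return the object with a \code{lognorm} assay and size factors added.
#' @examples
#' sce <- simCells(simConfig(nDonors = 4, nGenes = 30,
#'                           nCellsPerDonor = c(10, 20), seed = 1))
#' sce <- normalizeCells(sce)
#' @export
normalizeCells <- function(cells) {
  cts <- SummarizedExperiment::assay(cells, "counts")
  tot <- Matrix::colSums(cts)
  if (any(tot == 0))
    stop("all-zero cell(s): ",
         paste(utils::head(colnames(cells)[tot == 0], 5), collapse = ", "))
  sf <- tot / mean(tot)
  norm <- log1p(as.matrix(cts) %*% Matrix::Diagonal(x = 1 / sf))
  norm <- as.matrix(norm)
  dimnames(norm) <- dimnames(cts)
  SummarizedExperiment::assay(cells, "lognorm") <- norm
  SummarizedExperiment::colData(cells)$sizeFactor <- as.numeric(sf)
  cells
}

#' Aggregate normalized expression to donor-level pseudobulk
#'
#' For one cell type, the pseudobulk value for (donor, gene) is the mean
#' normalized expression over that donor's cells of the type.  Donors with
#' no cells of the type are excluded (listed in the metadata), never
#' imputed.  The result is invariant to cell ordering.
#'
#' @param cells a normalized \code{SingleCellExperiment} (see
#'   \code{\link{normalizeCells}}); \code{colData} must carry
#'   \code{donor} and, unless \code{cellType} is \code{NULL}, a
#'   \code{cellType} column.
#' @param cellType cell-type label to aggregate, or \code{NULL} to use
#'   every cell.
#' @return a \code{SummarizedExperiment} (genes x donors) with assay
#'   \code{pseudobulk}; \code{metadata()$excludedDonors} lists donors
#'   without cells of the type (relative to all donors present in the
#'   input), and \code{metadata()$normalization} documents the scheme.
#' @export
aggregatePseudobulk <- function(cells, cellType = NULL) {
  cd <- SummarizedExperiment::colData(cells)
  if (!"lognorm" %in% SummarizedExperiment::assayNames(cells))
    stop("run normalizeCells() first")
  allDonors <- sort(unique(cd$donor))
  keep <- rep(TRUE, ncol(cells))
  if (!is.null(cellType)) {
    if (!"cellType" %in% colnames(cd))
      stop("colData lacks a cellType column")
    if (!cellType %in% cd$cellType)
      stop("unknown cell-type label: ", cellType)
    keep <- cd$cellType == cellType
  }
  norm <- SummarizedExperiment::assay(cells, "lognorm")[, keep,
                                                        drop = FALSE]
  donor <- cd$donor[keep]
  used <- sort(unique(donor))
  ind <- Matrix::sparseMatrix(i = seq_along(donor),
                              j = match(donor, used),
                              x = 1, dims = c(length(donor), length(used)))
  ncell <- Matrix::colSums(ind)
  pb <- as.matrix(norm %*% ind) %*% diag(1 / ncell, length(used))
  dimnames(pb) <- list(rownames(norm), used)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(pseudobulk = pb),
    colData = S4Vectors::DataFrame(donor = used,
                                   nCells = as.integer(ncell),
                                   row.names = used),
    metadata = list(excludedDonors = setdiff(allDonors, used),
                    cellType = if (is.null(cellType)) "all" else cellType,
                    normalization =
                      "library-size factors (unit mean), log1p"))
}

#' Expression principal components of a pseudobulk matrix
#'
#' PCA of the donor-by-gene matrix after centering and unit-variance
#' scaling of genes.  Constant genes are dropped with a warning before
#' scaling.  Component signs follow a deterministic convention: the
#' largest-magnitude gene loading of each component is positive, so
#' repeated runs are byte-identical.
#'
#' @param pb a pseudobulk \code{SummarizedExperiment} (genes x donors).
#' @param k number of components (\code{k < min(donors, genes)}).
#' @return numeric matrix, donors x k, columns \code{PC1..PCk}.
#' @export
expressionPcs <- function(pb, k = 20) {
  x <- t(SummarizedExperiment::assay(pb, "pseudobulk"))  # donors x genes
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before scaling")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (k >= min(dim(x)))
    stop("k must be < min(donors, genes)")
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}
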