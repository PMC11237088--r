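#' Cell-level QC configuration
#'
#' Thresholds for the nucleus-level filters: minimum detected genes,
#' maximum mitochondrial/ribosomal/hemoglobin count fractions, minimum
#' log10(genes)/log10(UMI), and the half-width multiplier for the
#' sigmoid-derived total-UMI window (\code{log(4)} by default, placing the
#' cutoffs where the fitted logistic CDF equals 0.2 and 0.8).
#'
#' @param minGenes minimum detected genes per nucleus (default 200).
#' @param maxMitoFrac maximum mitochondrial count fraction (default 0.05).
#' @param maxRiboFrac maximum ribosomal count fraction (default 0.05).
#' @param maxHemoglobinFrac maximum hemoglobin count fraction
#'   (default 0.001).
#' @param minLog10GenesPerUmi minimum log10(genes detected)/log10(total
#'   UMI) (default 0.8).
#' @param sigmoidScaleMultiplier cutoff half-width in units of the fitted
#'   logistic scale (default \code{log(4)}).
#' @return a validated list of class \code{QcConfig}.
#' @export
qcConfig <- function(minGenes = 200, maxMitoFrac = 0.05,
                     maxRiboFrac = 0.05, maxHemoglobinFrac = 0.001,
                     minLog10GenesPerUmi = 0.8,
                     sigmoidScaleMultiplier = log(4)) {
  fr <- c(maxMitoFrac, maxRiboFrac, maxHemoglobinFrac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (sigmoidScaleMultiplier <= 0) stop("multiplier must be > 0")
  structure(list(minGenes = minGenes, maxMitoFrac = maxMitoFrac,
                 maxRiboFrac = maxRiboFrac,
                 maxHemoglobinFrac = maxHemoglobinFrac,
                 minLog10GenesPerUmi = minLog10GenesPerUmi,
                 sigmoidScaleMultiplier = sigmoidScaleMultiplier),
            class = "QcConfig")
}

#' Fit a logistic CDF to the log10-UMI distribution and derive cutoffs
#'
#' A logistic cumulative curve \code{F(x) = 1/(1 + exp(-(x - mu)/s))} is
#' fitted to the empirical CDF of per-cell log10 total UMI by least
#' squares; the retained window is \code{mu +/- multiplier * s}, so with
#' the default \code{multiplier = log(4)} the cutoffs sit where the fitted
#' CDF equals 1/5 and 4/5.  If the optimizer fails or the fit is poor
#' (RMSE above 0.1 against the empirical CDF) the cutoffs fall back to the
#' 1st/99th percentiles and \code{converged} is \code{FALSE}.
#'
#' @param log10Umi numeric vector of per-cell log10 total UMI (>= 50
#'   finite values with nonzero spread).
#' @param config a \code{\link{qcConfig}}.
#' @return a \linkS4class{SigmoidFit}.
#' @examples
#' x <- qlogis(ppoints(500), location = 3.5, scale = 0.1)
#' fitSigmoidCutoffs(x)
#' @export
fitSigmoidCutoffs <- function(log10Umi, config = qcConfig()) {
  x <- log10Umi[is.finite(log10Umi)]
  if (length(x) < 50)
    stop("degenerate input: need >= 50 finite log10-UMI values")
  if (stats::sd(x) == 0)
    stop("degenerate input: zero variance in log10 UMI")
  xs <- sort(x)
  n <- length(xs)
  Femp <- (seq_len(n) - 0.5) / n
  sse <- function(par) {
    if (par[2] <= 0) return(1e10)
    sum((stats::plogis(xs, location = par[1], scale = par[2]) - Femp)^2)
  }
  init <- c(stats::median(xs),
            max(stats::IQR(xs) / (2 * log(3)), 1e-3))
  opt <- try(stats::optim(init, sse, method = "Nelder-Mead",
                          control = list(reltol = 1e-12,
                                         maxit = 5000)), silent = TRUE)
  m <- config$sigmoidScaleMultiplier
  ok <- !inherits(opt, "try-error") && opt$convergence == 0 &&
    opt$par[2] > 0 && sqrt(opt$value / n) <= 0.1
  if (ok) {
    mu <- opt$par[1]; s <- opt$par[2]
    new("SigmoidFit", mu = mu, s = s, lower = mu - m * s,
        upper = mu + m * s, multiplier = m, converged = TRUE)
  } else {
    q <- stats::quantile(xs, c(0.01, 0.99), names = FALSE)
    new("SigmoidFit", mu = NA_real_, s = NA_real_, lower = q[1],
        upper = q[2], multiplier = m, converged = FALSE)
  }
}

#' Compute per-cell QC statistics from counts and gene classes
#'
#' Adds \code{nGenesDetected}, \code{totalUmi}, \code{fracMito},
#' \code{fracRibo}, \code{fracHemoglobin} and \code{log10GenesPerUmi} to
#' the cell metadata, using the \code{geneClass} row annotation
#' (\code{mito}/\code{ribo}/\code{hemoglobin}/\code{other}).
#'
#' @param cells a \code{SingleCellExperiment} with a \code{counts} assay.
#' @return the object with the QC columns added to \code{colData}.
#' @export
computeCellQcStats <- function(cells) {
  rd <- SummarizedExperiment::rowData(cells)
  if (!"geneClass" %in% colnames(rd))
    stop("configuration error: rowData lacks the 'geneClass' gene-set ",
         "annotation needed for mito/ribo/hemoglobin fractions")
  cts <- SummarizedExperiment::assay(cells, "counts")
  tot <- Matrix::colSums(cts)
  ng <- Matrix::colSums(cts > 0)
  fr <- function(cls) {
    idx <- rd$geneClass == cls
    if (!any(idx)) return(rep(0, ncol(cts)))
    as.numeric(Matrix::colSums(cts[idx, , drop = FALSE])) / pmax(tot, 1)
  }
  l10 <- ifelse(tot > 1 & ng > 0, log10(ng) / log10(tot), 0)
  cd <- SummarizedExperiment::colData(cells)
  cd$nGenesDetected <- as.integer(ng)
  cd$totalUmi <- as.numeric(tot)
  cd$fracMito <- fr("mito")
  cd$fracRibo <- fr("ribo")
  cd$fracHemoglobin <- fr("hemoglobin")
  cd$log10GenesPerUmi <- l10
  SummarizedExperiment::colData(cells) <- cd
  cells
}

# fixed attribution order for the filter report
.qcRules <- c("gene_count", "mito", "ribo", "hemoglobin", "genes_per_umi",
              "umi_range")

#' Apply the nucleus-level quality filters
#'
#' Removes cells with (in this fixed attribution order) fewer detected
#' genes than \code{minGenes}; mitochondrial, ribosomal or hemoglobin
#' count fractions above their thresholds; log10(genes)/log10(UMI) below
#' \code{minLog10GenesPerUmi}; or log10 total UMI outside the
#' sigmoid-derived window.  Each removed cell is attributed to the first
#' failing rule, so the per-rule counts partition the removed set.
#'
#' @param cells a \code{SingleCellExperiment}; per-cell QC statistics are
#'   computed from counts and \code{geneClass} row annotation if absent
#'   from \code{colData}.
#' @param config a \code{\link{qcConfig}}.
#' @param sigmoidFit optional precomputed \linkS4class{SigmoidFit}; when
#'   \code{NULL} the fit runs on the input cells' log10 total UMI.
#'   Passing a fixed fit makes filtering idempotent.
#' @return list with \code{cells} (the filtered object) and \code{report},
#'   a \code{FilterReport} list: per-rule removal \code{counts}, retained
#'   and removed cell ids, the applied \code{thresholds}, the
#'   \code{sigmoidFit}, and a per-cell table carrying any externally
#'   supplied \code{doublet} flag as a pass-through column.
#' @export
applyCellFilters <- function(cells, config = qcConfig(),
                             sigmoidFit = NULL) {
  cd <- SummarizedExperiment::colData(cells)
  need <- c("nGenesDetected", "totalUmi", "fracMito", "fracRibo",
            "fracHemoglobin", "log10GenesPerUmi")
  if (!all(need %in% colnames(cd))) {
    cells <- computeCellQcStats(cells)
    cd <- SummarizedExperiment::colData(cells)
  }
  if (is.null(sigmoidFit))
    sigmoidFit <- fitSigmoidCutoffs(log10(pmax(cd$totalUmi, 1)), config)
  l10umi <- log10(pmax(cd$totalUmi, 1))
  fails <- cbind(
    gene_count = cd$nGenesDetected < config$minGenes,
    mito = cd$fracMito > config$maxMitoFrac,
    ribo = cd$fracRibo > config$maxRiboFrac,
    hemoglobin = cd$fracHemoglobin > config$maxHemoglobinFrac,
    genes_per_umi = cd$log10GenesPerUmi < config$minLog10GenesPerUmi,
    umi_range = l10umi < sigmoidFit@lower | l10umi > sigmoidFit@upper)
  firstFail <- apply(fails, 1, function(r)
    if (any(r)) .qcRules[which(r)[1]] else NA_character_)
  removed <- !is.na(firstFail)
  counts <- vapply(.qcRules, function(r)
    sum(firstFail == r, na.rm = TRUE), 0L)
  perCell <- data.frame(cell = colnames(cells), rule = firstFail,
                        doublet = if ("doublet" %in% colnames(cd))
                          cd$doublet else NA,
                        stringsAsFactors = FALSE)
  report <- structure(list(counts = counts,
                           retained = colnames(cells)[!removed],
                           removed = colnames(cells)[removed],
                           thresholds = unclass(config),
                           sigmoidFit = sigmoidFit,
                           perCell = perCell),
                      class = "FilterReport")
  list(cells = cells[, !removed], report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", length(x$retained), "retained,",
      length(x$removed), "removed\n")
  print(x$counts)
  invisible(x)
}
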