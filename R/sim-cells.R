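#' Simulate single-nucleus counts with a condition-enriched subpopulation
#'
#' Counts are negative-binomial with gene-specific dispersions sampled
#' log-normally and per-cell lognormal library-size factors, the structure
#' the QC and normalization stages assume.  A designated subpopulation has a
#' distinct mean profile over a marker-gene block and a condition-dependent
#' frequency; a configurable fraction of cells violates QC rules (few
#' detected genes, or an inflated mitochondrial share) to exercise the QC
#' module.  Optional planted cis-eQTL effects shift per-donor gene means
#' multiplicatively by \code{exp(beta * dosage)}, i.e. additively on the log
#' scale read out by the pseudobulk estimator.
#'
#' Gene metadata assigns a \code{geneClass} (\code{mito}, \code{ribo},
#' \code{hemoglobin} or \code{other}) to the leading genes so fraction-based
#' QC rules are computable; cell metadata records donor, condition, the true
#' subpopulation label and the planted QC-violation flag.
#'
#' @param config a \code{\link{simConfig}}; donors are split evenly between
#'   conditions \code{"A"} and \code{"B"}.
#' @param subpopFractionByCondition named numeric, e.g.
#'   \code{c(A = 0.3, B = 0.05)}: probability that a cell of a donor in that
#'   condition belongs to the planted subpopulation.
#' @param geno optional \linkS4class{GenotypeMatrix} over the same donors,
#'   required when \code{eqtlEffects} is given.
#' @param eqtlEffects optional data.frame \code{gene}, \code{variant},
#'   \code{beta} of planted cis effects.
#' @param qcViolationFraction fraction of cells planted as QC violations.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with sparse
#'   \code{counts}, \code{colData(donor, condition, subpop, qcViolation)}
#'   and \code{rowData(geneClass, baseMean)}.
#' @examples
#' sce <- simCells(simConfig(nDonors = 4, nGenes = 50,
#'                           nCellsPerDonor = c(20, 30), seed = 1),
#'                 subpopFractionByCondition = c(A = 0.2, B = 0))
#' table(SummarizedExperiment::colData(sce)$condition)
#' @export
simCells <- function(config, subpopFractionByCondition = c(A = 0, B = 0),
                     geno = NULL, eqtlEffects = NULL,
                     qcViolationFraction = 0) {
  stopifnot(inherits(config, "SimConfig"))
  fr <- subpopFractionByCondition
  if (any(fr < 0 | fr > 1)) stop("subpopulation fractions must be in [0,1]")
  if (length(fr) != 2 || is.null(names(fr)))
    stop("subpopFractionByCondition must be a named pair")
  if (!is.null(eqtlEffects) && is.null(geno))
    stop("eqtlEffects requires geno")
  withSeed(config$seed + 11L, {
    n <- config$nDonors
    donors <- sprintf("D%03d", seq_len(n))
    condition <- rep(names(fr), length.out = n)
    rng <- config$nCellsPerDonor[1]:config$nCellsPerDonor[2]
    nc <- if (length(rng) == 1) rep(rng, n) else
      sample(rng, n, replace = TRUE)
    if (sum(nc) == 0) stop("invalid config: zero cells requested")
    cellDonor <- rep(donors, nc)
    cellCond <- rep(condition, nc)
    total <- sum(nc)
    g <- config$nGenes
    # gene classes: a handful of mito/ribo/hemoglobin genes up front
    nMito <- max(2L, round(0.03 * g)); nRibo <- max(2L, round(0.03 * g))
    nHb <- 2L
    geneClass <- c(rep("mito", nMito), rep("ribo", nRibo),
                   rep("hemoglobin", nHb),
                   rep("other", g - nMito - nRibo - nHb))
    geneNames <- sprintf("gene%04d", seq_len(g))
    baseMean <- exp(stats::rnorm(g, mean = log(5), sd = 1))
    # keep the special classes modest so passing cells stay under thresholds
    baseMean[geneClass == "mito"] <- 0.3
    baseMean[geneClass == "ribo"] <- 0.3
    baseMean[geneClass == "hemoglobin"] <- 0.005
    disp <- exp(stats::rnorm(g, mean = log(0.3), sd = 0.5))  # NB dispersion
    markers <- which(geneClass == "other")[seq_len(max(3L, round(0.1 * g)))]
    subpop <- stats::runif(total) < fr[cellCond]
    sf <- exp(stats::rnorm(total, 0, 0.3))
    # per-donor eQTL multipliers on gene means
    mult <- matrix(1, nrow = g, ncol = n, dimnames = list(geneNames, donors))
    if (!is.null(eqtlEffects)) {
      dos <- dosages(geno)
      if (!all(donors %in% rownames(dos)))
        stop("geno must cover all simulated donors")
      for (i in seq_len(nrow(eqtlEffects))) {
        gi <- eqtlEffects$gene[i]; vi <- eqtlEffects$variant[i]
        d <- dos[donors, vi]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        mult[gi, ] <- mult[gi, ] * exp(eqtlEffects$beta[i] * d)
      }
    }
    mu <- mult[, cellDonor, drop = FALSE] * baseMean  # g x total
    mu[markers, subpop] <- mu[markers, subpop] * 4
    mu <- sweep(mu, 2, sf, `*`)
    counts <- matrix(stats::rnbinom(g * total, mu = as.vector(mu),
                                    size = rep(1 / disp, total)),
                     nrow = g, ncol = total)
    qcBad <- stats::runif(total) < qcViolationFraction
    if (any(qcBad)) {
      kind <- sample(c("lowgenes", "mito"), sum(qcBad), replace = TRUE)
      idx <- which(qcBad)
      for (ii in seq_along(idx)) {
        cc <- idx[ii]
        if (kind[ii] == "lowgenes") {
          keep <- sample(g, max(2L, round(0.02 * g)))
          drop <- setdiff(seq_len(g), keep)
          counts[drop, cc] <- 0L
          counts[keep, cc] <- pmax(counts[keep, cc], 1L)
        } else {
          tot <- max(sum(counts[, cc]), 50L)
          counts[geneClass == "mito", cc] <-
            counts[geneClass == "mito", cc] + ceiling(0.2 * tot / nMito)
        }
      }
    }
    dimnames(counts) <- list(geneNames, sprintf("cell%05d", seq_len(total)))
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts,
                                                        sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(donor = cellDonor,
                                     condition = cellCond, subpop = subpop,
                                     qcViolation = qcBad,
                                     row.names = colnames(counts)),
      rowData = S4Vectors::DataFrame(geneClass = geneClass,
                                     baseMean = baseMean,
                                     row.names = geneNames))
  })
}
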