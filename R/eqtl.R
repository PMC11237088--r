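#' cis-eQTL mapping configuration
#'
#' @param cisWindow cis window in bp around the transcribed span
#'   (default 250000; the boundary is inclusive).
#' @param nExpressionPcs number of expression PCs added as covariates
#'   (default 20; 0 disables, and must stay below the donor count).
#' @param covariateNames covariate columns expected in the donor table
#'   (default age, sex, race, diagnosis).
#' @param ldR2Threshold r-squared for LD pruning (default 0.8).
#' @param fdrThreshold significance threshold on the conditional FDR
#'   (default 0.05).
#' @return a list of class \code{EqtlConfig}.
#' @export
eqtlConfig <- function(cisWindow = 250000, nExpressionPcs = 20,
                       covariateNames = c("age", "sex", "race",
                                          "diagnosis"),
                       ldR2Threshold = 0.8, fdrThreshold = 0.05) {
  if (cisWindow <= 0) stop("cisWindow must be > 0")
  structure(list(cisWindow = cisWindow,
                 nExpressionPcs = nExpressionPcs,
                 covariateNames = covariateNames,
                 ldR2Threshold = ldR2Threshold,
                 fdrThreshold = fdrThreshold), class = "EqtlConfig")
}

# Build the covariate design (intercept + covariates + PCs) for a donor set.
.eqtlDesign <- function(donors, covars, pcs) {
  X <- matrix(1, nrow = length(donors), ncol = 1,
              dimnames = list(donors, "(Intercept)"))
  if (!is.null(covars)) {
    cv <- covars[donors, , drop = FALSE]
    mm <- stats::model.matrix(~ ., data = as.data.frame(cv))[, -1,
                                                             drop = FALSE]
    X <- cbind(X, mm)
  }
  if (!is.null(pcs)) X <- cbind(X, pcs[donors, , drop = FALSE])
  X
}

#' Map cis-eQTL by per-pair ordinary least squares
#'
#' For every gene and every variant whose position lies within
#' \code{cisWindow} bp of the gene's transcribed span (inclusive distance,
#' 1-based coordinates), fits
#' \code{expression ~ dosage + covariates + expression PCs} by OLS on the
#' per-pair complete cases and reports the dosage slope with its standard
#' error, t statistic and two-sided p-value.  Pairs with a singular design
#' (e.g. constant dosage among non-missing donors) are skipped with a
#' reason code.  Results are invariant to donor ordering.
#'
#' @param pb pseudobulk \code{SummarizedExperiment} (genes x donors) from
#'   \code{\link{aggregatePseudobulk}}.
#' @param geno \linkS4class{GenotypeMatrix}; donors are matched to the
#'   pseudobulk by id (intersection used).
#' @param genes data.frame with \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param covars optional data.frame of donor covariates (rownames =
#'   donor ids).
#' @param config an \code{\link{eqtlConfig}}.
#' @param pcs optional precomputed donor-by-PC matrix; by default
#'   expression PCs are computed from \code{pb} when
#'   \code{nExpressionPcs > 0}.
#' @return list with \code{results} (data.frame: gene, variant, beta, se,
#'   t, p, n) and \code{skipped} (gene, variant, reason).
#' @export
mapCisEqtl <- function(pb, geno, genes, covars = NULL,
                       config = eqtlConfig(), pcs = NULL) {
  donors <- intersect(colnames(pb), donorIds(geno))
  if (length(donors) < 3) stop("need at least 3 shared donors")
  expr <- SummarizedExperiment::assay(pb, "pseudobulk")[, donors,
                                                        drop = FALSE]
  dos <- dosages(geno)[donors, , drop = FALSE]
  vi <- variantInfo(geno)
  if (is.null(pcs) && config$nExpressionPcs > 0) {
    k <- min(config$nExpressionPcs, length(donors) - 2L,
             nrow(expr) - 1L)
    pcs <- expressionPcs(pb[, donors], k)
  }
  res <- list(); skip <- list()
  Xall <- .eqtlDesign(donors, covars, pcs)
  w <- config$cisWindow
  for (gi in seq_len(nrow(genes))) {
    gene <- genes$gene_id[gi]
    if (!gene %in% rownames(expr)) next
    hits <- which(vi$chrom == genes$chrom[gi] &
                    vi$pos >= genes$start[gi] - w &
                    vi$pos <= genes$end[gi] + w)
    if (!length(hits)) next
    y <- expr[gene, ]
    for (j in hits) {
      d <- dos[, j]
      ok <- !is.na(d) & !is.na(y)
      if (sum(ok) < ncol(Xall) + 2) {
        skip[[length(skip) + 1L]] <-
          data.frame(gene = gene, variant = colnames(dos)[j],
                     reason = "too_few_complete_cases")
        next
      }
      if (stats::var(d[ok]) == 0) {
        skip[[length(skip) + 1L]] <-
          data.frame(gene = gene, variant = colnames(dos)[j],
                     reason = "constant_dosage")
        next
      }
      pf <- partialF(y[ok], Xall[ok, , drop = FALSE], d[ok])
      if (is.null(pf)) {
        skip[[length(skip) + 1L]] <-
          data.frame(gene = gene, variant = colnames(dos)[j],
                     reason = "singular_design")
        next
      }
      tstat <- pf$beta / pf$se
      res[[length(res) + 1L]] <-
        data.frame(gene = gene, variant = colnames(dos)[j],
                   beta = pf$beta, se = pf$se, t = tstat,
                   p = pFromT(tstat, pf$df2), n = sum(ok),
                   stringsAsFactors = FALSE)
    }
  }
  list(results = if (length(res)) do.call(rbind, res) else
         data.frame(gene = character(), variant = character(),
                    beta = numeric(), se = numeric(), t = numeric(),
                    p = numeric(), n = integer()),
       skipped = if (length(skip)) do.call(rbind, skip) else
         data.frame(gene = character(), variant = character(),
                    reason = character()))
}

#' Diagnosis-by-dosage interaction test for one eQTL pair
#'
#' Fits \code{expression ~ dosage + diagnosis + dosage:diagnosis +
#' covariates} by OLS and tests the interaction coefficient, the
#' diagnosis-specific eQTL effect.
#'
#' @param expr numeric expression vector (one gene, donors aligned).
#' @param dosage numeric dosage vector.
#' @param diagnosis binary (0/1 or two-level factor) diagnosis label.
#' @param covars optional data.frame of covariates.
#' @return list with \code{betaInt}, \code{se}, \code{p} for the
#'   interaction plus \code{betaMain} (dosage effect in the reference
#'   group).
#' @export
testInteraction <- function(expr, dosage, diagnosis, covars = NULL) {
  dx <- if (is.factor(diagnosis)) as.integer(diagnosis) - 1L
        else as.numeric(diagnosis)
  if (length(unique(dx[!is.na(dx)])) < 2)
    stop("both diagnosis groups must be represented")
  for (lev in unique(dx)) {
    if (stats::var(dosage[dx == lev], na.rm = TRUE) == 0)
      stop("dosage is constant within a diagnosis stratum")
  }
  df <- data.frame(y = expr, dos = dosage, dx = dx)
  if (!is.null(covars)) df <- cbind(df, covars)
  fit <- stats::lm(y ~ . - dos - dx + dos * dx, data = df)
  cf <- summary(fit)$coefficients
  list(betaInt = cf["dos:dx", 1], se = cf["dos:dx", 2],
       p = cf["dos:dx", 4], betaMain = cf["dos", 1])
}
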