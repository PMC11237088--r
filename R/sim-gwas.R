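#' Simulate a pair of summary-statistic tracks over one region
#'
#' Builds a shared genotype panel, simulates one quantitative phenotype
#' (e.g. a cell-type eQTL trait) and one case-control phenotype (a
#' liability-threshold disease model analysed by per-variant logistic
#' regression), then computes marginal per-variant association statistics
#' for each.  With \code{shared = TRUE} both phenotypes are driven by the
#' same causal variant; otherwise trait 2 uses a distinct variant
#' (\code{causalIndex2}, by default the panel position farthest from
#' \code{causalIndex}).
#'
#' @param shared logical; do the two traits share their causal variant?
#' @param regionSize number of variants in the region (>= 2).
#' @param causalIndex index of the causal variant for trait 1.
#' @param config a \code{\link{simConfig}}; \code{nDonors} is the GWAS
#'   sample size, \code{effectSize} the standardized causal effect
#'   (0 gives a null region) and \code{noiseSd} the residual sd.
#' @param causalIndex2 causal index for trait 2 when \code{shared = FALSE}.
#' @param caseFraction case fraction of the binary trait (default 0.087).
#' @return list of two \linkS4class{SummaryTrack}s (\code{eqtl},
#'   \code{gwas}) plus \code{truth} (the causal indices).
#' @examples
#' pair <- simGwasPair(TRUE, regionSize = 20, causalIndex = 10,
#'                     simConfig(nDonors = 500, nVariants = 20, seed = 2))
#' pair$truth
#' @export
simGwasPair <- function(shared, regionSize, causalIndex, config,
                        causalIndex2 = NULL, caseFraction = 0.087) {
  if (regionSize < 2)
    stop("regionSize must be >= 2 (pairwise hypothesis H3 undefined)")
  if (causalIndex < 1 || causalIndex > regionSize)
    stop("causalIndex must lie within the region")
  cfg <- config
  cfg$nVariants <- as.integer(regionSize)
  geno <- simGenotypes(cfg)
  dos <- dosages(geno)
  n <- nrow(dos)
  if (is.null(causalIndex2)) {
    causalIndex2 <- if (shared) causalIndex else
      if (causalIndex <= regionSize / 2) regionSize else 1L
  }
  if (shared) causalIndex2 <- causalIndex
  withSeed(config$seed + 23L, {
    g1 <- scale(dos[, causalIndex])[, 1]
    g2 <- scale(dos[, causalIndex2])[, 1]
    b <- config$effectSize
    y <- b * g1 + stats::rnorm(n, 0, config$noiseSd)
    # moderate liability effect: very large logistic slopes degrade the
    # Wald z under quasi-separation (Hauck-Donner), inverting the LD peak
    liab <- b * g2 + stats::rnorm(n, 0, config$noiseSd)
    case <- as.integer(liab >= stats::quantile(liab, 1 - caseFraction))
    freq <- colMeans(dos) / 2
    maf <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
    maf <- pmin(maf, 1 - maf)
    # marginal OLS per variant for the quantitative trait
    bet <- se <- numeric(regionSize)
    for (j in seq_len(regionSize)) {
      f <- stats::lm.fit(cbind(1, dos[, j]), y)
      s2 <- sum(f$residuals^2) / (n - 2)
      vj <- s2 * chol2inv(chol(crossprod(cbind(1, dos[, j]))))[2, 2]
      bet[j] <- f$coefficients[2]; se[j] <- sqrt(vj)
    }
    t1 <- summaryTrack(variant = colnames(dos),
                       position = variantInfo(geno)$pos, beta = bet,
                       se = se, maf = maf, n = rep(n, regionSize),
                       traitType = "quantitative")
    # per-variant logistic regression for the case-control trait
    bet2 <- se2 <- numeric(regionSize)
    for (j in seq_len(regionSize)) {
      fit <- stats::glm(case ~ dos[, j], family = stats::binomial())
      cf <- summary(fit)$coefficients
      bet2[j] <- cf[2, 1]; se2[j] <- cf[2, 2]
    }
    t2 <- summaryTrack(variant = colnames(dos),
                       position = variantInfo(geno)$pos, beta = bet2,
                       se = se2, maf = maf, n = rep(n, regionSize),
                       caseFraction = caseFraction,
                       traitType = "case_control")
    list(eqtl = t1, gwas = t2,
         truth = c(trait1 = causalIndex, trait2 = causalIndex2))
  })
}
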