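#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of conditional probabilities of all heterozygote counts (of
#' matching parity) whose probability under Hardy-Weinberg equilibrium does
#' not exceed that of the observed count.  Probabilities are computed in
#' log space from the conditional distribution
#' \deqn{P(n_{het} | n, n_A) = \frac{n!\,2^{n_{het}}\,n_A!\,n_a!}
#'   {n_{AA}!\,n_{het}!\,n_{aa}!\,(2n)!} \binom{2n}{n_A}^{-1}}
#' (equivalently, the multinomial genotype probability conditioned on
#' allele counts).
#'
#' @param homRef,het,homAlt nonnegative genotype counts.
#' @return the exact p-value in (0, 1].
#' @examples
#' hweExactTest(2, 0, 2)   # 6/70
#' hweExactTest(50, 0, 0)  # monomorphic: 1
#' @export
hweExactTest <- function(homRef, het, homAlt) {
  if (any(c(homRef, het, homAlt) < 0)) stop("counts must be >= 0")
  n <- homRef + het + homAlt
  if (n < 1) stop("at least one genotype required")
  nAlt <- 2 * homAlt + het
  nMinor <- min(nAlt, 2 * n - nAlt)
  if (nMinor == 0) return(1)  # monomorphic: single attainable configuration
  hets <- seq(nMinor %% 2, nMinor, by = 2)
  logp <- vapply(hets, function(h) {
    homMinor <- (nMinor - h) / 2
    homMajor <- n - h - homMinor
    lgamma(n + 1) - lgamma(homMajor + 1) - lgamma(h + 1) -
      lgamma(homMinor + 1) + h * log(2) +
      lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - logSumExp(logp))  # renormalize against rounding
  obs <- p[match(het, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Per-variant QC on a dosage panel
#'
#' Computes minor allele frequency, missing call rate and the HWE exact
#' test p-value for each variant, and removes variants with
#' \code{maf < mafMin}, \code{missing_rate > missMax} or
#' \code{hwe_p < hweMin}.  All three statistics are recorded for retained
#' and removed variants; a variant with every genotype missing is removed
#' with \code{missing_rate = 1} and no numeric error.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param missMax maximum missing call rate (default 0.1).
#' @param hweMin minimum HWE exact p (default 1e-6).
#' @return list with \code{geno} (the filtered panel) and \code{records},
#'   a data.frame (variant, chrom, pos, maf, missing_rate, hwe_p,
#'   pass_qc).
#' @export
variantQC <- function(geno, mafMin = 0.05, missMax = 0.1, hweMin = 1e-6) {
  dos <- dosages(geno)
  m <- ncol(dos)
  n <- nrow(dos)
  maf <- missr <- hwe <- numeric(m)
  for (j in seq_len(m)) {
    d <- dos[, j]
    miss <- is.na(d)
    missr[j] <- mean(miss)
    d <- d[!miss]
    if (!length(d)) {
      maf[j] <- NA_real_; hwe[j] <- NA_real_
      next
    }
    f <- mean(d) / 2
    maf[j] <- min(f, 1 - f)
    hwe[j] <- hweExactTest(sum(d == 0), sum(d == 1), sum(d == 2))
  }
  pass <- !is.na(maf) & maf >= mafMin & missr <= missMax &
    !is.na(hwe) & hwe >= hweMin
  rec <- data.frame(variant = colnames(dos),
                    chrom = variantInfo(geno)$chrom,
                    pos = variantInfo(geno)$pos,
                    maf = maf, missing_rate = missr, hwe_p = hwe,
                    pass_qc = pass, stringsAsFactors = FALSE)
  list(geno = geno[, pass], records = rec)
}

#' Greedy LD pruning of a variant panel
#'
#' Position-ordered scan: a variant is dropped when its dosage r-squared
#' with any already-kept variant within \code{window} bp exceeds
#' \code{r2Threshold}; with perfectly correlated pairs the first by
#' position is kept.  The kept list is deterministic.
#'
#' @param geno a QC-passed \linkS4class{GenotypeMatrix}.
#' @param r2Threshold r-squared above which the later variant is dropped
#'   (default 0.8, surfaced in \code{\link{eqtlConfig}}).
#' @param window comparison window in bp (default 250000).
#' @return character vector of kept variant ids.
#' @export
ldPrune <- function(geno, r2Threshold = 0.8, window = 250000) {
  dos <- dosages(geno)
  vi <- variantInfo(geno)
  ord <- order(vi$chrom, vi$pos)
  kept <- integer(0)
  for (j in ord) {
    drop <- FALSE
    for (k in kept) {
      if (vi$chrom[k] == vi$chrom[j] &&
          abs(vi$pos[k] - vi$pos[j]) <= window) {
        r <- suppressWarnings(
          stats::cor(dos[, j], dos[, k], use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2Threshold) { drop <- TRUE; break }
      }
    }
    if (!drop) kept <- c(kept, j)
  }
  colnames(dos)[sort(kept)]
}
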