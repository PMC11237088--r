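# Independent oracles used across the suite.  Each one is written from
# the definition, with none of the package's numerical machinery (no log
# space, no closed forms shared with the implementation).

# HWE exact test by direct enumeration with exact choose() arithmetic.
hweOracle <- function(homRef, het, homAlt) {
  n <- homRef + het + homAlt
  nAlt <- 2 * homAlt + het
  nMinor <- min(nAlt, 2 * n - nAlt)
  if (nMinor == 0) return(1)
  hets <- seq(nMinor %% 2, nMinor, by = 2)
  probs <- sapply(hets, function(h) {
    homMinor <- (nMinor - h) / 2
    homMajor <- n - h - homMinor
    # multinomial count of genotype configurations x 2^het over the
    # number of ways to pick the minor alleles among 2n
    exp(lfactorial(n) - lfactorial(homMajor) - lfactorial(h) -
          lfactorial(homMinor) + h * log(2) -
          (lchoose(2 * n, nMinor)))
  })
  probs <- probs / sum(probs)
  obs <- probs[match(het, hets)]
  sum(probs[probs <= obs + 1e-12])
}

# Two-sided Fisher p by full enumeration over margin-fixed tables.
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  ks <- lo:hi
  probs <- dhyper(ks, m1, m2, n1)
  obs <- dhyper(a, m1, m2, n1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Coloc posteriors by naive direct summation (no log space).
colocOracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  S1 <- sum(exp(l1)); S2 <- sum(exp(l2)); S12 <- sum(exp(l1 + l2))
  h <- c(1, p1 * S1, p2 * S2, p1 * p2 * (S1 * S2 - S12), p12 * S12)
  setNames(h / sum(h), paste0("PP", 0:4))
}

# Partial F-test of one added column via lm() + anova().
partialFOracle <- function(y, covars, z) {
  d0 <- if (is.null(covars)) data.frame(y = y) else
    data.frame(y = y, covars)
  fit0 <- lm(y ~ ., data = d0)
  d1 <- cbind(d0, z = z)
  fit1 <- lm(y ~ ., data = d1)
  an <- anova(fit0, fit1)
  list(F = an$F[2], p = an$`Pr(>F)`[2])
}

# Tiny SingleCellExperiment with fully specified QC stats in colData.
makeQcCells <- function(nGenes, totalUmi, fracMito = 0, fracRibo = 0,
                        fracHb = 0) {
  n <- length(nGenes)
  cts <- Matrix::Matrix(matrix(1, nrow = 3, ncol = n), sparse = TRUE)
  rownames(cts) <- paste0("g", 1:3)
  colnames(cts) <- paste0("c", seq_len(n))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cts),
    colData = S4Vectors::DataFrame(
      donor = rep("D1", n),
      nGenesDetected = as.integer(nGenes),
      totalUmi = as.numeric(totalUmi),
      fracMito = rep(fracMito, length.out = n),
      fracRibo = rep(fracRibo, length.out = n),
      fracHemoglobin = rep(fracHb, length.out = n),
      log10GenesPerUmi = ifelse(totalUmi > 1 & nGenes > 0,
                                log10(pmax(nGenes, 1)) /
                                  log10(pmax(totalUmi, 2)), 0),
      row.names = colnames(cts)))
}

# GenotypeMatrix built directly from a dosage matrix.
makeGeno <- function(dos, pos = NULL, chrom = "chr1") {
  if (is.null(rownames(dos)))
    rownames(dos) <- sprintf("D%03d", seq_len(nrow(dos)))
  if (is.null(colnames(dos)))
    colnames(dos) <- sprintf("v%04d", seq_len(ncol(dos)))
  if (is.null(pos)) pos <- seq_len(ncol(dos)) * 1000L + 1000000L
  new("GenotypeMatrix", dosage = dos,
      variants = S4Vectors::DataFrame(
        chrom = rep(chrom, ncol(dos)), pos = as.integer(pos),
        ref = rep("A", ncol(dos)), alt = rep("G", ncol(dos)),
        row.names = colnames(dos)))
}
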