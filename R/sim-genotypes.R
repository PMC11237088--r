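#' Configuration for the synthetic-data generators
#'
#' Collects the knobs shared by the generators: cohort size, variant panel,
#' gene panel, allele-frequency spectrum, linkage disequilibrium, per-donor
#' cell counts, planted effect size and noise level.  The frequency range is
#' restricted to [0.05, 0.5], mirroring the common-variant spectrum retained
#' by variant QC downstream.
#'
#' @param nDonors number of donors (>= 2).
#' @param nVariants number of variants on one simulated chromosome.
#' @param nGenes number of genes.
#' @param mafRange length-2 numeric in [0.05, 0.5]; per-variant minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param ldDecay latent correlation between adjacent variants in [0, 1);
#'   correlation between variants i and j decays as \code{ldDecay^|i-j|}.
#' @param nCellsPerDonor length-2 integer range of nuclei per donor.
#' @param effectSize standardized slope used for planted effects.
#' @param noiseSd Gaussian noise standard deviation (> 0).
#' @param missingRate fraction of dosage entries set missing.
#' @param seed integer; fully determines all generator output.
#' @return a validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nDonors = 50, nVariants = 20, seed = 1)
#' @export
simConfig <- function(nDonors = 100, nVariants = 50, nGenes = 100,
                      mafRange = c(0.05, 0.5), ldDecay = 0.5,
                      nCellsPerDonor = c(50, 150), effectSize = 0.5,
                      noiseSd = 1, missingRate = 0, seed = 1) {
  if (nDonors < 2) stop("invalid config: nDonors must be >= 2")
  if (length(mafRange) != 2 || any(is.na(mafRange)) ||
      mafRange[1] > mafRange[2])
    stop("invalid config: mafRange must be a nondecreasing pair")
  if (mafRange[1] < 0.05 - 1e-12 || mafRange[2] > 0.5 + 1e-12)
    stop("invalid config: mafRange must lie within [0.05, 0.5]")
  if (ldDecay < 0 || ldDecay >= 1)
    stop("invalid config: ldDecay must be in [0, 1)")
  if (noiseSd < 0) stop("invalid config: noiseSd must be >= 0")
  if (missingRate < 0 || missingRate >= 1)
    stop("invalid config: missingRate must be in [0, 1)")
  if (nCellsPerDonor[1] < 1 || nCellsPerDonor[2] < nCellsPerDonor[1])
    stop("invalid config: nCellsPerDonor must be an increasing range >= 1")
  structure(list(nDonors = as.integer(nDonors),
                 nVariants = as.integer(nVariants),
                 nGenes = as.integer(nGenes), mafRange = mafRange,
                 ldDecay = ldDecay,
                 nCellsPerDonor = as.integer(nCellsPerDonor),
                 effectSize = effectSize, noiseSd = noiseSd,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a donor-by-variant dosage panel with local LD
#'
#' Haplotypes are generated as a first-order Markov chain: a latent Gaussian
#' AR(1) process with per-step correlation \code{ldDecay} is thresholded at
#' each variant's allele-frequency quantile, so marginal allele frequencies
#' match the drawn MAFs exactly while correlation between variants decays
#' geometrically with distance in the panel.  Dosage is the sum of two
#' independent haplotypes per donor; positions increase monotonically along
#' one chromosome.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return a \linkS4class{GenotypeMatrix}; variant metadata carries
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt} and the generating
#'   \code{trueMaf}.
#' @examples
#' g <- simGenotypes(simConfig(nDonors = 20, nVariants = 10, seed = 7))
#' table(dosages(g)[, 1])
#' @export
simGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed, {
    n <- config$nDonors
    m <- config$nVariants
    maf <- stats::runif(m, config$mafRange[1], config$mafRange[2])
    rho <- config$ldDecay
    # 2n haplotypes x m variants of latent AR(1) Gaussians
    z <- matrix(0, nrow = 2L * n, ncol = m)
    z[, 1] <- stats::rnorm(2L * n)
    if (m > 1) {
      for (j in 2:m) {
        z[, j] <- rho * z[, j - 1] +
          sqrt(1 - rho^2) * stats::rnorm(2L * n)
      }
    }
    thr <- stats::qnorm(1 - maf)
    alle <- sweep(z, 2, thr, ">") * 1L
    dos <- alle[seq_len(n), , drop = FALSE] +
      alle[n + seq_len(n), , drop = FALSE]
    storage.mode(dos) <- "double"
    if (config$missingRate > 0) {
      mis <- matrix(stats::runif(n * m) < config$missingRate, n, m)
      dos[mis] <- NA_real_
    }
    pos <- cumsum(sample(1000:5000, m, replace = TRUE)) + 1000000L
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
    rownames(dos) <- sprintf("D%03d", seq_len(n))
    colnames(dos) <- sprintf("v%04d", seq_len(m))
    vars <- S4Vectors::DataFrame(chrom = rep("chr1", m),
                                 pos = as.integer(pos), ref = ref,
                                 alt = unname(alt), trueMaf = maf,
                                 row.names = colnames(dos))
    new("GenotypeMatrix", dosage = dos, variants = vars)
  })
}

#' Simulate gene coordinates interleaved with the variant panel
#'
#' Places \code{nGenes} transcribed spans along the simulated chromosome so
#' that every gene has variants within the default 250 kb cis window.
#' Coordinates are 1-based inclusive (BED-like TSV with 1-based starts on
#' disk).
#'
#' @param config a \code{\link{simConfig}}.
#' @param geno the \linkS4class{GenotypeMatrix} the genes should bracket.
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}.
#' @export
simGeneCoordinates <- function(config, geno) {
  stopifnot(inherits(config, "SimConfig"), is(geno, "GenotypeMatrix"))
  withSeed(config$seed + 101L, {
    pos <- variantInfo(geno)$pos
    k <- config$nGenes
    starts <- as.integer(round(seq(min(pos), max(pos), length.out = k)))
    len <- sample(2000:8000, k, replace = TRUE)
    data.frame(gene_id = sprintf("gene%04d", seq_len(k)),
               chrom = rep(variantInfo(geno)$chrom[1], k),
               start = starts, end = starts + len,
               stringsAsFactors = FALSE)
  })
}
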