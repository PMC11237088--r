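#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Donor-by-variant dosage matrix with variant metadata
#'
#' Holds alt-allele dosages (0/1/2, \code{NA} for missing calls) for a set of
#' donors over biallelic variants on one or more chromosomes, together with
#' per-variant metadata (chromosome, 1-based position, ref/alt alleles and,
#' once \code{\link{variantQC}} has run, per-variant QC statistics).
#'
#' @slot dosage numeric matrix, donors in rows, variants in columns; entries
#'   in \{0, 1, 2, NA\}.
#' @slot variants \code{DataFrame} with one row per variant; required columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", variants = "DataFrame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosage
  if (ncol(d) != nrow(object@variants))
    msg <- c(msg, "ncol(dosage) must equal nrow(variants)")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(object@variants)))
    msg <- c(msg, paste("variants must have columns:",
                        paste(need, collapse = ", ")))
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(d))) msg <- c(msg, "dosage must carry donor rownames")
  if (length(msg)) msg else TRUE
})

#' Aligned (L, G, T) vectors for one causal-inference trio
#'
#' Per-donor dosage at a locus (L), candidate mediator expression (G) and a
#' downstream quantitative trait (T), optionally with fixed covariates.  The
#' generating scenario, when known (synthetic data), is kept for scoring.
#'
#' @slot L numeric dosage vector (values in 0..2).
#' @slot G,T numeric vectors aligned with \code{L}.
#' @slot covariates \code{DataFrame} with one row per donor (possibly with
#'   zero columns).
#' @slot donors character donor identifiers.
#' @slot scenario character; one of \code{"causal"}, \code{"reactive"},
#'   \code{"independent"}, \code{"confounded"} or \code{NA} when unknown.
#'
#' @aliases TrioData-class
#' @exportClass TrioData
setClass("TrioData",
  representation(L = "numeric", G = "numeric", T = "numeric",
                 covariates = "DataFrame", donors = "character",
                 scenario = "character"))

setValidity("TrioData", function(object) {
  n <- length(object@L)
  msg <- character()
  if (length(object@G) != n || length(object@T) != n ||
      length(object@donors) != n)
    msg <- c(msg, "L, G, T and donors must have equal length")
  if (nrow(object@covariates) != 0L && nrow(object@covariates) != n)
    msg <- c(msg, "covariates must have one row per donor (or none)")
  if (any(!is.na(object@L) & (object@L < 0 | object@L > 2)))
    msg <- c(msg, "L must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Per-variant association statistics for one trait over one region
#'
#' A summary-statistic track as used for colocalization: per variant either
#' (beta, se) or (p, maf, n) must be available.  Case-control tracks carry
#' the case fraction \code{s}.
#'
#' @slot variant character variant identifiers.
#' @slot position integer positions (bp).
#' @slot beta,se,p,maf numeric per-variant statistics (\code{NA} allowed for
#'   the optional members, subject to the either/or rule).
#' @slot n numeric per-variant sample size.
#' @slot caseFraction numeric scalar in (0,1) for case-control tracks,
#'   \code{NA} otherwise.
#' @slot traitType \code{"quantitative"} or \code{"case_control"}.
#'
#' @aliases SummaryTrack-class
#' @exportClass SummaryTrack
setClass("SummaryTrack",
  representation(variant = "character", position = "integer",
                 beta = "numeric", se = "numeric", p = "numeric",
                 maf = "numeric", n = "numeric", caseFraction = "numeric",
                 traitType = "character"))

setValidity("SummaryTrack", function(object) {
  m <- length(object@variant)
  msg <- character()
  if (any(vapply(list(object@position, object@beta, object@se, object@p,
                      object@maf, object@n), length, 1L) != m))
    msg <- c(msg, "all per-variant slots must share the variant length")
  if (!object@traitType %in% c("quantitative", "case_control"))
    msg <- c(msg, "traitType must be 'quantitative' or 'case_control'")
  if (object@traitType == "case_control" &&
      (is.na(object@caseFraction) || object@caseFraction <= 0 ||
       object@caseFraction >= 1))
    msg <- c(msg, "case-control tracks need caseFraction in (0,1)")
  okA <- !is.na(object@beta) & !is.na(object@se)
  okB <- !is.na(object@p) & !is.na(object@maf) & !is.na(object@n)
  if (m && !all(okA | okB))
    msg <- c(msg, "each variant needs (beta, se) or (p, maf, n)")
  if (any(!is.na(object@maf) & (object@maf <= 0 | object@maf > 0.5)))
    msg <- c(msg, "maf must lie in (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Logistic-CDF fit to the log10-UMI distribution
#'
#' Result of \code{\link{fitSigmoidCutoffs}}: the inflection location
#' \code{mu} (the fitted median of log10 UMI), the scale \code{s}, and the
#' two retained-cell cutoffs \code{mu +/- multiplier * s}.
#'
#' @slot mu,s numeric logistic location and scale on the log10-UMI axis.
#' @slot lower,upper numeric cutoffs.
#' @slot multiplier numeric; the cutoff half-width in units of \code{s}
#'   (default \code{log(4)}).
#' @slot converged logical; \code{FALSE} means the percentile fallback was
#'   used and \code{mu}, \code{s} are \code{NA}.
#'
#' @aliases SigmoidFit-class
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  representation(mu = "numeric", s = "numeric", lower = "numeric",
                 upper = "numeric", multiplier = "numeric",
                 converged = "logical"))

setValidity("SigmoidFit", function(object) {
  if (object@lower >= object@upper) "lower cutoff must be < upper" else TRUE
})

#' Five-hypothesis colocalization posterior
#'
#' @slot pp named numeric of length 5 (\code{PP0}..\code{PP4}) summing to 1.
#' @slot perVariantPP4 named numeric; posterior that each variant is the
#'   shared causal variant, conditional on H4; sums to 1.
#' @slot nVariants integer number of shared variants used.
#' @slot priors named numeric \code{p1}, \code{p2}, \code{p12}.
#'
#' @aliases ColocResult-class
#' @exportClass ColocResult
setClass("ColocResult",
  representation(pp = "numeric", perVariantPP4 = "numeric",
                 nVariants = "integer", priors = "numeric"))

setValidity("ColocResult", function(object) {
  msg <- character()
  if (length(object@pp) != 5L) msg <- c(msg, "pp must have 5 entries")
  if (abs(sum(object@pp) - 1) > 1e-9) msg <- c(msg, "pp must sum to 1")
  if (length(object@perVariantPP4) &&
      abs(sum(object@perVariantPP4) - 1) > 1e-9)
    msg <- c(msg, "per-variant H4 posteriors must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Four-condition causal inference test result
#'
#' Component p-values for the four conditions (L-G association, L-T
#' association, L-G given T, and the L-independent-of-T-given-G equivalence
#' test), the intersection-union omnibus p, and after
#' \code{\link{citFdr}} a permutation FDR value \code{q} and call.
#'
#' @slot p1,p2,p3,p4,pCit numeric p-values; \code{pCit = max(p1..p4)}.
#' @slot q numeric permutation FDR value (\code{NA} before \code{citFdr}).
#' @slot call character \code{"causal"} or \code{"not-called"}.
#' @slot n integer number of complete cases used.
#'
#' @aliases CitResult-class
#' @exportClass CitResult
setClass("CitResult",
  representation(p1 = "numeric", p2 = "numeric", p3 = "numeric",
                 p4 = "numeric", pCit = "numeric", q = "numeric",
                 call = "character", n = "integer"))

setValidity("CitResult", function(object) {
  pc <- max(object@p1, object@p2, object@p3, object@p4)
  if (abs(object@pCit - pc) > 1e-12)
    "pCit must equal max(p1, p2, p3, p4)" else TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "donors x",
      ncol(object@dosage), "variants\n")
  cat("  chrom:", paste(unique(object@variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missing rate: %.4f\n", miss))
})

setMethod("show", "TrioData", function(object) {
  cat("TrioData:", length(object@L), "donors; scenario:",
      ifelse(is.na(object@scenario), "unknown", object@scenario), "\n")
})

setMethod("show", "SummaryTrack", function(object) {
  cat("SummaryTrack (", object@traitType, "): ", length(object@variant),
      " variants\n", sep = "")
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf(
    "SigmoidFit: mu=%.4f s=%.4f cutoffs=[%.4f, %.4f] converged=%s\n",
    object@mu, object@s, object@lower, object@upper, object@converged))
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult over", object@nVariants, "variants\n")
  print(round(object@pp, 4))
})

setMethod("show", "CitResult", function(object) {
  cat(sprintf(
    "CitResult: p1=%.3g p2=%.3g p3=%.3g p4=%.3g pCit=%.3g q=%.3g call=%s\n",
    object@p1, object@p2, object@p3, object@p4, object@pCit, object@q,
    object@call))
})
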