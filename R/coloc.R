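#' Construct a SummaryTrack
#'
#' @param variant character variant ids.
#' @param position integer positions (bp).
#' @param beta,se per-variant effect and standard error (optional if
#'   \code{p} is given with \code{maf} and \code{n}).
#' @param p per-variant p-values (optional if \code{beta}, \code{se}
#'   given).
#' @param maf minor allele frequencies in (0, 0.5].
#' @param n per-variant sample size (scalar recycled).
#' @param caseFraction case fraction for case-control tracks.
#' @param traitType \code{"quantitative"} or \code{"case_control"}.
#' @return a \linkS4class{SummaryTrack}.
#' @export
summaryTrack <- function(variant, position = seq_along(variant),
                         beta = NULL, se = NULL, p = NULL, maf = NULL,
                         n = NULL, caseFraction = NA_real_,
                         traitType = c("quantitative", "case_control")) {
  traitType <- match.arg(traitType)
  m <- length(variant)
  fill <- function(x) if (is.null(x)) rep(NA_real_, m) else
    rep(as.numeric(x), length.out = m)
  new("SummaryTrack", variant = as.character(variant),
      position = as.integer(rep(position, length.out = m)),
      beta = fill(beta), se = fill(se), p = fill(p), maf = fill(maf),
      n = fill(n), caseFraction = as.numeric(caseFraction),
      traitType = traitType)
}

#' Per-variant approximate Bayes factors (log scale)
#'
#' Wakefield-style lABF for each variant:
#' \code{z = beta/se} (or |z| back-computed from the two-sided p when
#' beta/se are unavailable), \code{V = se^2} or approximated as
#' \code{1/(2 n maf (1-maf))} for quantitative traits, additionally
#' divided by \code{s(1-s)} for case-control, and
#' \deqn{lABF = \tfrac12\left[\log\frac{V}{V+W} +
#'   z^2\,\frac{W}{V+W}\right].}
#' When both (beta, se) and (p, maf, n) are present, se is preferred.
#'
#' @param track a \linkS4class{SummaryTrack}.
#' @param W prior effect variance; defaults to \code{0.15^2} for
#'   quantitative and \code{0.2^2} for case-control tracks.
#' @param mafOverride optional replacement MAF vector (e.g. cohort
#'   estimates) used for the variance approximation.
#' @return numeric lABF vector named by variant.
#' @examples
#' tr <- summaryTrack("v1", beta = 0.75, se = 0.1, maf = 0.3, n = 500)
#' computeLabf(tr)
#' @export
computeLabf <- function(track, W = NULL, mafOverride = NULL) {
  stopifnot(is(track, "SummaryTrack"))
  cc <- track@traitType == "case_control"
  if (is.null(W)) W <- if (cc) 0.2^2 else 0.15^2
  if (W <= 0) stop("prior variance W must be > 0")
  maf <- if (is.null(mafOverride)) track@maf else
    rep(mafOverride, length.out = length(track@variant))
  haveSe <- !is.na(track@beta) & !is.na(track@se)
  z <- V <- numeric(length(track@variant))
  for (i in seq_along(z)) {
    if (haveSe[i]) {
      if (track@se[i] == 0)
        stop("se = 0 for variant ", track@variant[i])
      z[i] <- track@beta[i] / track@se[i]
      V[i] <- track@se[i]^2
    } else {
      if (is.na(maf[i]) || maf[i] <= 0 || maf[i] > 0.5)
        stop("maf outside (0, 0.5] for variant ", track@variant[i])
      z[i] <- stats::qnorm(track@p[i] / 2, lower.tail = FALSE)
      V[i] <- 1 / (2 * track@n[i] * maf[i] * (1 - maf[i]))
      if (cc) V[i] <- V[i] / (track@caseFraction *
                                (1 - track@caseFraction))
    }
  }
  labf <- 0.5 * (log(V / (V + W)) + z^2 * W / (V + W))
  names(labf) <- track@variant
  labf
}

#' Five-hypothesis colocalization from two summary tracks
#'
#' Enumerates the standard hypotheses -- H0 no association, H1/H2
#' association with one trait only, H3 both traits via distinct variants,
#' H4 a shared causal variant -- from per-variant log approximate Bayes
#' factors accumulated in log space with log-sum-exp.  With
#' \code{S1 = sum(exp(lABF1))}, \code{S2} likewise and
#' \code{S12 = sum(exp(lABF1 + lABF2))}, the unnormalized weights are
#' \code{1, p1 S1, p2 S2, p1 p2 (S1 S2 - S12), p12 S12}.  The per-variant
#' posterior under H4 is the softmax of \code{lABF1 + lABF2}.
#'
#' The two tracks must share an identical ordered variant set; the
#' intersection is taken (and reported) when they differ.
#'
#' @param track1,track2 \linkS4class{SummaryTrack}s over one region.
#' @param p1,p2 prior probability a variant is causal for trait 1/2 only
#'   (defaults 1e-4).
#' @param p12 prior probability a variant is causal for both
#'   (default 1e-5).
#' @param W1,W2 prior effect variances per track (see
#'   \code{\link{computeLabf}}).
#' @param mafOverride optional cohort MAF estimates applied to both
#'   tracks.
#' @return a \linkS4class{ColocResult}.
#' @examples
#' pair <- simGwasPair(TRUE, 20, 10,
#'                     simConfig(nDonors = 1000, nVariants = 20,
#'                               effectSize = 1, seed = 5))
#' posteriors(colocalize(pair$eqtl, pair$gwas))
#' @export
colocalize <- function(track1, track2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       W1 = NULL, W2 = NULL, mafOverride = NULL) {
  shared <- intersect(track1@variant, track2@variant)
  if (length(shared) < 2)
    stop("need >= 2 shared variants (H3 undefined otherwise)")
  i1 <- match(shared, track1@variant)
  i2 <- match(shared, track2@variant)
  sub <- function(tr, i) summaryTrack(
    tr@variant[i], tr@position[i], beta = tr@beta[i], se = tr@se[i],
    p = tr@p[i], maf = tr@maf[i], n = tr@n[i],
    caseFraction = tr@caseFraction, traitType = tr@traitType)
  l1 <- computeLabf(sub(track1, i1), W = W1, mafOverride = mafOverride)
  l2 <- computeLabf(sub(track2, i2), W = W2, mafOverride = mafOverride)
  .colocFromLabf(l1, l2, p1, p2, p12, variants = shared,
                 priors = c(p1 = p1, p2 = p2, p12 = p12))
}

# Posteriors from two aligned lABF vectors; log-space accumulation.
.colocFromLabf <- function(l1, l2, p1, p2, p12, variants = NULL,
                           priors = c(p1 = p1, p2 = p2, p12 = p12)) {
  if (is.null(variants)) variants <- names(l1)
  lS1 <- logSumExp(l1)
  lS2 <- logSumExp(l2)
  lS12 <- logSumExp(l1 + l2)
  # log(S1*S2 - S12), guarded against negative rounding residue
  diffArg <- 1 - exp(lS12 - lS1 - lS2)
  if (diffArg <= 0) {
    if (diffArg < -1e-8)
      warning("negative H3 weight clipped to 0")
    lH3 <- -Inf
  } else {
    lH3 <- lS1 + lS2 + log(diffArg)
  }
  lh <- c(h0 = 0,
          h1 = log(p1) + lS1,
          h2 = log(p2) + lS2,
          h3 = log(p1) + log(p2) + lH3,
          h4 = log(p12) + lS12)
  lz <- logSumExp(lh)
  pp <- exp(lh - lz)
  names(pp) <- paste0("PP", 0:4)
  s <- l1 + l2
  pv <- exp(s - logSumExp(s))
  names(pv) <- variants
  new("ColocResult", pp = pp, perVariantPP4 = pv,
      nVariants = length(variants), priors = priors)
}
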