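#' Conditional false discovery rate with an auxiliary p-value track
#'
#' Empirical conditional-CDF estimator with the null proportion
#' conservatively set to 1: for each aligned (gene, variant) pair i,
#' \deqn{cFDR_i = p_i \cdot \frac{\#\{j : p^{aux}_j \le p^{aux}_i\}}
#'   {\#\{j : p_j \le p_i \wedge p^{aux}_j \le p^{aux}_i\}}}
#' clipped to at most 1 and then monotonized (non-decreasing in the
#' primary p, ties sharing their group maximum) so thresholding at any
#' level yields a p-threshold rule.  With an uninformative auxiliary track
#' (all values equal) this reduces to \code{p / ecdf(p)}, the
#' unconditional analog.
#'
#' Pairs with a missing auxiliary value get \code{cfdr = 1} and are
#' flagged in the \code{"empty_conditioning"} attribute.
#'
#' @param primaryP numeric vector of primary p-values in (0, 1].
#' @param auxP auxiliary p-values for the same hypotheses, aligned by
#'   (gene, variant) pair.
#' @return numeric cfdr vector aligned with the input; attribute
#'   \code{empty_conditioning} marks flagged pairs.
#' @examples
#' p <- c(0.001, 0.01, 0.5)
#' conditionalFdr(p, p)  # shared signal ordering
#' @export
conditionalFdr <- function(primaryP, auxP) {
  if (length(primaryP) != length(auxP))
    stop("primaryP and auxP must have equal length")
  bad <- is.na(primaryP) | is.na(auxP)
  n <- length(primaryP)
  raw <- rep(1, n)
  idx <- which(!bad)
  p <- primaryP[idx]; a <- auxP[idx]
  if (any(p <= 0 | p > 1) || any(a <= 0 | a > 1))
    stop("p-values must lie in (0, 1]")
  for (k in seq_along(idx)) {
    A <- sum(a <= a[k])
    J <- sum(p <= p[k] & a <= a[k])
    raw[idx[k]] <- min(1, p[k] * A / J)
  }
  # monotonize in the primary p; tied p share their group maximum
  o <- order(primaryP[idx])
  v <- cummax(raw[idx][o])
  ps <- p[o]
  v <- stats::ave(v, match(ps, unique(ps)), FUN = max)
  out <- raw
  out[idx[o]] <- pmin(v, 1)
  attr(out, "empty_conditioning") <- bad
  out
}

#' Attach conditional-FDR significance calls to eQTL results
#'
#' Joins an auxiliary p-value table to the mapped pairs by (gene,
#' variant), computes \code{\link{conditionalFdr}} and flags pairs with
#' \code{cfdr <= fdrThreshold}.  Pairs absent from the auxiliary table are
#' treated as missing (cfdr 1, flagged).
#'
#' @param results eQTL results data.frame from \code{\link{mapCisEqtl}}.
#' @param aux data.frame with columns \code{gene}, \code{variant},
#'   \code{p} from the external reference study.
#' @param fdrThreshold call threshold (default 0.05).
#' @return \code{results} with \code{cfdr} and \code{significant} added.
#' @export
eqtlCallSignificance <- function(results, aux, fdrThreshold = 0.05) {
  key <- paste(results$gene, results$variant, sep = "\r")
  akey <- paste(aux$gene, aux$variant, sep = "\r")
  auxP <- aux$p[match(key, akey)]
  cf <- conditionalFdr(results$p, auxP)
  results$cfdr <- as.numeric(cf)
  results$significant <- results$cfdr <= fdrThreshold
  results
}
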