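#' Construct a TrioData object
#'
#' @param L numeric dosage vector (0/1/2).
#' @param G mediator expression vector.
#' @param T downstream trait vector.
#' @param covariates optional data.frame/DataFrame of per-donor
#'   covariates.
#' @param donors donor identifiers (defaults to an index sequence).
#' @return a \linkS4class{TrioData}.
#' @export
trioData <- function(L, G, T, covariates = NULL, donors = NULL) {
  n <- length(L)
  if (is.null(donors)) donors <- sprintf("D%03d", seq_len(n))
  cv <- if (is.null(covariates))
    S4Vectors::DataFrame(matrix(nrow = n, ncol = 0)) else
      methods::as(as.data.frame(covariates), "DataFrame")
  new("TrioData", L = as.numeric(L), G = as.numeric(G),
      T = as.numeric(T), covariates = cv,
      donors = as.character(donors), scenario = NA_character_)
}

# Complete-case extraction with the degeneracy guards shared by citTest
# and the permutation machinery.
.citPrepare <- function(trio) {
  L <- trio@L; G <- trio@G; T_ <- trio@T
  cv <- as.data.frame(trio@covariates)
  ok <- !is.na(L) & !is.na(G) & !is.na(T_)
  if (ncol(cv)) ok <- ok & stats::complete.cases(cv)
  L <- L[ok]; G <- G[ok]; T_ <- T_[ok]
  cv <- cv[ok, , drop = FALSE]
  if (length(L) < 10) stop("need >= 10 complete cases")
  if (length(unique(L)) < 2) stop("constant L")
  if (stats::sd(G) == 0 || stats::sd(T_) == 0)
    stop("G and T must be nonconstant")
  if (abs(stats::cor(G, T_)) >= 1 - 1e-12)
    stop("degenerate trio: G and T are collinear")
  C <- if (ncol(cv))
    stats::model.matrix(~ ., data = cv) else
      matrix(1, nrow = length(L), ncol = 1)
  list(L = L, G = G, T = T_, C = C, n = length(L))
}

# The four component p-values for prepared data; returns c(p1..p4).
# ncp4Override fixes the condition-4 noncentrality (permutation use).
.citP <- function(L, G, T_, C, ncp4Override = NULL) {
  f1 <- partialF(G, C, L)                 # L-G association
  f2 <- partialF(T_, C, L)                # L-T association
  f3 <- partialF(G, cbind(C, T_), L)      # L-G given T
  f4 <- partialF(T_, cbind(C, G), L)      # conditional L-T given G
  if (is.null(f1) || is.null(f2) || is.null(f3) || is.null(f4))
    stop("singular design in a component regression")
  # equivalence-type condition 4: compare the conditional F against a
  # noncentral F whose noncentrality reflects the marginal L-T effect;
  # small p4 = the conditional association is significantly smaller than
  # expected were the L-T effect direct.  Under a direct effect the
  # conditional design inflates Var(beta_L) by 1/(1 - r^2(L,G)), so the
  # marginal F is deflated by (1 - r^2) before use as the noncentrality.
  ncp <- if (is.null(ncp4Override)) {
    rL <- stats::lm.fit(C, L)$residuals
    rG <- stats::lm.fit(C, G)$residuals
    1 * f2$F * (1 - stats::cor(rL, rG)^2)
  } else ncp4Override
  p4 <- stats::pf(f4$F, 1, f4$df2, ncp = ncp)
  c(p1 = f1$p, p2 = f2$p, p3 = f3$p, p4 = p4)
}

#' Four-condition causal inference test for one trio
#'
#' Tests whether mediator G transmits the effect of locus L onto trait T
#' via the intersection-union of four conditions: (1) L and G are
#' associated; (2) L and T are associated; (3) L is associated with G
#' given T; (4) L is independent of T given G.  Conditions 1-3 are
#' partial F-tests of L in the obvious OLS models (covariates included
#' when present).  Condition 4 is an equivalence-type test: the observed
#' F for L in \code{T ~ covariates + G + L} is referred to a noncentral F
#' whose noncentrality represents the direct-effect hypothesis, estimated
#' from condition 2's marginal F deflated for the L-G collinearity of the
#' conditional design (\code{ncp = df1 * F_marginal * (1 - r^2(L, G))},
#' since a direct effect's conditional F is attenuated by exactly that
#' factor), and \code{p4 = Pr(F_ncp <= F_obs)}.  The omnibus p is the
#' maximum of the four, so every condition must hold simultaneously.
#'
#' L is treated as a numeric dosage (1 df) by default;
#' \code{genotypeFactor = TRUE} switches to a genotype factor (2 df).
#'
#' @param trio a \linkS4class{TrioData}.
#' @param genotypeFactor treat L as a factor instead of a numeric dosage.
#' @return a \linkS4class{CitResult} with \code{q = NA} (see
#'   \code{\link{citFdr}}).
#' @examples
#' td <- simTrio(trioScenario("causal", n = 300, seed = 1))
#' citTest(td)
#' @export
citTest <- function(trio, genotypeFactor = FALSE) {
  pr <- .citPrepare(trio)
  L <- pr$L
  if (genotypeFactor && length(unique(L)) > 2) {
    # 2-df genotype coding: test both columns jointly via model
    # comparison F-tests
    Lm <- stats::model.matrix(~ factor(L))[, -1, drop = FALSE]
    p <- .citPmulti(Lm, pr$G, pr$T, pr$C)
  } else {
    p <- .citP(L, pr$G, pr$T, pr$C)
  }
  new("CitResult", p1 = unname(p[1]), p2 = unname(p[2]),
      p3 = unname(p[3]), p4 = unname(p[4]), pCit = max(p),
      q = NA_real_, call = "not-called", n = as.integer(pr$n))
}

# multi-column L (genotype-factor coding): joint F for the L block
.citPmulti <- function(Lm, G, T_, C) {
  blockF <- function(y, X0) {
    fit0 <- stats::lm.fit(X0, y)
    fit1 <- stats::lm.fit(cbind(X0, Lm), y)
    df1 <- fit1$rank - fit0$rank
    df2 <- length(y) - fit1$rank
    rss0 <- sum(fit0$residuals^2); rss1 <- sum(fit1$residuals^2)
    Fs <- max(0, rss0 - rss1) / df1 / (rss1 / df2)
    list(F = Fs, df1 = df1, df2 = df2,
         p = stats::pf(Fs, df1, df2, lower.tail = FALSE))
  }
  f1 <- blockF(G, C); f2 <- blockF(T_, C)
  f3 <- blockF(G, cbind(C, T_)); f4 <- blockF(T_, cbind(C, G))
  rG <- stats::lm.fit(C, G)$residuals
  rL <- stats::lm.fit(C, Lm)$residuals
  R2 <- summary(stats::lm(rG ~ rL))$r.squared
  p4 <- stats::pf(f4$F, f4$df1, f4$df2,
                  ncp = f2$df1 * f2$F * (1 - R2))
  c(p1 = f1$p, p2 = f2$p, p3 = f3$p, p4 = p4)
}

# Observed noncentrality of the condition-4 reference: the equivalence
# bound is part of the test's definition, so permutation replicates reuse
# the observed value rather than re-estimating it from permuted data
# (where it would collapse together with the conditional F and leave the
# permuted omnibus with no left tail).
.citNcp4 <- function(pr) {
  f2 <- partialF(pr$T, pr$C, pr$L)
  rL <- stats::lm.fit(pr$C, pr$L)$residuals
  rG <- stats::lm.fit(pr$C, pr$G)$residuals
  f2$F * (1 - stats::cor(rL, rG)^2)
}

# Vectorized permutation p_cit stream for a no-covariate, numeric-L trio:
# all component tests reduce to (partial) correlation F statistics, so a
# B-column crossprod gives every permuted replicate at once.  ncp4 is the
# fixed observed condition-4 noncentrality.
.citPermFast <- function(pr, permIdx, ncp4) {
  n <- pr$n
  Lz <- as.vector(scale(pr$L)); Gz <- as.vector(scale(pr$G))
  Tz <- as.vector(scale(pr$T))
  rLG <- sum(Lz * Gz) / (n - 1)
  B <- ncol(permIdx)
  TzP <- matrix(Tz[permIdx], nrow = n, ncol = B)
  rLT <- as.vector(crossprod(Lz, TzP)) / (n - 1)
  rGT <- as.vector(crossprod(Gz, TzP)) / (n - 1)
  clip <- function(r) pmax(pmin(r, 1 - 1e-12), -(1 - 1e-12))
  rLT <- clip(rLT); rGT <- clip(rGT); rLGc <- clip(rLG)
  p1 <- {  # unchanged by T permutation
    F1 <- (n - 2) * rLGc^2 / (1 - rLGc^2)
    stats::pf(F1, 1, n - 2, lower.tail = FALSE)
  }
  F2 <- (n - 2) * rLT^2 / (1 - rLT^2)
  p2 <- stats::pf(F2, 1, n - 2, lower.tail = FALSE)
  prLG_T <- clip((rLGc - rLT * rGT) / sqrt((1 - rLT^2) * (1 - rGT^2)))
  F3 <- (n - 3) * prLG_T^2 / (1 - prLG_T^2)
  p3 <- stats::pf(F3, 1, n - 3, lower.tail = FALSE)
  prLT_G <- clip((rLT - rLGc * rGT) / sqrt((1 - rLGc^2) * (1 - rGT^2)))
  F4 <- (n - 3) * prLT_G^2 / (1 - prLT_G^2)
  p4 <- stats::pf(F4, 1, n - 3, ncp = ncp4)
  pmax(p1, p2, p3, p4)
}

#' Permutation FDR for a set of CIT results
#'
#' For each permutation replicate, T is permuted across donors within
#' every trio (destroying mediation while preserving the L-G backbone)
#' and the omnibus p recomputed.  The condition-4 equivalence bound (the
#' direct-effect noncentrality) is part of the test's definition, so the
#' observed estimate is held fixed across the replicates; re-estimating
#' it from permuted data would collapse it together with the conditional
#' F and leave the permuted omnibus with no left tail.  The FDR value at
#' an observed p is
#' \deqn{q(p) = \frac{\mathrm{mean}_b \#\{p^*_b \le p\}}
#'   {\max(1, \#\{p_{obs} \le p\})}}
#' clipped to at most 1 and monotonized in p.  Trios with
#' \code{q < 0.05} are called causal.
#'
#' @param results list of \linkS4class{CitResult} from
#'   \code{\link{citTest}} (one per trio, same order as \code{trios}).
#' @param trios list of \linkS4class{TrioData}.
#' @param B number of permutations (default 1000; below 100 a warning is
#'   emitted since q is unstable).
#' @param seed integer seed for the permutation stream.
#' @param qThreshold call threshold (default 0.05).
#' @return the result list with \code{q} and \code{call} filled in.
#' @export
citFdr <- function(results, trios, B = 1000, seed = 1,
                   qThreshold = 0.05) {
  if (length(results) != length(trios) || !length(trios))
    stop("results and trios must be aligned and nonempty")
  if (B < 100) warning("B < 100: q estimates are unstable")
  pObs <- vapply(results, function(r) r@pCit, 0)
  m <- length(trios)
  pStar <- withSeed(seed, {
    out <- matrix(NA_real_, nrow = m, ncol = B)
    for (i in seq_len(m)) {
      pr <- .citPrepare(trios[[i]])
      ncp4 <- .citNcp4(pr)
      permIdx <- replicate(B, sample.int(pr$n))
      if (ncol(pr$C) == 1) {
        out[i, ] <- .citPermFast(pr, permIdx, ncp4)
      } else {
        out[i, ] <- apply(permIdx, 2, function(ix)
          max(.citP(pr$L, pr$G, pr$T[ix], pr$C,
                    ncp4Override = ncp4)))
      }
    }
    out
  })
  q <- vapply(pObs, function(p) {
    num <- sum(pStar <= p) / B
    den <- max(1, sum(pObs <= p))
    min(1, num / den)
  }, 0)
  # monotonize in p
  o <- order(pObs)
  q[o] <- cummax(q[o])
  q <- pmin(q, 1)
  for (i in seq_along(results)) {
    results[[i]]@q <- q[i]
    results[[i]]@call <- if (q[i] < qThreshold) "causal" else "not-called"
  }
  results
}

#' Downstream-gene network around a mediator
#'
#' Screens candidate downstream genes T for mediation by G of the locus
#' L: candidates are prefiltered by absolute correlation with G, each
#' surviving candidate is CIT-tested as the trait of an (L, G, T) trio,
#' and the permutation FDR is computed across candidates.  Genes with
#' \code{q < 0.05} form the "downstream of G" set.  A candidate collinear
#' with G (including G itself) is rejected by the degeneracy guard and
#' reported, not called.
#'
#' @param L numeric dosage vector.
#' @param G mediator expression vector.
#' @param candidates numeric matrix of candidate expression, donors in
#'   rows, genes in columns.
#' @param corThreshold minimum |cor(G, candidate)| to enter testing
#'   (default 0.3).
#' @param B permutations for \code{\link{citFdr}}.
#' @param seed integer seed.
#' @param covariates optional covariate data.frame.
#' @return data.frame per tested candidate: gene, p1..p4, pCit, q, call;
#'   attribute \code{"rejected"} lists candidates failing the prefilter
#'   or guards.  Empty candidate set yields an empty data.frame.
#' @export
buildDownstreamNetwork <- function(L, G, candidates, corThreshold = 0.3,
                                   B = 1000, seed = 1,
                                   covariates = NULL) {
  empty <- data.frame(gene = character(), p1 = numeric(),
                      p2 = numeric(), p3 = numeric(), p4 = numeric(),
                      pCit = numeric(), q = numeric(),
                      call = character(), stringsAsFactors = FALSE)
  if (is.null(candidates) || NCOL(candidates) == 0) return(empty)
  genes <- colnames(candidates)
  if (is.null(genes)) genes <- sprintf("T%03d", seq_len(ncol(candidates)))
  rejected <- character(0)
  trios <- list(); results <- list(); kept <- character(0)
  for (j in seq_len(ncol(candidates))) {
    tv <- candidates[, j]
    r <- suppressWarnings(stats::cor(G, tv, use = "complete.obs"))
    if (is.na(r) || abs(r) < corThreshold) {
      rejected <- c(rejected, genes[j]); next
    }
    td <- trioData(L, G, tv, covariates = covariates)
    res <- try(citTest(td), silent = TRUE)
    if (inherits(res, "try-error")) {
      rejected <- c(rejected, genes[j]); next
    }
    trios[[length(trios) + 1L]] <- td
    results[[length(results) + 1L]] <- res
    kept <- c(kept, genes[j])
  }
  if (!length(results)) {
    attr(empty, "rejected") <- rejected
    return(empty)
  }
  results <- citFdr(results, trios, B = B, seed = seed)
  out <- cbind(gene = kept, citResultTable(results))
  out <- out[order(out$q, out$pCit), , drop = FALSE]
  out$n <- NULL
  attr(out, "rejected") <- rejected
  out
}
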