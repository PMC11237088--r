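# Internal numerical helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf-safe.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Stage seeds are derived from one global seed by fixed offsets so a stage
# rerun in isolation reproduces its in-pipeline stream.  Offsets stay small;
# callers pass seeds < 2^31 - 1000.
stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 1L, qc = 2L, pseudobulk = 3L, eqtl = 4L,
               cfdr = 5L, coloc = 6L, cit = 7L, da = 8L, enrich = 9L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer(seed) + offsets[[stage]]
}

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Two-sided p from a t statistic.
pFromT <- function(t, df) 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)

# Partial F-test p-value for a single added column `z` in y ~ X + z, where X
# already contains an intercept.  Returns list(F, p, df2, beta, se).
partialF <- function(y, X, z) {
  fit0 <- stats::lm.fit(X, y)
  X1 <- cbind(X, z)
  fit1 <- stats::lm.fit(X1, y)
  if (fit1$rank < ncol(X1)) return(NULL)  # singular with z added
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df2 <- length(y) - fit1$rank
  if (df2 <= 0) return(NULL)
  Fs <- max(0, (rss0 - rss1)) / (rss1 / df2)
  XtXinv <- chol2inv(chol(crossprod(X1)))
  k <- ncol(X1)
  beta <- fit1$coefficients[k]
  se <- sqrt(XtXinv[k, k] * rss1 / df2)
  list(F = Fs, p = stats::pf(Fs, 1, df2, lower.tail = FALSE), df2 = df2,
       beta = unname(beta), se = se)
}
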