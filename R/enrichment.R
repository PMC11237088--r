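#' Collapse cell-level cluster assignments to donor membership
#'
#' A donor is a member of a cluster iff at least \code{minCells} of its
#' cells carry the cluster label (default 1), so each donor counts once
#' per cluster regardless of how many nuclei it contributed.
#'
#' @param cellMeta data.frame with per-cell \code{donor}.
#' @param clusterAssignment per-cell cluster labels aligned with
#'   \code{cellMeta}.
#' @param minCells minimum cells for membership (default 1).
#' @return named list (one entry per cluster) of member donor vectors;
#'   attribute \code{"cohort"} carries all donors seen.
#' @export
collapseToDonors <- function(cellMeta, clusterAssignment, minCells = 1) {
  if (nrow(cellMeta) != length(clusterAssignment))
    stop("cluster assignment must align with cell metadata")
  cohort <- sort(unique(cellMeta$donor))
  out <- lapply(split(cellMeta$donor, clusterAssignment), function(d) {
    tab <- table(d)
    sort(names(tab)[tab >= minCells])
  })
  attr(out, "cohort") <- cohort
  out
}

# Sample odds ratio with Haldane 0.5 correction when a margin cell is 0.
.sampleOR <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Donor-level categorical trait enrichment per cluster
#'
#' For each cluster, the 2x2 membership-by-trait table over the cohort is
#' tested by a two-sided Fisher exact test (the hypergeometric
#' distribution); the sample odds ratio is reported with a Haldane 0.5
#' correction when a table cell is zero; Benjamini-Hochberg FDR is
#' computed across all clusters tested in the call.  An empty or
#' all-cohort membership is degenerate: p = 1, flagged.
#'
#' @param memberships named list of member-donor vectors (from
#'   \code{\link{collapseToDonors}}).
#' @param trait named logical/binary vector over the cohort donors.
#' @param cohort cohort donor ids (defaults to the memberships'
#'   \code{"cohort"} attribute, else \code{names(trait)}).
#' @return data.frame: cluster, oddsRatio, p, fdr, degenerate.
#' @export
categoricalEnrichment <- function(memberships, trait, cohort = NULL) {
  if (is.null(cohort)) cohort <- attr(memberships, "cohort")
  if (is.null(cohort)) cohort <- names(trait)
  if (!all(cohort %in% names(trait)))
    stop("trait must be defined for all cohort donors")
  if (!length(memberships))
    return(data.frame(cluster = character(), oddsRatio = numeric(),
                      p = numeric(), fdr = numeric(),
                      degenerate = logical()))
  tr <- as.logical(trait[cohort])
  rows <- lapply(names(memberships), function(cl) {
    mem <- cohort %in% memberships[[cl]]
    if (!any(mem) || all(mem))
      return(data.frame(cluster = cl, oddsRatio = NA_real_, p = 1,
                        degenerate = TRUE))
    a <- sum(mem & tr); b <- sum(mem & !tr)
    c <- sum(!mem & tr); d <- sum(!mem & !tr)
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(cluster = cl, oddsRatio = .sampleOR(a, b, c, d),
               p = ft$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("cluster", "oddsRatio", "p", "fdr", "degenerate")]
}

#' Donor-level quantitative trait enrichment by subset resampling
#'
#' The observed statistic is the mean trait over the member donors; the
#' null distribution is the mean over random donor subsets of the same
#' size drawn without replacement from the cohort (membership is
#' permuted, not trait values).  Deviation is quantified as
#' \code{z = (obs - mean(null)) / sd(null)} (population sd) and the
#' empirical two-sided p uses the add-one estimator
#' \code{(1 + #\{|null - mean(null)| >= |obs - mean(null)|\}) /
#' (N + 1)}.  When the subset-choice space has at most \code{nPerm}
#' elements, exhaustive enumeration replaces sampling.  A z-derived
#' normal p is also emitted.
#'
#' @param members member donor ids (>= 2 with nonmissing trait).
#' @param trait named numeric vector over the cohort.
#' @param cohort cohort donor ids (default \code{names(trait)}).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed (sampling path only).
#' @return list: observed, z, p (empirical), pNormal, nPerm used,
#'   exhaustive flag, degenerate flag (sd(null) = 0: z undefined,
#'   p = 1), and the null means themselves (\code{nullMeans}).
#' @examples
#' tr <- c(D1 = 1, D2 = 2, D3 = 3, D4 = 4)
#' quantitativeEnrichment(c("D2", "D4"), tr)$z  # 0.774597
#' @export
quantitativeEnrichment <- function(members, trait, cohort = NULL,
                                   nPerm = 10000, seed = 1) {
  if (is.null(cohort)) cohort <- names(trait)
  vals <- trait[cohort]
  mem <- cohort %in% members
  mvals <- vals[mem & !is.na(vals)]
  if (length(mvals) < 2)
    stop("need >= 2 members with nonmissing trait")
  m <- length(mvals)
  pool <- vals[!is.na(vals)]
  obs <- mean(mvals)
  nC <- length(pool)
  exhaustive <- choose(nC, m) <= nPerm
  nullMeans <- if (exhaustive) {
    utils::combn(pool, m, mean)
  } else {
    withSeed(seed, replicate(nPerm, mean(sample(pool, m))))
  }
  nUsed <- length(nullMeans)
  mu <- mean(nullMeans)
  sdPop <- sqrt(mean((nullMeans - mu)^2))
  if (sdPop == 0)
    return(list(observed = obs, z = NA_real_, p = 1, pNormal = 1,
                nPerm = nUsed, exhaustive = exhaustive,
                degenerate = TRUE))
  z <- (obs - mu) / sdPop
  p <- (1 + sum(abs(nullMeans - mu) >= abs(obs - mu) - 1e-12)) /
    (nUsed + 1)
  list(observed = obs, z = z, p = min(1, p),
       pNormal = 2 * stats::pnorm(-abs(z)), nPerm = nUsed,
       exhaustive = exhaustive, degenerate = FALSE,
       nullMeans = as.numeric(nullMeans))
}

#' Fisher set-overlap enrichment
#'
#' Two-sided Fisher exact test on the 2x2 membership-in-A by
#' membership-in-B table over a stated background, with the sample odds
#' ratio (Haldane-corrected on zero cells).
#'
#' @param setA,setB character sets, subsets of \code{background}.
#' @param background the universe over which overlap is assessed.
#' @return list: oddsRatio, p, table (the 2x2 counts).
#' @export
setOverlapEnrichment <- function(setA, setB, background) {
  if (!all(setA %in% background) || !all(setB %in% background))
    stop("background must contain both sets")
  inA <- background %in% setA
  inB <- background %in% setB
  a <- sum(inA & inB); b <- sum(inA & !inB)
  c <- sum(!inA & inB); d <- sum(!inA & !inB)
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                dimnames = list(c("inA", "notA"), c("inB", "notB")))
  ft <- stats::fisher.test(tab)
  list(oddsRatio = .sampleOR(a, b, c, d), p = ft$p.value, table = tab)
}

#' Donor-level detection share of a subpopulation
#'
#' The percentage of donors in which a subpopulation was detected, the
#' summary used when reporting how widespread a differentially abundant
#' population is across a cohort (e.g. among AD subjects).
#'
#' @param nDetected donors with the subpopulation detected.
#' @param nTotal donors examined.
#' @return the share in percent.
#' @examples
#' detectionShare(31, 66)  # ~47
#' @export
detectionShare <- function(nDetected, nTotal) {
  if (nTotal < 1 || nDetected < 0 || nDetected > nTotal)
    stop("need 0 <= nDetected <= nTotal, nTotal >= 1")
  100 * nDetected / nTotal
}

#' Select the last antemortem measurement within a window of death
#'
#' Per donor (and measurement name), the value with the smallest
#' time-before-death among entries with time at most \code{windowDays}
#' (inclusive boundary; default 1095 days = three years).  Donors with
#' no qualifying entry are absent from the result, never imputed.
#'
#' @param series data.frame: \code{donor}, \code{measurement},
#'   \code{value}, \code{days_before_death} (nonnegative).
#' @param windowDays window in days (default 1095).
#' @return data.frame with one row per (donor, measurement) retained.
#' @export
lastMeasurementBeforeDeath <- function(series, windowDays = 1095) {
  if (any(series$days_before_death < 0))
    stop("times before death must be nonnegative")
  ok <- series$days_before_death <= windowDays
  s <- series[ok, , drop = FALSE]
  if (!nrow(s)) return(s)
  key <- paste(s$donor, s$measurement, sep = "\r")
  pick <- unlist(lapply(split(seq_len(nrow(s)), key), function(ix)
    ix[which.min(s$days_before_death[ix])]), use.names = FALSE)
  out <- s[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genotype-trait association with optional pathology interaction
#'
#' OLS of a donor trait on allele dosage plus covariates, optionally
#' adding a pathology variable and a dosage-by-pathology interaction.
#' Quantitative pathology burdens can be log-transformed as
#' \code{log(x + 1)} (zeros allowed); semiquantitative stages are treated
#' as numeric.  Dosage is used as supplied; \code{flipDosage = TRUE}
#' recodes \code{2 - dosage} to switch between major- and minor-allele
#' counting.
#'
#' @param dosage numeric allele dosage (0-2).
#' @param trait numeric donor trait.
#' @param covariates optional data.frame (e.g. age, sex, education).
#' @param interaction optional numeric pathology variable; requests the
#'   interaction term.
#' @param logTransform log(x+1)-transform the pathology variable.
#' @param flipDosage recode dosage as \code{2 - dosage}.
#' @return list: beta, se, p for dosage; with interaction also betaInt,
#'   seInt, pInt; and \code{n} complete cases.
#' @export
genotypeTraitAssoc <- function(dosage, trait, covariates = NULL,
                               interaction = NULL, logTransform = FALSE,
                               flipDosage = FALSE) {
  if (flipDosage) dosage <- 2 - dosage
  df <- data.frame(trait = trait, dosage = dosage)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (!is.null(interaction)) {
    path <- if (logTransform) log(interaction + 1) else interaction
    df$pathology <- path
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < 10) stop("need >= 10 complete cases")
  if (stats::var(df$dosage) == 0) stop("dosage is constant")
  form <- if (is.null(interaction))
    trait ~ . else trait ~ . - dosage - pathology + dosage * pathology
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  out <- list(beta = cf["dosage", 1], se = cf["dosage", 2],
              p = cf["dosage", 4], n = nrow(df))
  if (!is.null(interaction)) {
    out$betaInt <- cf["dosage:pathology", 1]
    out$seInt <- cf["dosage:pathology", 2]
    out$pInt <- cf["dosage:pathology", 4]
  }
  out
}
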