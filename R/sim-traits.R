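#' Simulate donor quantitative traits with genotype and pathology effects
#'
#' Builds a donor table with covariates (age, sex, years of education), a
#' neuropathology burden, and a quantitative trait
#' \code{trait = covariate effects + mainBeta * dosage +
#' interactionBeta * dosage * pathology + noise}, plus a longitudinal
#' antemortem measurement series (repeated timestamped values per donor)
#' for the last-measurement windowing rule.
#'
#' @param geno a \linkS4class{GenotypeMatrix}; the first variant (or
#'   \code{variant}) supplies the dosage.
#' @param mainBeta genotype main-effect slope.
#' @param interactionBeta dosage-by-pathology interaction slope.
#' @param pathologyModel \code{"lognormal"} (a continuous burden such as
#'   tangle density) or \code{"stage"} (semiquantitative 0-6 staging).
#' @param seed integer seed.
#' @param variant variant id or index used for the dosage.
#' @param noiseSd residual sd of the trait.
#' @return list with \code{donors} (data.frame: donor, dosage, age, sex,
#'   educ, pathology, trait) and \code{measurements} (data.frame: donor,
#'   measurement, value, days_before_death) suitable for
#'   \code{\link{lastMeasurementBeforeDeath}}.
#' @examples
#' g <- simGenotypes(simConfig(nDonors = 30, nVariants = 5, seed = 1))
#' tr <- simDonorTraits(g, mainBeta = 1, interactionBeta = 0, seed = 1)
#' head(tr$donors)
#' @export
simDonorTraits <- function(geno, mainBeta, interactionBeta,
                           pathologyModel = c("lognormal", "stage"),
                           seed = 1, variant = 1, noiseSd = 1) {
  stopifnot(is(geno, "GenotypeMatrix"))
  pathologyModel <- match.arg(pathologyModel)
  withSeed(seed, {
    dos <- dosages(geno)[, variant]
    dos[is.na(dos)] <- round(mean(dos, na.rm = TRUE))
    n <- length(dos)
    donors <- rownames(dosages(geno))
    age <- stats::rnorm(n, 85, 5)
    sex <- stats::rbinom(n, 1, 0.5)
    educ <- stats::rnorm(n, 16, 2)
    pathology <- if (pathologyModel == "lognormal")
      stats::rlnorm(n, 0, 1) else sample(0:6, n, replace = TRUE)
    # fixed, documented covariate slopes: age -0.02/yr, sex +0.5, educ +0.05
    trait <- -0.02 * age + 0.5 * sex + 0.05 * educ +
      mainBeta * dos + interactionBeta * dos * pathology +
      stats::rnorm(n, 0, noiseSd)
    donorTab <- data.frame(donor = donors, dosage = dos, age = age,
                           sex = sex, educ = educ, pathology = pathology,
                           trait = trait, stringsAsFactors = FALSE)
    nMeas <- sample(1:5, n, replace = TRUE)
    meas <- data.frame(
      donor = rep(donors, nMeas),
      measurement = "trait",
      days_before_death = unlist(lapply(nMeas, function(k)
        sort(sample(0:2000, k)))),
      stringsAsFactors = FALSE)
    meas$value <- trait[match(meas$donor, donors)] +
      stats::rnorm(nrow(meas), 0, 0.1 * max(noiseSd, 0.1))
    list(donors = donorTab, measurements = meas)
  })
}
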