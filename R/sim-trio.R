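#' Generative scenario for one (L, G, T) trio
#'
#' Describes how locus dosage L, mediator expression G and quantitative
#' trait T are wired: \code{causal} (L -> G -> T), \code{reactive}
#' (L -> T -> G), \code{independent} (L drives G and T separately, no G-T
#' edge) or \code{confounded} (a shared latent confounder drives G and T).
#' Slopes are standardized; noise is Gaussian.
#'
#' @param kind one of \code{"causal"}, \code{"reactive"},
#'   \code{"independent"}, \code{"confounded"}.
#' @param betaLG slope of L on G (causal/independent/confounded chains).
#' @param betaGT slope of G on T (causal) or of T on G (reactive); must be
#'   0 for \code{independent}.
#' @param betaLTdirect direct L-on-T slope; must be 0 for \code{causal}.
#' @param betaConf confounder slope (confounded only).
#' @param n number of donors (>= 10).
#' @param maf minor-allele frequency of L.
#' @param noiseSd Gaussian noise sd applied to every structural equation.
#' @param seed integer seed.
#' @return a validated list of class \code{TrioScenario}.
#' @export
trioScenario <- function(kind, betaLG = 0.5, betaGT = 0.5,
                         betaLTdirect = 0, betaConf = 0, n = 300,
                         maf = 0.3, noiseSd = 1, seed = 1) {
  kinds <- c("causal", "reactive", "independent", "confounded")
  if (!kind %in% kinds)
    stop("unknown scenario kind: ", kind)
  if (n < 10) stop("n must be >= 10")
  if (kind == "causal" && betaLTdirect != 0)
    stop("causal scenario requires betaLTdirect = 0")
  if (kind == "independent" && betaGT != 0)
    stop("independent scenario requires betaGT = 0")
  structure(list(kind = kind, betaLG = betaLG, betaGT = betaGT,
                 betaLTdirect = betaLTdirect, betaConf = betaConf,
                 n = as.integer(n), maf = maf, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "TrioScenario")
}

#' Simulate one (L, G, T) trio under a stated generative model
#'
#' Structural equations by scenario kind (all noise iid Gaussian with the
#' scenario's \code{noiseSd}):
#' \describe{
#'   \item{causal}{\code{G = betaLG*L + e}, \code{T = betaGT*G + e}.}
#'   \item{reactive}{\code{T = betaLTdirect*L + e},
#'     \code{G = betaGT*T + e}.}
#'   \item{independent}{\code{G = betaLG*L + e},
#'     \code{T = betaLTdirect*L + e}.}
#'   \item{confounded}{latent \code{C ~ N(0,1)};
#'     \code{G = betaLG*L + betaConf*C + e},
#'     \code{T = betaLTdirect*L + betaConf*C + e}.}
#' }
#' The true scenario is recorded on the returned object for scoring.
#'
#' @param scenario a \code{\link{trioScenario}}.
#' @return a \linkS4class{TrioData}.
#' @examples
#' td <- simTrio(trioScenario("causal", n = 100, seed = 3))
#' cor(td@L, td@T)
#' @export
simTrio <- function(scenario) {
  stopifnot(inherits(scenario, "TrioScenario"))
  withSeed(scenario$seed, {
    n <- scenario$n
    L <- as.numeric(stats::rbinom(n, 2, scenario$maf))
    e <- function() stats::rnorm(n, 0, scenario$noiseSd)
    G <- T_ <- NULL
    switch(scenario$kind,
      causal = {
        G <- scenario$betaLG * L + e()
        T_ <- scenario$betaGT * G + e()
      },
      reactive = {
        T_ <- scenario$betaLTdirect * L + e()
        G <- scenario$betaGT * T_ + e()
      },
      independent = {
        G <- scenario$betaLG * L + e()
        T_ <- scenario$betaLTdirect * L + e()
      },
      confounded = {
        C <- stats::rnorm(n)
        G <- scenario$betaLG * L + scenario$betaConf * C + e()
        T_ <- scenario$betaLTdirect * L + scenario$betaConf * C + e()
      })
    new("TrioData", L = L, G = G, T = T_,
        covariates = S4Vectors::DataFrame(matrix(nrow = n, ncol = 0)),
        donors = sprintf("D%03d", seq_len(n)), scenario = scenario$kind)
  })
}
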