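# Donor collapse, enrichment tests, windowing and trait association.

test_that("donor collapse counts each donor once per cluster", {
  meta <- data.frame(donor = c(rep("D1", 500), "D2", rep("D3", 20)))
  cl <- c(rep(1, 500), 1, rep(2, 20))
  memb <- collapseToDonors(meta, cl)
  expect_setequal(memb[["1"]], c("D1", "D2"))
  expect_identical(memb[["2"]], "D3")
  memb10 <- collapseToDonors(meta, cl, minCells = 10)
  expect_identical(memb10[["1"]], "D1")  # the 1-cell donor drops out
  expect_setequal(attr(memb, "cohort"), c("D1", "D2", "D3"))
})

test_that("categorical enrichment matches arithmetic and the
           hypergeometric oracle", {
  cohort <- paste0("D", 1:100)
  trait <- setNames(rep(c(TRUE, FALSE), c(20, 80)), cohort)
  # membership yielding the 2x2 table [[10,10],[10,70]]
  memb <- list(c1 = c(cohort[1:10], cohort[21:30]))
  out <- categoricalEnrichment(memb, trait, cohort)
  expect_equal(out$oddsRatio, (10 * 70) / (10 * 10))
  expect_equal(out$p, fisherOracle(10, 10, 10, 70), tolerance = 1e-9)
  expect_equal(out$p, fisher.test(matrix(c(10, 10, 10, 70), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-12)
  # degenerate memberships are flagged with p = 1
  dg <- categoricalEnrichment(list(all = cohort, none = character(0)),
                              trait, cohort)
  expect_true(all(dg$degenerate))
  expect_true(all(dg$p == 1))
  # FDR is computed across the clusters of one call
  multi <- categoricalEnrichment(list(a = cohort[1:10],
                                      b = cohort[15:40]),
                                 trait, cohort)
  expect_equal(multi$fdr, p.adjust(multi$p, "BH"))
})

test_that("categorical enrichment p is calibrated for random membership", {
  set.seed(101)
  cohort <- paste0("D", 1:60)
  trait <- setNames(rep(c(TRUE, FALSE), each = 30), cohort)
  ps <- vapply(1:300, function(i)
    categoricalEnrichment(list(c = sample(cohort, 15)), trait,
                          cohort)$p, 0)
  expect_lte(mean(ps <= 0.05), 0.07)  # discrete Fisher is conservative
})

test_that("quantitative enrichment reproduces the exhaustive fixture", {
  tr <- c(D1 = 1, D2 = 2, D3 = 3, D4 = 4)
  out <- quantitativeEnrichment(c("D2", "D4"), tr)
  expect_true(out$exhaustive)
  expect_identical(out$nPerm, 6L)
  expect_equal(out$z, (3 - 2.5) / 0.645497, tolerance = 1e-6)
  # membership = entire cohort: degenerate, z undefined, p = 1
  whole <- quantitativeEnrichment(names(tr), tr)
  expect_true(whole$degenerate)
  expect_identical(whole$p, 1)
  expect_error(quantitativeEnrichment("D1", tr), ">= 2")
})

test_that("planted shifts grow z monotonically in expectation", {
  set.seed(102)
  cohort <- paste0("D", 1:80)
  meanZ <- vapply(c(0, 0.5, 1.2), function(delta) {
    mean(vapply(1:80, function(i) {
      vals <- setNames(rnorm(80), cohort)
      mem <- sample(cohort, 12)
      vals[mem] <- vals[mem] + delta
      quantitativeEnrichment(mem, vals, nPerm = 1500,
                             seed = 300 + i)$z
    }, 0))
  }, 0)
  expect_true(all(diff(meanZ) > 0))
  expect_lt(abs(meanZ[1]), 0.3)
})

test_that("sampling and exhaustive null distributions agree (KS)", {
  set.seed(103)
  cohort <- paste0("D", 1:14)
  vals <- setNames(rnorm(14), cohort)
  mem <- cohort[1:7]
  ex <- quantitativeEnrichment(mem, vals, nPerm = 10000, seed = 1)
  expect_true(ex$exhaustive)   # choose(14,7) = 3432 <= 10000
  sam <- quantitativeEnrichment(mem, vals, nPerm = 3000, seed = 2)
  expect_false(sam$exhaustive)
  ks <- suppressWarnings(ks.test(ex$nullMeans, sam$nullMeans))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("set-overlap enrichment covers identity, disjoint and oracle", {
  bg <- paste0("g", 1:100)
  idt <- setOverlapEnrichment(bg[1:10], bg[1:10], bg)
  expect_gt(idt$oddsRatio, 100)
  expect_lt(idt$p, 1e-10)
  dis <- setOverlapEnrichment(bg[1:50], bg[51:100], bg)
  expect_lt(dis$oddsRatio, 1)
  set.seed(104)
  a <- sample(bg, 30); b <- sample(bg, 25)
  got <- setOverlapEnrichment(a, b, bg)
  tab <- got$table
  expect_equal(got$p, fisherOracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                   tab[2, 2]), tolerance = 1e-9)
  expect_error(setOverlapEnrichment(c(bg[1], "zzz"), b, bg),
               "background")
})

test_that("the antemortem window selects the last qualifying value", {
  s <- data.frame(donor = c("D1", "D1", "D1", "D2", "D3"),
                  measurement = "hct",
                  value = c(10, 20, 30, 40, 50),
                  days_before_death = c(200, 800, 1200, 2000, 1095))
  out <- lastMeasurementBeforeDeath(s, windowDays = 1095)
  expect_identical(out$value[out$donor == "D1"], 10)   # smallest time
  expect_false("D2" %in% out$donor)                     # all beyond
  expect_identical(out$value[out$donor == "D3"], 50)   # inclusive edge
  expect_error(lastMeasurementBeforeDeath(
    data.frame(donor = "D1", measurement = "x", value = 1,
               days_before_death = -3)), "nonnegative")
})

test_that("genotype-trait association recovers planted structure", {
  set.seed(105)
  n <- 60
  dos <- rbinom(n, 2, 0.4)
  out <- genotypeTraitAssoc(dos, 2 * dos)
  expect_equal(out$beta, 2, tolerance = 1e-10)
  # flipDosage flips the slope sign
  outF <- genotypeTraitAssoc(dos, 2 * dos, flipDosage = TRUE)
  expect_equal(outF$beta, -2, tolerance = 1e-10)
  expect_error(genotypeTraitAssoc(rep(1, n), rnorm(n)), "constant")
})

test_that("opposite-sign interactions flip stratified slopes", {
  g <- simGenotypes(simConfig(nDonors = 2000, nVariants = 2, seed = 106))
  tr <- simDonorTraits(g, mainBeta = 0.8, interactionBeta = -0.5,
                       pathologyModel = "lognormal", seed = 107)
  d <- tr$donors
  out <- genotypeTraitAssoc(d$dosage, d$trait,
                            covariates = d[, c("age", "sex", "educ")],
                            interaction = d$pathology,
                            logTransform = TRUE)
  expect_lt(out$pInt, 1e-4)
  expect_lt(out$betaInt, 0)
  lowS <- d$pathology <= quantile(d$pathology, 1 / 3)
  highS <- d$pathology > quantile(d$pathology, 2 / 3)
  bLow <- genotypeTraitAssoc(d$dosage[lowS], d$trait[lowS])$beta
  bHigh <- genotypeTraitAssoc(d$dosage[highS], d$trait[highS])$beta
  expect_gt(bLow, 0)
  expect_lt(bHigh, 0)
})

test_that("detection shares are plain percentages with guards", {
  expect_equal(detectionShare(31, 66), 100 * 31 / 66)
  expect_error(detectionShare(5, 4), "nTotal")
})
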