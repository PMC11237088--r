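# Approximate Bayes factors and five-hypothesis posteriors.

test_that("lABF matches direct evaluation of the Wakefield formula", {
  # V = 0.01, W = 0.0225, z = 5
  tr <- summaryTrack("v1", beta = 0.5, se = 0.1, maf = 0.3, n = 500)
  expect_equal(unname(computeLabf(tr, W = 0.0225)),
               0.5 * (log(0.01 / 0.0325) + 25 * 0.0225 / 0.0325),
               tolerance = 1e-6)
  # z = 0: lABF = 0.5 log(V/(V+W)) < 0
  tr0 <- summaryTrack("v1", beta = 0, se = 0.1, maf = 0.3, n = 500)
  expect_equal(unname(computeLabf(tr0, W = 0.0225)),
               0.5 * log(0.01 / 0.0325), tolerance = 1e-12)
  # strictly increasing in |z| at fixed V, W
  zs <- seq(0, 6, by = 0.5)
  trz <- summaryTrack(paste0("v", seq_along(zs)), beta = zs * 0.1,
                      se = 0.1, maf = 0.3, n = 500)
  expect_true(all(diff(computeLabf(trz)) > 0))
})

test_that("p-based and se-based variance paths are available", {
  # back-computation from p reproduces |z|; case-control divides by
  # s(1-s)
  z <- 4.2; n <- 1000; maf <- 0.25; s <- 0.1
  p <- 2 * pnorm(-z)
  trQ <- summaryTrack("v1", p = p, maf = maf, n = n)
  Vq <- 1 / (2 * n * maf * (1 - maf))
  W <- 0.15^2
  expect_equal(unname(computeLabf(trQ)),
               0.5 * (log(Vq / (Vq + W)) + z^2 * W / (Vq + W)),
               tolerance = 1e-9)
  trC <- summaryTrack("v1", p = p, maf = maf, n = n, caseFraction = s,
                      traitType = "case_control")
  Vc <- Vq / (s * (1 - s))
  Wc <- 0.2^2
  expect_equal(unname(computeLabf(trC)),
               0.5 * (log(Vc / (Vc + Wc)) + z^2 * Wc / (Vc + Wc)),
               tolerance = 1e-9)
  trBad <- summaryTrack("v1", beta = 1, se = 0, maf = 0.3, n = 10)
  expect_error(computeLabf(trBad), "v1")
})

test_that("log-space posteriors match the direct-summation oracle", {
  set.seed(71)
  for (rep in 1:5) {
    m <- sample(10:50, 1)
    l1 <- rnorm(m, 0, 3); l2 <- rnorm(m, 0, 3)
    names(l1) <- names(l2) <- paste0("v", seq_len(m))
    got <- posteriors(scVarLink:::.colocFromLabf(l1, l2, 1e-4, 1e-4,
                                                 1e-5))
    want <- colocOracle(l1, l2)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)
  }
})

test_that("posteriors are invariant to shifting one track's lABFs", {
  set.seed(72)
  m <- 30
  l1 <- rnorm(m, 0, 2); l2 <- rnorm(m, 0, 2)
  names(l1) <- names(l2) <- paste0("v", seq_len(m))
  ppA <- posteriors(scVarLink:::.colocFromLabf(l1, l2, 1e-4, 1e-4, 1e-5))
  ppB <- posteriors(scVarLink:::.colocFromLabf(l1 + 7.5, l2, 1e-4, 1e-4,
                                               1e-5))
  # H0/H1 trade off with the shift, but the H3:H4 ratio and per-variant
  # posterior are shift-invariant; on the H4-conditional scale:
  pvA <- perVariantPosteriors(
    scVarLink:::.colocFromLabf(l1, l2, 1e-4, 1e-4, 1e-5))
  pvB <- perVariantPosteriors(
    scVarLink:::.colocFromLabf(l1 + 7.5, l2, 1e-4, 1e-4, 1e-5))
  expect_equal(pvA, pvB, tolerance = 1e-12)
  expect_equal(ppA["PP4"] / ppA["PP3"], ppB["PP4"] / ppB["PP3"],
               tolerance = 1e-9)
})

test_that("a single-variant region leaves no room for distinct signals", {
  l1 <- c(v1 = 3.3); l2 <- c(v1 = 1.1)
  pp <- posteriors(scVarLink:::.colocFromLabf(l1, l2, 1e-4, 1e-4, 1e-5))
  expect_identical(unname(pp["PP3"]), 0)  # S1*S2 == S12 exactly
  expect_error(colocalize(summaryTrack("v1", beta = 1, se = 0.2,
                                       maf = 0.3, n = 100),
                          summaryTrack("v1", beta = 1, se = 0.2,
                                       maf = 0.3, n = 100)),
               "2 shared")
})

test_that("a 1122-variant region with strong signals does not overflow", {
  set.seed(73)
  m <- 1122
  l1 <- c(rnorm(m - 1, 0, 2), 700)  # enormous lABF at the last variant
  l2 <- c(rnorm(m - 1, 0, 2), 690)
  names(l1) <- names(l2) <- paste0("v", seq_len(m))
  res <- scVarLink:::.colocFromLabf(l1, l2, 1e-4, 1e-4, 1e-5)
  expect_true(all(is.finite(posteriors(res))))
  expect_equal(sum(posteriors(res)), 1, tolerance = 1e-9)
  expect_gt(posteriors(res)["PP4"], 0.99)
  expect_identical(names(which.max(perVariantPosteriors(res))),
                   paste0("v", m))
})

test_that("intersection of differing variant sets is used and reported", {
  t1 <- summaryTrack(c("a", "b", "c"), beta = c(1, 2, 3), se = 1,
                     maf = 0.3, n = 100)
  t2 <- summaryTrack(c("b", "c", "d"), beta = c(2, 3, 4), se = 1,
                     maf = 0.3, n = 100)
  res <- colocalize(t1, t2)
  expect_identical(res@nVariants, 2L)
  expect_identical(names(perVariantPosteriors(res)), c("b", "c"))
})

test_that("simulated sharing and separation drive PP4 and PP3", {
  cfg <- simConfig(nDonors = 2000, nVariants = 50, ldDecay = 0.6,
                   effectSize = 0.6, seed = 11)
  shared <- simGwasPair(TRUE, 50, 25, cfg)
  ppS <- posteriors(colocalize(shared$eqtl, shared$gwas))
  expect_gt(ppS["PP4"], 0.9)
  expect_identical(names(which.max(perVariantPosteriors(
    colocalize(shared$eqtl, shared$gwas)))), "v0025")
  distinct <- simGwasPair(FALSE, 50, 5, cfg)
  expect_gt(posteriors(colocalize(distinct$eqtl, distinct$gwas))["PP3"],
            0.9)
  cfg0 <- cfg; cfg0$effectSize <- 0
  null <- simGwasPair(TRUE, 50, 25, cfg0)
  expect_gt(posteriors(colocalize(null$eqtl, null$gwas))["PP0"], 0.9)
  expect_error(simGwasPair(TRUE, 1, 1, cfg), "regionSize")
})
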