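# Sigmoid UMI cutoff and the nucleus-level filter chain.

test_that("an exact logistic sample recovers mu +/- ln4*s analytically", {
  x <- qlogis(ppoints(500), location = 3.5, scale = 0.1)
  f <- fitSigmoidCutoffs(x)
  expect_true(f@converged)
  expect_equal(f@lower, 3.5 - log(4) * 0.1, tolerance = 1e-3)
  expect_equal(f@upper, 3.5 + log(4) * 0.1, tolerance = 1e-3)
  # the fitted CDF evaluates to 1/5 and 4/5 at the cutoffs
  expect_equal(plogis(f@lower, f@mu, f@s), 0.2, tolerance = 1e-6)
  expect_equal(plogis(f@upper, f@mu, f@s), 0.8, tolerance = 1e-6)
})

test_that("the least-squares fit matches a grid-search oracle", {
  set.seed(21)
  x <- c(rnorm(400, 3, 0.15), rnorm(100, 1.8, 0.3))  # dominant mode at 3
  f <- fitSigmoidCutoffs(x)
  xs <- sort(x)
  Femp <- (seq_along(xs) - 0.5) / length(xs)
  sse <- function(mu, s)
    sum((plogis(xs, mu, s) - Femp)^2)
  grid <- expand.grid(mu = seq(1.5, 3.5, by = 0.02),
                      s = seq(0.02, 0.8, by = 0.02))
  gridSse <- mapply(sse, grid$mu, grid$s)
  # the optimizer is at least as good as the best grid point
  expect_lte(sse(f@mu, f@s), min(gridSse) + 1e-8)
  # cutoffs bracket the dominant mode
  expect_lt(f@lower, 3)
  expect_gt(f@upper, 3)
})

test_that("sigmoid cutoffs are equivariant under affine shifts", {
  x <- qlogis(ppoints(300), location = 2.8, scale = 0.2)
  f0 <- fitSigmoidCutoffs(x)
  f1 <- fitSigmoidCutoffs(x + 1.3)
  expect_equal(f1@mu, f0@mu + 1.3, tolerance = 1e-6)
  expect_equal(f1@lower, f0@lower + 1.3, tolerance = 1e-6)
  expect_equal(f1@upper, f0@upper + 1.3, tolerance = 1e-6)
})

test_that("degenerate sigmoid inputs error; hopeless fits fall back", {
  expect_error(fitSigmoidCutoffs(rep(3, 10)), "degenerate")
  expect_error(fitSigmoidCutoffs(rnorm(49)), "degenerate")
  expect_error(fitSigmoidCutoffs(rep(2, 100)), "degenerate")
})

test_that("single rule violations remove cells per the stated thresholds", {
  # 60 passing cells plus one violating each rule; wide sigmoid via an
  # explicit fit so the UMI window covers everyone
  base <- makeQcCells(nGenes = rep(1000, 60),
                      totalUmi = rep(4000, 60))
  fit <- new("SigmoidFit", mu = log10(4000), s = 0.1, lower = 1,
             upper = 6, multiplier = log(4), converged = TRUE)
  r0 <- applyCellFilters(base, qcConfig(), sigmoidFit = fit)
  expect_identical(length(r0$report$removed), 0L)
  gene150 <- makeQcCells(nGenes = c(rep(1000, 60), 150),
                         totalUmi = rep(4000, 61))
  r1 <- applyCellFilters(gene150, qcConfig(), sigmoidFit = fit)
  expect_identical(unname(r1$report$counts["gene_count"]), 1L)
  expect_identical(r1$report$removed, "c61")
  mito <- makeQcCells(nGenes = rep(1000, 61), totalUmi = rep(4000, 61),
                      fracMito = c(rep(0, 60), 0.06))
  r2 <- applyCellFilters(mito, qcConfig(), sigmoidFit = fit)
  expect_identical(unname(r2$report$counts["mito"]), 1L)
  expect_identical(r2$report$removed, "c61")
})

test_that("removal attribution is a partition in the documented order", {
  # one cell failing both gene count and mito goes to gene_count
  cells <- makeQcCells(nGenes = c(rep(1000, 60), 100),
                       totalUmi = rep(4000, 61),
                       fracMito = c(rep(0, 60), 0.5))
  fit <- new("SigmoidFit", mu = log10(4000), s = 0.1, lower = 1,
             upper = 6, multiplier = log(4), converged = TRUE)
  r <- applyCellFilters(cells, qcConfig(), sigmoidFit = fit)
  expect_identical(unname(r$report$counts["gene_count"]), 1L)
  expect_identical(unname(r$report$counts["mito"]), 0L)
  expect_identical(sum(r$report$counts), length(r$report$removed))
})

test_that("filtering is idempotent given a fixed sigmoid fit", {
  cfg <- simConfig(nDonors = 5, nGenes = 100,
                   nCellsPerDonor = c(60, 60), seed = 22)
  sce <- simCells(cfg, subpopFractionByCondition = c(A = 0, B = 0),
                  qcViolationFraction = 0.15)
  qcc <- qcConfig(minGenes = 20, maxHemoglobinFrac = 0.05,
                  minLog10GenesPerUmi = 0.5,
                  sigmoidScaleMultiplier = 10 * log(4))
  sce <- computeCellQcStats(sce)
  fit <- fitSigmoidCutoffs(
    log10(pmax(SummarizedExperiment::colData(sce)$totalUmi, 1)), qcc)
  r1 <- applyCellFilters(sce, qcc, sigmoidFit = fit)
  r2 <- applyCellFilters(r1$cells, qcc, sigmoidFit = fit)
  expect_identical(length(r2$report$removed), 0L)
  expect_identical(colnames(r2$cells), colnames(r1$cells))
})

test_that("planted QC violations are exactly the removed cells", {
  cfg <- simConfig(nDonors = 10, nGenes = 100,
                   nCellsPerDonor = c(100, 100), seed = 23)
  sce <- simCells(cfg, subpopFractionByCondition = c(A = 0, B = 0),
                  qcViolationFraction = 0.1)
  truth <- SummarizedExperiment::colData(sce)$qcViolation
  # thresholds scaled to the 100-gene synthetic panel; wide UMI window
  qcc <- qcConfig(minGenes = 20, maxHemoglobinFrac = 0.05,
                  minLog10GenesPerUmi = 0.5,
                  sigmoidScaleMultiplier = 10 * log(4))
  r <- applyCellFilters(sce, qcc)
  expect_setequal(r$report$removed, colnames(sce)[truth])
  # brute-force re-application of every rule, straight from counts
  sce <- computeCellQcStats(sce)
  cd <- SummarizedExperiment::colData(sce)
  fit <- r$report$sigmoidFit
  l10 <- log10(pmax(cd$totalUmi, 1))
  oracle <- cd$nGenesDetected < qcc$minGenes |
    cd$fracMito > qcc$maxMitoFrac | cd$fracRibo > qcc$maxRiboFrac |
    cd$fracHemoglobin > qcc$maxHemoglobinFrac |
    cd$log10GenesPerUmi < qcc$minLog10GenesPerUmi |
    l10 < fit@lower | l10 > fit@upper
  expect_identical(sort(r$report$removed), sort(colnames(sce)[oracle]))
})

test_that("missing gene-set annotation is a configuration error", {
  cts <- Matrix::Matrix(matrix(5, 4, 60), sparse = TRUE,
                        dimnames = list(paste0("g", 1:4),
                                        paste0("c", 1:60)))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cts))
  expect_error(applyCellFilters(sce, qcConfig()), "geneClass")
})
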