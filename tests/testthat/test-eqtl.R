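# cis-eQTL mapping, interaction testing and the conditional FDR.

makePb <- function(exprMat, donors = NULL) {
  if (is.null(donors))   # same naming scheme makeGeno applies
    donors <- sprintf("D%03d", seq_len(ncol(exprMat)))
  dimnames(exprMat) <- list(paste0("gene", seq_len(nrow(exprMat))),
                            donors)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(pseudobulk = exprMat),
    colData = S4Vectors::DataFrame(donor = donors, row.names = donors))
}

test_that("the cis window boundary is inclusive at 250 kb", {
  set.seed(51)
  n <- 30
  dos <- cbind(rbinom(n, 2, 0.4), rbinom(n, 2, 0.4))
  g <- makeGeno(dos, pos = c(1254999, 1255001))
  genes <- data.frame(gene_id = "gene1", chrom = "chr1",
                      start = 1000000, end = 1005000)
  pb <- makePb(matrix(rnorm(n), 1), rownames(dos))
  out <- mapCisEqtl(pb, g, genes, config = eqtlConfig(nExpressionPcs = 0))
  expect_identical(out$results$variant, "v0001")  # 249,999 bp away
})

test_that("noise-free dosage expression gives beta 1 and tiny p", {
  set.seed(52)
  n <- 40
  dos <- matrix(rbinom(n, 2, 0.4), n, 1)
  g <- makeGeno(dos, pos = 1002000)
  pb <- makePb(matrix(dos[, 1], 1), rownames(dos))
  genes <- data.frame(gene_id = "gene1", chrom = "chr1",
                      start = 1000000, end = 1004000)
  out <- mapCisEqtl(pb, g, genes, config = eqtlConfig(nExpressionPcs = 0))
  expect_equal(out$results$beta, 1, tolerance = 1e-10)
  expect_lt(out$results$p, 1e-20)
})

test_that("per-pair OLS agrees with a matrix-algebra oracle", {
  set.seed(53)
  n <- 60
  dos <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  rownames(dos) <- sprintf("D%03d", seq_len(n))
  colnames(dos) <- sprintf("v%04d", 1:3)
  g <- makeGeno(dos, pos = c(1001000, 1002000, 1003000))
  covars <- data.frame(age = rnorm(n, 80, 5), sex = rbinom(n, 1, 0.5),
                       row.names = rownames(dos))
  expr <- matrix(rnorm(2 * n), 2, n)
  pb <- makePb(expr, rownames(dos))
  genes <- data.frame(gene_id = c("gene1", "gene2"), chrom = "chr1",
                      start = c(1000000, 1001500),
                      end = c(1004000, 1005000))
  out <- mapCisEqtl(pb, g, genes, covars = covars,
                    config = eqtlConfig(nExpressionPcs = 0))
  for (i in seq_len(nrow(out$results))) {
    r <- out$results[i, ]
    y <- expr[match(r$gene, rownames(pb)), ]
    z <- dos[, r$variant]
    fit <- lm(y ~ age + sex + z, data = cbind(covars, z = z))
    cf <- summary(fit)$coefficients["z", ]
    expect_equal(r$beta, unname(cf["Estimate"]), tolerance = 1e-8)
    expect_equal(r$se, unname(cf["Std. Error"]), tolerance = 1e-8)
    expect_equal(r$p, unname(cf["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("results are invariant to donor ordering", {
  set.seed(54)
  n <- 50
  dos <- matrix(rbinom(n * 2, 2, 0.3), n, 2)
  g <- makeGeno(dos, pos = c(1001000, 1002000))
  expr <- matrix(rnorm(n) + 0.5 * dos[, 1], 1, n)
  pb <- makePb(expr, rownames(dos))
  genes <- data.frame(gene_id = "gene1", chrom = "chr1",
                      start = 1000000, end = 1003000)
  cfg <- eqtlConfig(nExpressionPcs = 0)
  out1 <- mapCisEqtl(pb, g, genes, config = cfg)$results
  perm <- sample(n)
  out2 <- mapCisEqtl(pb[, perm], g[perm, ], genes,
                     config = cfg)$results
  expect_equal(out1$beta, out2$beta, tolerance = 1e-12)
  expect_equal(out1$p, out2$p, tolerance = 1e-12)
})

test_that("constant-dosage pairs are skipped with a reason code", {
  n <- 30
  dos <- cbind(rep(1, n), rbinom(n, 2, 0.4))
  g <- makeGeno(dos, pos = c(1001000, 1002000))
  pb <- makePb(matrix(rnorm(n), 1), rownames(dos))
  genes <- data.frame(gene_id = "gene1", chrom = "chr1",
                      start = 1000000, end = 1003000)
  out <- mapCisEqtl(pb, g, genes, config = eqtlConfig(nExpressionPcs = 0))
  expect_identical(out$skipped$variant, "v0001")
  expect_identical(out$skipped$reason, "constant_dosage")
  expect_identical(out$results$variant, "v0002")
})

test_that("planted effects are recovered and null genes calibrated", {
  set.seed(55)
  n <- 200
  dos <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  g <- makeGeno(dos, pos = c(1001000, 1002000))
  betas <- c(0.3, 0)
  expr <- rbind(betas[1] * dos[, 1] + rnorm(n),
                rnorm(n))
  pb <- makePb(expr, rownames(dos))
  genes <- data.frame(gene_id = c("gene1", "gene2"), chrom = "chr1",
                      start = 1000000, end = 1003000)
  out <- mapCisEqtl(pb, g, genes,
                    config = eqtlConfig(nExpressionPcs = 0))$results
  r1 <- out[out$gene == "gene1" & out$variant == "v0001", ]
  expect_lt(abs(r1$beta - 0.3), 3 * r1$se)
  # null-gene p-values behave uniformly across replicates
  ps <- vapply(1:200, function(i) {
    y <- rnorm(n)
    f <- summary(lm(y ~ dos[, 2]))$coefficients
    f[2, 4]
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the diagnosis-by-dosage interaction is testable and guarded", {
  set.seed(56)
  n <- 80
  dos <- rbinom(n, 2, 0.4)
  dx <- rep(c(0, 1), each = n / 2)
  # noise-free: expression follows dosage only in the diagnosis group
  y <- ifelse(dx == 1, dos, 0)
  out <- testInteraction(y, dos, dx)
  expect_equal(out$betaInt, 1, tolerance = 1e-10)
  expect_equal(out$betaMain, 0, tolerance = 1e-10)
  # identical slopes in both groups: no interaction
  y2 <- 0.7 * dos + rnorm(n, sd = 0.1)
  out2 <- testInteraction(y2, dos, dx)
  expect_lt(abs(out2$betaInt), 0.2)
  expect_gt(out2$p, 0.01)
  expect_error(testInteraction(y, dos, rep(1, n)), "both")
  expect_error(testInteraction(y, ifelse(dx == 1, dos, 0), dx),
               "constant")
})

test_that("interaction p-values are calibrated under label permutation", {
  set.seed(57)
  n <- 120
  dos <- rbinom(n, 2, 0.4)
  y <- 0.5 * dos + rnorm(n)
  ps <- vapply(1:200, function(i)
    testInteraction(y, dos, sample(rep(c(0, 1), each = n / 2)))$p, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
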