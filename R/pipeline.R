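#' Pipeline run configuration
#'
#' Bundles the module configuration blocks, stage selection, output
#' location and the single global seed that fans out to per-stage seeds
#' via a fixed offset scheme (so a stage rerun in isolation reproduces
#' its in-pipeline stream).
#'
#' The default scale (60 donors, 30 variants, 60 genes, ~50 cells per
#' donor) exercises every stage in seconds; real cohorts swap in their
#' own inputs per stage.  The demo DA thresholds (-0.4, 0.4) suit the
#' planted 0.25-vs-0.05 condition fractions, whose calibrated measure
#' ceiling sits near 0.56.
#'
#' @param outputDir directory for stage outputs and the manifest.
#' @param seed global integer seed.
#' @param stages stages to run, in dependency order, from
#'   \code{simulate, qc, pseudobulk, eqtl, coloc, cit, da, enrich}.
#' @param sim a \code{\link{simConfig}}.
#' @param qc a \code{\link{qcConfig}}; the demo default rescales the
#'   gene-count, genes-per-UMI and hemoglobin thresholds to the small
#'   synthetic gene panel (the shipped defaults assume a
#'   transcriptome-wide panel, where e.g. log10 genes / log10 UMI sits
#'   near 0.8 rather than the ~0.7 a 40-gene panel yields).
#' @param eqtl an \code{\link{eqtlConfig}}.
#' @param da a \code{\link{daConfig}}.
#' @param citB CIT permutation count for the demo stage.
#' @return a list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(outputDir = tempfile("scvarlink_run_"),
                           seed = 1,
                           stages = c("simulate", "qc", "pseudobulk",
                                      "eqtl", "coloc", "cit", "da",
                                      "enrich"),
                           sim = simConfig(nDonors = 60, nVariants = 30,
                                           nGenes = 60,
                                           nCellsPerDonor = c(40, 60),
                                           ldDecay = 0.3, seed = seed),
                           qc = qcConfig(minGenes = 15,
                                         minLog10GenesPerUmi = 0.5,
                                         maxHemoglobinFrac = 0.01),
                           eqtl = eqtlConfig(nExpressionPcs = 5),
                           da = daConfig(kGrid = seq(50, 350, by = 100),
                                         thresholds = c(-0.4, 0.4)),
                           citB = 200) {
  known <- c("simulate", "qc", "pseudobulk", "eqtl", "coloc", "cit",
             "da", "enrich")
  if (!all(stages %in% known))
    stop("config error: unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 stages = stages, sim = sim, qc = qc, eqtl = eqtl,
                 da = da, citB = citB), class = "RunConfig")
}

#' Validate pipeline input files
#'
#' Structural checks on a set of input paths: the VCF parses and its
#' data lines have at least 8 tab-separated fields (violations reported
#' with file and line number), the MatrixMarket directory has its
#' sidecars with aligned dimensions, gene coordinates satisfy
#' \code{start <= end} with positive positions, and donor identifiers
#' align between genotypes and cell metadata (mismatches reported by
#' name).  Problems are collected and returned, never thrown mid-parse.
#'
#' @param vcf optional VCF path.
#' @param cellsDir optional cell-matrix directory
#'   (see \code{\link{writeCellMatrix}}).
#' @param genes optional gene-coordinate TSV path.
#' @return data.frame \code{level, file, line, message}; zero rows when
#'   everything is consistent.
#' @export
validateInputs <- function(vcf = NULL, cellsDir = NULL, genes = NULL) {
  issues <- data.frame(level = character(), file = character(),
                       line = integer(), message = character(),
                       stringsAsFactors = FALSE)
  add <- function(level, file, line, message) {
    issues[nrow(issues) + 1L, ] <<-
      list(level, file, as.integer(line), message)
  }
  vcfDonors <- NULL
  if (!is.null(vcf)) {
    if (!file.exists(vcf)) {
      add("error", vcf, NA, "file not found")
    } else {
      con <- gzfile(vcf, "r")
      lines <- readLines(con); close(con)
      body <- which(!startsWith(lines, "#"))
      for (i in body) {
        if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8)
          add("error", vcf, i, "malformed VCF line (< 8 fields)")
      }
      hdr <- grep("^#CHROM", lines, value = TRUE)
      if (length(hdr)) {
        f <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
        if (length(f) > 9) vcfDonors <- f[-(1:9)]
      } else {
        add("error", vcf, NA, "missing #CHROM header line")
      }
    }
  }
  cellDonors <- NULL
  if (!is.null(cellsDir)) {
    mtx <- file.path(cellsDir, "matrix.mtx")
    for (f in c(mtx, file.path(cellsDir, c("genes.tsv", "cells.tsv")))) {
      if (!file.exists(f)) add("error", f, NA, "file not found")
    }
    if (all(file.exists(c(mtx, file.path(cellsDir, "cells.tsv"))))) {
      first <- readLines(mtx, n = 1)
      if (!grepl("^%%MatrixMarket", first))
        add("error", mtx, 1, "missing MatrixMarket banner")
      cm <- readTsv(file.path(cellsDir, "cells.tsv"))
      if (!"donor" %in% colnames(cm)) {
        add("error", file.path(cellsDir, "cells.tsv"), NA,
            "cells.tsv lacks a donor column")
      } else {
        cellDonors <- unique(cm$donor)
      }
    }
  }
  if (!is.null(genes) && file.exists(genes)) {
    g <- readTsv(genes)
    bad <- which(g$start > g$end | g$start < 1)
    for (i in bad)
      add("error", genes, i + 1L,
          paste0("bad coordinates for ", g$gene_id[i]))
  } else if (!is.null(genes)) {
    add("error", genes, NA, "file not found")
  }
  if (!is.null(vcfDonors) && !is.null(cellDonors)) {
    for (d in setdiff(cellDonors, vcfDonors))
      add("warning", "donor alignment", NA,
          paste0("donor ", d, " present in expression but absent ",
                 "from VCF"))
  }
  issues
}

# Run one stage with a stage-named abort on failure.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the selected stages in dependency order on synthetic data:
#' simulate (genotypes, genes, cells with planted cis effects and QC
#' violations, donor traits) -> qc -> pseudobulk -> eqtl (+ conditional
#' FDR against a simulated replication cohort) -> coloc -> cit -> da ->
#' enrich.  Each stage writes its outputs under
#' \code{config$outputDir}; a YAML manifest records package and R
#' versions, the seed fan-out, the configuration blocks and md5
#' checksums of every output, and is reproducible byte-for-byte for a
#' fixed seed except for its timestamp.  Any stage failure aborts with a
#' stage-named error.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest list, invisibly; the YAML lives at
#'   \code{file.path(config$outputDir, "manifest.yaml")}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (!inherits(config, "RunConfig"))
    stop("config error: not a RunConfig")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  od <- config$outputDir
  seed <- config$seed
  stages <- config$stages
  outputs <- character(0)
  results <- list()
  geno <- cells <- genes <- traits <- NULL
  if ("simulate" %in% stages) .stage("simulate", {
    simCfg <- config$sim
    simCfg$seed <- stageSeed(seed, "simulate")
    geno <- simGenotypes(simCfg)
    genes <- simGeneCoordinates(simCfg, geno)
    planted <- data.frame(
      gene = genes$gene_id[seq_len(min(5, nrow(genes)))],
      variant = vapply(seq_len(min(5, nrow(genes))), function(i)
        rownames(variantInfo(geno))[
          which.min(abs(variantInfo(geno)$pos - genes$start[i]))], ""),
      beta = simCfg$effectSize)
    cells <- simCells(simCfg,
                       subpopFractionByCondition = c(A = 0.25, B = 0.05),
                       geno = geno, eqtlEffects = planted,
                       qcViolationFraction = 0.05)
    traits <- simDonorTraits(geno, mainBeta = simCfg$effectSize,
                              interactionBeta = 0,
                              seed = stageSeed(seed, "simulate"))
    writeGenotypeVcf(geno, file.path(od, "genotypes.vcf.gz"))
    writeCellMatrix(cells, file.path(od, "cells"))
    writeTsv(genes, file.path(od, "genes.tsv"))
    writeTsv(traits$donors, file.path(od, "donors.tsv"))
    writeTsv(traits$measurements, file.path(od, "measurements.tsv"))
    writeTsv(planted, file.path(od, "planted_eqtl.tsv"))
    outputs <- c(outputs, "genotypes.vcf.gz", "cells/matrix.mtx",
                  "cells/genes.tsv", "cells/cells.tsv", "genes.tsv",
                  "donors.tsv", "measurements.tsv", "planted_eqtl.tsv")
    results$planted <- planted
  }) else {
    # preflight for a partial run: required inputs must already exist
    need <- c("genotypes.vcf.gz", "cells", "genes.tsv", "donors.tsv")
    miss <- need[!file.exists(file.path(od, need))]
    if (length(miss))
      stop("config error: missing inputs for partial run: ",
           paste(miss, collapse = ", "))
    geno <- readGenotypeVcf(file.path(od, "genotypes.vcf.gz"))
    cells <- readCellMatrix(file.path(od, "cells"))
    genes <- readTsv(file.path(od, "genes.tsv"))
    traits <- list(donors = readTsv(file.path(od, "donors.tsv")))
    if (file.exists(file.path(od, "measurements.tsv")))
      traits$measurements <- readTsv(file.path(od, "measurements.tsv"))
  }
  if ("qc" %in% stages) .stage("qc", {
    flt <- applyCellFilters(cells, config$qc)
    cells <- flt$cells
    rep <- flt$report
    writeTsv(rep$perCell, file.path(od, "filter_report.tsv"))
    outputs <- c(outputs, "filter_report.tsv")
    results$qc <- rep$counts
  })
  pb <- NULL
  if ("pseudobulk" %in% stages) .stage("pseudobulk", {
    cells <- normalizeCells(cells)
    pb <- aggregatePseudobulk(cells)
    writeTsv(cbind(gene = rownames(pb),
                   as.data.frame(SummarizedExperiment::assay(pb))),
             file.path(od, "pseudobulk.tsv"))
    outputs <- c(outputs, "pseudobulk.tsv")
  })
  if ("eqtl" %in% stages) .stage("eqtl", {
    vq <- variantQC(geno)
    kept <- ldPrune(vq$geno, config$eqtl$ldR2Threshold,
                    config$eqtl$cisWindow)
    panel <- vq$geno[, kept]
    mapped <- mapCisEqtl(pb, panel, genes, config = config$eqtl)
    # conditional FDR against an independently simulated replication
    simCfg <- config$sim
    simCfg$seed <- stageSeed(seed, "cfdr")
    repCells <- simCells(simCfg,
                         subpopFractionByCondition = c(A = 0.25,
                                                       B = 0.05),
                         geno = geno, eqtlEffects = results$planted)
    repPb <- aggregatePseudobulk(normalizeCells(repCells))
    aux <- mapCisEqtl(repPb, panel, genes,
                      config = config$eqtl)$results
    res <- eqtlCallSignificance(mapped$results, aux,
                                config$eqtl$fdrThreshold)
    writeTsv(res, file.path(od, "eqtl_results.tsv"))
    writeTsv(vq$records, file.path(od, "variant_qc.tsv"))
    outputs <- c(outputs, "eqtl_results.tsv", "variant_qc.tsv")
    results$eqtl <- res
  })
  if ("coloc" %in% stages) .stage("coloc", {
    gcfg <- config$sim
    gcfg$nDonors <- max(gcfg$nDonors, 500L)
    gcfg$seed <- stageSeed(seed, "coloc")
    gcfg$effectSize <- 1
    pair <- simGwasPair(TRUE, regionSize = 20, causalIndex = 10,
                        config = gcfg)
    cr <- colocalize(pair$eqtl, pair$gwas)
    writeTsv(data.frame(hypothesis = names(posteriors(cr)),
                        posterior = as.numeric(posteriors(cr))),
             file.path(od, "coloc_posteriors.tsv"))
    outputs <- c(outputs, "coloc_posteriors.tsv")
    results$coloc <- posteriors(cr)
  })
  if ("cit" %in% stages) .stage("cit", {
    mk <- function(kind, i) simTrio(trioScenario(
      kind, betaLTdirect = if (kind == "causal") 0 else 0.5,
      betaGT = if (kind == "independent") 0 else 0.5,
      n = 200, seed = stageSeed(seed, "cit") + i))
    trios <- c(lapply(1:10, function(i) mk("causal", i)),
               lapply(1:10, function(i) mk("independent", 100 + i)))
    res <- citFdr(lapply(trios, citTest), trios, B = config$citB,
                  seed = stageSeed(seed, "cit"))
    tab <- citResultTable(res)
    tab$truth <- vapply(trios, function(t) t@scenario, "")
    writeTsv(tab, file.path(od, "cit_results.tsv"))
    outputs <- c(outputs, "cit_results.tsv")
    results$cit <- tab
  })
  if ("da" %in% stages) .stage("da", {
    emb <- daEmbedding(cells, config$da$nPcs)
    cond <- SummarizedExperiment::colData(cells)$condition
    daCfg <- config$da
    daCfg$kGrid <- daCfg$kGrid[daCfg$kGrid < nrow(emb)]
    if (!length(daCfg$kGrid))
      stop("no usable k values below the cell count")
    da <- daRun(emb, cond, daCfg)
    writeTsv(data.frame(cell = colnames(cells),
                        measure = da$measure),
             file.path(od, "da_measure.tsv"))
    writeTsv(da$selected, file.path(od, "da_cells.tsv"))
    outputs <- c(outputs, "da_measure.tsv", "da_cells.tsv")
    results$da <- da
  })
  if ("enrich" %in% stages) .stage("enrich", {
    cd <- as.data.frame(SummarizedExperiment::colData(cells))
    da <- results$da
    if (is.null(da)) stop("enrich requires the da stage")
    lab <- rep(NA_integer_, ncol(cells))
    if (nrow(da$selected))
      lab[da$selected$cell] <- da$selected$subpopulation
    memb <- if (any(!is.na(lab)))
      collapseToDonors(cd[!is.na(lab), , drop = FALSE],
                       lab[!is.na(lab)]) else list()
    attr(memb, "cohort") <- sort(unique(cd$donor))
    donorCond <- tapply(cd$condition, cd$donor, function(x) x[1])
    trait <- stats::setNames(donorCond == "A", names(donorCond))
    cat <- categoricalEnrichment(memb, trait)
    writeTsv(cat, file.path(od, "cluster_enrichment.tsv"))
    sel <- lastMeasurementBeforeDeath(traits$measurements)
    donorsTab <- traits$donors
    m <- match(donorsTab$donor, sel$donor)
    assoc <- genotypeTraitAssoc(
      donorsTab$dosage[!is.na(m)], sel$value[m[!is.na(m)]],
      covariates = donorsTab[!is.na(m), c("age", "sex", "educ")])
    writeTsv(data.frame(beta = assoc$beta, se = assoc$se, p = assoc$p,
                        n = assoc$n),
             file.path(od, "trait_assoc.tsv"))
    outputs <- c(outputs, "cluster_enrichment.tsv", "trait_assoc.tsv")
    results$enrich <- list(categorical = cat, assoc = assoc)
  })
  manifest <- list(
    package = "scVarLink",
    version = as.character(utils::packageVersion("scVarLink")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    stageSeeds = as.list(vapply(stages, function(s)
      stageSeed(seed, if (s %in% c("pseudobulk")) "pseudobulk" else s),
      1L)),
    stages = stages,
    configs = list(sim = unclass(config$sim), qc = unclass(config$qc),
                   eqtl = unclass(config$eqtl),
                   da = lapply(unclass(config$da), function(x)
                     if (length(x) > 1) as.list(x) else x)),
    outputs = as.list(vapply(outputs, function(f)
      unname(tools::md5sum(file.path(od, f))), "")))
  writeRunManifest(manifest, file.path(od, "manifest.yaml"))
  invisible(manifest)
}
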