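# Readers and writers for the interchange formats: VCF (v4.2, GT field)
# for genotypes, MatrixMarket + TSV sidecars for counts, TSV for donor
# tables and summary tracks, YAML for run manifests.

#' Write a GenotypeMatrix as VCF (v4.2, GT genotypes)
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param path output path; written gzip-compressed (use a
#'   \code{.vcf.gz} suffix).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(geno, path) {
  dos <- dosages(geno)
  vi <- variantInfo(geno)
  gtStr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = ncol(dos), ncol = nrow(dos))
  for (i in seq_len(nrow(dos))) {
    d <- dos[i, ]
    gt[, i] <- ifelse(is.na(d), "./.", gtStr[as.character(d)])
  }
  colnames(gt) <- rownames(dos)
  fix <- cbind(CHROM = as.character(vi$chrom),
               POS = as.character(vi$pos), ID = colnames(dos),
               REF = as.character(vi$ref), ALT = as.character(vi$alt),
               QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- methods::new("vcfR",
    meta = c("##fileformat=VCFv4.2",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">")),
    fix = fix,
    gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read a VCF into a GenotypeMatrix
#'
#' Biallelic GT calls are converted to alt-allele dosage; any genotype
#' containing a missing allele becomes \code{NA}.
#'
#' @param path a VCF (optionally gzip-compressed).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt <- gsub("[|]", "/", gt)
  dos <- apply(alt, c(1, 2), function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_real_)
    sum(as.numeric(strsplit(g, "/", fixed = TRUE)[[1]]) > 0)
  })
  dos <- t(dos)  # donors x variants
  fx <- vcfR::getFIX(vcf)
  vars <- S4Vectors::DataFrame(chrom = fx[, "CHROM"],
                               pos = as.integer(fx[, "POS"]),
                               ref = fx[, "REF"], alt = fx[, "ALT"],
                               row.names = fx[, "ID"])
  colnames(dos) <- fx[, "ID"]
  new("GenotypeMatrix", dosage = dos, variants = vars)
}

#' Write/read a cell matrix as MatrixMarket plus TSV sidecars
#'
#' \code{writeCellMatrix} writes \code{matrix.mtx} (genes x cells sparse
#' counts), \code{genes.tsv} (gene id + row metadata) and
#' \code{cells.tsv} (cell id + cell metadata) into a directory;
#' \code{readCellMatrix} reconstructs the
#' \code{SingleCellExperiment} losslessly.
#'
#' @param cells a \code{SingleCellExperiment} with a counts assay.
#' @param dir target/source directory.
#' @return the directory (writer) or the reconstructed object (reader).
#' @export
writeCellMatrix <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- SummarizedExperiment::assay(cells, "counts")
  Matrix::writeMM(methods::as(cts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  rd <- as.data.frame(SummarizedExperiment::rowData(cells))
  writeTsv(cbind(gene = rownames(cells), rd),
           file.path(dir, "genes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(cells))
  writeTsv(cbind(cell = colnames(cells), cd),
           file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname writeCellMatrix
#' @export
readCellMatrix <- function(dir) {
  cts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
  genes <- readTsv(file.path(dir, "genes.tsv"))
  cellsMeta <- readTsv(file.path(dir, "cells.tsv"))
  dimnames(cts) <- list(genes$gene, cellsMeta$cell)
  rd <- genes[, setdiff(colnames(genes), "gene"), drop = FALSE]
  cd <- cellsMeta[, setdiff(colnames(cellsMeta), "cell"), drop = FALSE]
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cts),
    rowData = S4Vectors::DataFrame(rd, row.names = genes$gene),
    colData = S4Vectors::DataFrame(cd, row.names = cellsMeta$cell))
}

#' Tab-separated table I/O (UTF-8, single header row)
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{path} (writer) / data.frame (reader).
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Summary-track TSV I/O
#'
#' Fixed column order: variant, position, beta, se, p, maf, n,
#' case_fraction, trait_type.
#'
#' @param track a \linkS4class{SummaryTrack}.
#' @param path file path.
#' @return \code{path} (writer) / \code{SummaryTrack} (reader).
#' @export
writeSummaryTrack <- function(track, path) {
  writeTsv(data.frame(variant = track@variant,
                      position = track@position, beta = track@beta,
                      se = track@se, p = track@p, maf = track@maf,
                      n = track@n, case_fraction = track@caseFraction,
                      trait_type = track@traitType), path)
}

#' @rdname writeSummaryTrack
#' @export
readSummaryTrack <- function(path) {
  d <- readTsv(path)
  summaryTrack(d$variant, d$position, beta = d$beta, se = d$se,
               p = d$p, maf = d$maf, n = d$n,
               caseFraction = d$case_fraction[1],
               traitType = d$trait_type[1])
}

#' Write a YAML run manifest
#'
#' @param manifest named list (seeds, configs, checksums, versions).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRunManifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}
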