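# Readers and writers for the plain-text formats used around the pipeline.

#' Read a genotype panel from VCF
#'
#' Reads the GT field of a (plain-text or bgzipped) VCF and converts it to
#' alternate-allele dosages; any genotype containing a missing allele
#' becomes `NA`.
#'
#' @param path path to a VCF file.
#' @return a [GenotypePanel-class].
#' @export
readGenotypeVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  conv <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- matrix(unname(conv[gt]), nrow = nrow(gt),
                dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  map <- data.frame(snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  GenotypePanel(t(dos), map)
}

#' Write a genotype panel as VCF
#'
#' Writes an uncompressed VCFv4.2 file with a GT field; dosage 1 is written
#' as `0/1`, missing as `./.`.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(panel, path) {
  dos <- SummarizedExperiment::assay(panel, "dosage")  # SNP x genotype
  map <- snpInfo(panel)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- code[as.character(dos[ok])]
  header <- c("##fileformat=VCFv4.2",
              "##source=staygreenGT",
              sprintf("##contig=<ID=%s,length=%d>",
                      names(chromosomeLengths(panel)),
                      as.integer(chromosomeLengths(panel))),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(dos)), collapse = "\t"))
  body <- paste(map$chrom, as.integer(map$pos), map$snp_id, map$ref, map$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a genotype panel as dosage + map CSV
#'
#' The dosage CSV holds one row per genotype and one column per SNP (first
#' column `genotype`); the map CSV has columns `snp_id`, `chrom`, `pos` and
#' optionally `ref`, `alt`.
#'
#' @param dosagePath,mapPath CSV paths.
#' @return [GenotypePanel-class] for the reader; the paths, invisibly, for
#'   the writer.
#' @export
readDosageCsv <- function(dosagePath, mapPath) {
  d <- utils::read.csv(dosagePath, check.names = FALSE)
  map <- utils::read.csv(mapPath, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  GenotypePanel(m, map)
}

#' @rdname readDosageCsv
#' @param panel a [GenotypePanel-class].
#' @export
writeDosageCsv <- function(panel, dosagePath, mapPath) {
  d <- dosageMatrix(panel)
  utils::write.csv(data.frame(genotype = rownames(d), d,
                              check.names = FALSE),
                   dosagePath, row.names = FALSE)
  utils::write.csv(snpInfo(panel), mapPath, row.names = FALSE)
  invisible(c(dosagePath, mapPath))
}

#' Read / write a kinship matrix as CSV
#'
#' Square CSV with genotype ids as header and first column.
#'
#' @param path CSV path.
#' @return [KinshipMatrix-class] for the reader.
#' @export
readKinshipCsv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  methods::new("KinshipMatrix", mat = m,
               excludedChromosome = NA_character_, nSnpsUsed = NA_integer_)
}

#' @rdname readKinshipCsv
#' @param kinship a [KinshipMatrix-class].
#' @export
writeKinshipCsv <- function(kinship, path) {
  m <- as.matrix(kinship)
  utils::write.csv(data.frame(genotype = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
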