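#' Construct a GenotypePanel
#'
#' @param dosage genotype-by-SNP numeric matrix with entries 0/1/2 (count of
#'   the alternate allele) or `NA` for missing; rownames are genotype ids,
#'   colnames SNP ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp)
#'   and optionally `ref`, `alt`; one row per column of `dosage`, same order
#'   or matched by `snp_id`.
#' @param chromLengths optional named vector of chromosome lengths in bp
#'   (used to clip QTL intervals); defaults to the maximal observed position.
#' @return a [GenotypePanel-class] object (SNPs ordered by chromosome then
#'   position).
#' @examples
#' d <- matrix(c(0, 2, 2, 0, 0, 2), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' map <- data.frame(snp_id = c("s1", "s2"), chrom = "1A", pos = c(100, 200))
#' GenotypePanel(d, map)
#' @export
GenotypePanel <- function(dosage, map, chromLengths = NULL) {
  stopifnot(is.matrix(dosage), is.data.frame(map))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- map$snp_id
  map <- map[match(colnames(dosage), map$snp_id), , drop = FALSE]
  if (anyNA(map$snp_id))
    stop("every dosage column must have a row in 'map'")
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "B"
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  dosage <- dosage[, o, drop = FALSE]
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("G%03d", seq_len(nrow(dosage)))
  if (is.null(chromLengths)) {
    chromLengths <- tapply(map$pos, map$chrom, max)
    chromLengths <- stats::setNames(as.numeric(chromLengths),
                                    names(chromLengths))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosage)),
    rowData = S4Vectors::DataFrame(chrom = as.character(map$chrom),
                                   pos = as.numeric(map$pos),
                                   ref = as.character(map$ref),
                                   alt = as.character(map$alt),
                                   row.names = map$snp_id))
  obj <- methods::new("GenotypePanel", se)
  S4Vectors::metadata(obj)$chromLengths <- chromLengths
  obj
}

#' Accessors for GenotypePanel
#'
#' `dosageMatrix()` returns the genotype-by-SNP dosage matrix;
#' `snpInfo()` the physical map (`snp_id`, `chrom`, `pos`, `ref`, `alt`);
#' `maf()` the per-SNP minor-allele frequency computed on non-missing calls;
#' `missingRate()` the per-SNP missing-call proportion.
#'
#' @param x a [GenotypePanel-class].
#' @param ... unused.
#' @name GenotypePanel-accessors
NULL

#' @rdname GenotypePanel-accessors
#' @export
setMethod("dosageMatrix", "GenotypePanel", function(x, ...) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname GenotypePanel-accessors
#' @export
setMethod("snpInfo", "GenotypePanel", function(x, ...) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(snp_id = rownames(x), chrom = rd$chrom, pos = rd$pos,
             ref = rd$ref, alt = rd$alt, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' @rdname GenotypePanel-accessors
#' @export
setMethod("maf", "GenotypePanel", function(x, ...) {
  p <- rowMeans(SummarizedExperiment::assay(x, "dosage"), na.rm = TRUE) / 2
  stats::setNames(pmin(p, 1 - p), rownames(x))
})

#' @rdname GenotypePanel-accessors
#' @export
setMethod("missingRate", "GenotypePanel", function(x, ...) {
  stats::setNames(rowMeans(is.na(SummarizedExperiment::assay(x, "dosage"))),
                  rownames(x))
})

setMethod("show", "GenotypePanel", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("GenotypePanel:", ncol(object), "genotypes x", nrow(object), "SNPs on",
      length(unique(rd$chrom)), "chromosome(s)\n")
  mr <- mean(is.na(SummarizedExperiment::assay(object, "dosage")))
  cat(sprintf("  missing calls: %.2f%%; MAF range: %.3f-%.3f\n",
              100 * mr, min(maf(object)), max(maf(object))))
})

#' Chromosome lengths of a panel
#'
#' @param panel a [GenotypePanel-class].
#' @return named numeric vector of chromosome lengths (bp).
#' @export
chromosomeLengths <- function(panel) {
  S4Vectors::metadata(panel)$chromLengths
}

# ---- KinshipMatrix accessors -------------------------------------------

#' Accessors for KinshipMatrix
#'
#' @param x a [KinshipMatrix-class].
#' @param ... unused.
#' @name KinshipMatrix-accessors
NULL

#' @rdname KinshipMatrix-accessors
#' @export
setMethod("excludedChromosome", "KinshipMatrix",
          function(x, ...) x@excludedChromosome)

#' @rdname KinshipMatrix-accessors
#' @export
setMethod("nSnpsUsed", "KinshipMatrix", function(x, ...) x@nSnpsUsed)

#' @rdname KinshipMatrix-accessors
#' @param row.names,optional ignored (S3 compatibility).
#' @export
setMethod("as.matrix", "KinshipMatrix", function(x, ...) x@mat)

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix (VanRaden method 1):", nrow(object@mat), "genotypes,",
      object@nSnpsUsed, "SNPs")
  if (!is.na(object@excludedChromosome))
    cat(" (chromosome", object@excludedChromosome, "excluded)")
  cat("\n  mean diagonal:", round(mean(diag(object@mat)), 3), "\n")
})
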