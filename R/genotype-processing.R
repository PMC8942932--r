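# SNP quality control, frequency imputation, LD, r2-cluster pruning and
# VanRaden kinship (full and leave-one-chromosome-out).

#' SNP quality control
#'
#' In the stated order: heterozygous calls are recoded to missing (the
#' panel is inbred, dosage-1 calls are errors); SNPs with missingness above
#' `maxMissing` are discarded; SNPs with minor-allele frequency (computed
#' on the remaining non-missing calls) below `minMaf` are discarded.  The
#' MAF threshold is exclusive: MAF exactly `minMaf` is retained.
#'
#' @param panel a [GenotypePanel-class].
#' @param maxMissing maximal per-SNP missing proportion (default 0.10).
#' @param minMaf minimal minor-allele frequency (default 0.05).
#' @return the filtered [GenotypePanel-class].
#' @export
qcFilter <- function(panel, maxMissing = 0.10, minMaf = 0.05) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  d[d == 1] <- NA
  miss <- rowMeans(is.na(d))
  p <- rowMeans(d, na.rm = TRUE) / 2
  mafv <- pmin(p, 1 - p)
  mafv[is.nan(mafv)] <- 0
  keep <- miss <= maxMissing & mafv >= minMaf
  if (!any(keep))
    stop("no SNP passes quality control (empty panel)")
  out <- panel[keep, ]
  SummarizedExperiment::assay(out, "dosage") <- d[keep, , drop = FALSE]
  out
}

#' Binomial frequency imputation
#'
#' Each missing call is replaced by a draw from Binomial(2, p) with p the
#' SNP's non-missing alternate-allele frequency.  A stand-in for
#' phasing-based imputation: kinship and single-SNP tests are insensitive
#' to phase.
#'
#' @param panel a post-QC [GenotypePanel-class].
#' @param seed RNG seed (imputation is deterministic given the seed).
#' @return the panel without missing calls.
#' @export
imputeMissing <- function(panel, seed = 1L) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (!anyNA(d)) return(panel)
  p <- rowMeans(d, na.rm = TRUE) / 2
  idx <- which(is.na(d), arr.ind = TRUE)
  withr::with_seed(.subSeed(seed, 4L), {
    d[idx] <- stats::rbinom(nrow(idx), 2L, p[idx[, 1]])
  })
  SummarizedExperiment::assay(panel, "dosage") <- d
  panel
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two SNPs' dosage vectors.
#'
#' @param panel an imputed [GenotypePanel-class].
#' @param snpI,snpJ SNP ids or column indices.
#' @return r2 in [0, 1].
#' @export
ldR2 <- function(panel, snpI, snpJ) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  xi <- d[snpI, ]
  xj <- d[snpJ, ]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0)
    stop("r2 is undefined for a zero-variance SNP")
  stats::cor(xi, xj)^2
}

# r2 matrix for a set of SNP rows (imputed); zero-variance columns give NA
.ldMatrix <- function(d) {
  suppressWarnings(stats::cor(t(d))^2)
}

#' Prune SNPs by r2 clustering
#'
#' Per chromosome, average-linkage hierarchical clustering on the distance
#' 1 - r2; the tree is cut at height `cutHeight` (default 0.1) and one SNP
#' per cluster is kept, chosen by a seeded uniform draw.  SNPs are
#' processed in map order, so the retained set does not depend on the
#' panel's input column order.
#'
#' @param panel an imputed [GenotypePanel-class].
#' @param cutHeight dendrogram cut height on the 1 - r2 scale.
#' @param seed RNG seed for the within-cluster choice.
#' @return the pruned [GenotypePanel-class].
#' @export
pruneByLD <- function(panel, cutHeight = 0.1, seed = 1L) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (anyNA(d)) stop("prune requires an imputed panel")
  chrom <- SummarizedExperiment::rowData(panel)$chrom
  keep <- logical(nrow(d))
  withr::with_seed(.subSeed(seed, 5L), {
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      if (length(idx) == 1L) { keep[idx] <- TRUE; next }
      r2 <- .ldMatrix(d[idx, , drop = FALSE])
      r2[is.na(r2)] <- 0
      diag(r2) <- 1
      cl <- stats::cutree(stats::hclust(stats::as.dist(1 - r2),
                                        method = "average"),
                          h = cutHeight)
      for (k in unique(cl)) {
        members <- idx[cl == k]
        keep[members[sample.int(length(members), 1L)]] <- TRUE
      }
    }
  })
  panel[keep, ]
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' K = Z Z' / (2 sum p (1 - p)) with Z the dosage matrix column-centred by
#' twice the allele frequency.
#'
#' @param panel an imputed (ideally pruned) [GenotypePanel-class].
#' @param excludeChromosome optional chromosome label(s) to leave out.
#' @return a [KinshipMatrix-class].
#' @export
vanRadenKinship <- function(panel, excludeChromosome = NULL) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (anyNA(d)) stop("kinship requires an imputed panel")
  chrom <- SummarizedExperiment::rowData(panel)$chrom
  if (!is.null(excludeChromosome) && length(excludeChromosome)) {
    if (!all(excludeChromosome %in% chrom))
      stop("unknown chromosome label: ",
           paste(setdiff(excludeChromosome, chrom), collapse = ", "))
    d <- d[!(chrom %in% excludeChromosome), , drop = FALSE]
  }
  if (nrow(d) < 2) stop("at least 2 SNPs are required for kinship")
  p <- rowMeans(d) / 2
  Z <- t(d - 2 * p)                      # genotype x SNP, centred
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("kinship denominator is zero (monomorphic panel)")
  K <- tcrossprod(Z) / denom
  methods::new("KinshipMatrix", mat = K,
               excludedChromosome = if (is.null(excludeChromosome))
                 NA_character_ else as.character(excludeChromosome[1]),
               nSnpsUsed = nrow(d))
}

#' Leave-one-chromosome-out kinship
#'
#' Kinship computed with all SNPs not on the tested chromosome, avoiding
#' proximal contamination in the association scan.
#'
#' @param panel an imputed [GenotypePanel-class] with >= 2 chromosomes.
#' @param chromosome label of the chromosome to exclude.
#' @return a [KinshipMatrix-class] with `excludedChromosome` recorded.
#' @export
locoKinship <- function(panel, chromosome) {
  chrom <- unique(SummarizedExperiment::rowData(panel)$chrom)
  if (length(chrom) < 2)
    stop("leave-one-chromosome-out kinship needs >= 2 chromosomes")
  vanRadenKinship(panel, excludeChromosome = chromosome)
}
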