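#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' GenotypePanel: biallelic dosage matrix with a physical map
#'
#' Container for a biallelic SNP panel: a SNP-by-genotype dosage assay
#' (`"dosage"`, entries 0/1/2 counting the alternate allele, `NA` for
#' missing) plus a physical map in `rowData` (`chrom` using the wheat
#' 1A..7D convention, `pos` in 1-based bp, `ref`, `alt`).  Extends
#' [SummarizedExperiment::SummarizedExperiment] so standard subsetting,
#' `rowData()` and `assay()` work; use [dosageMatrix()] for the
#' genotype-by-SNP orientation used by the statistical functions.
#'
#' Positions must be strictly increasing within each chromosome.
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    return("rowData must contain 'chrom' and 'pos'")
  pos <- split(rd$pos, rd$chrom)
  if (!all(vapply(pos, function(p) all(diff(p) > 0), logical(1))))
    msg <- c(msg, "positions must be strictly increasing within chromosome")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "genotype (column) names must be unique")
  if (length(msg)) msg else TRUE
})

#' KinshipMatrix: genomic relationship matrix
#'
#' Symmetric positive semidefinite genotype-by-genotype relationship matrix
#' (VanRaden method 1), optionally computed leaving one chromosome out.
#'
#' @slot mat numeric matrix, genotypes in rows and columns.
#' @slot excludedChromosome chromosome label excluded from the SNP set
#'   (`NA_character_` for a full-genome matrix).
#' @slot nSnpsUsed number of SNPs entering the cross-product.
#' @export
setClass("KinshipMatrix",
  representation(mat = "matrix",
                 excludedChromosome = "character",
                 nSnpsUsed = "integer"))

setValidity("KinshipMatrix", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m))))
    return("matrix must be symmetric")
  TRUE
})

#' LogisticFit: per-plant logistic senescence fit
#'
#' Result of fitting `CHL(t) = D + K / (1 + a * exp(r * t))` to one plant's
#' chlorophyll kinetics: `D` is the final CHL of the dead leaf, `K` the
#' amplitude between maximal and final CHL, and `a`, `r` control timing and
#' rate of the decline.  Fitting is a two-pass nonlinear least squares
#' (outliers flagged on first-pass residuals, refit without them).
#'
#' @slot plantId plant identifier.
#' @slot D,K,a,r fitted parameters (`K > 0`, `r > 0`).
#' @slot pseudoR2 Efron pseudo-R-squared of the second pass.
#' @slot nUsed observations used in the second pass.
#' @slot outlierIndices indices (into the input curve) flagged as outliers.
#' @slot converged `FALSE` when the optimiser failed; other slots are `NA`.
#' @slot t,chl the data the fit was run on (pseudo-point included if added).
#' @export
setClass("LogisticFit",
  representation(plantId = "character", D = "numeric", K = "numeric",
                 a = "numeric", r = "numeric", pseudoR2 = "numeric",
                 nUsed = "integer", outlierIndices = "integer",
                 converged = "logical", t = "numeric", chl = "numeric"))

#' SplitPlotFit: REML fit of the split-plot mixed model
#'
#' REML solution of the single-year or multi-year split-plot model with
#' kinship-structured genotype, genotype-by-treatment (and, multi-year,
#' genotype-by-year) random effects, an i.i.d. sub-block effect and an
#' i.i.d. residual.
#'
#' @slot components named variance components
#'   (`subblock`, `g`, `gt`, `gy`, `residual`; absent terms dropped).
#' @slot logLik restricted log-likelihood at convergence.
#' @slot fixef,fixefCov fixed-effect estimates and their covariance.
#' @slot blupG per-genotype polygenic BLUPs.
#' @slot blupGT genotype-by-treatment BLUP matrix (columns NS, S).
#' @slot blupGY genotype-by-year BLUP matrix (0 columns when single-year).
#' @slot treatmentMeans estimated fixed-part mean per treatment (used by
#'   [gblupByTreatment()]).
#' @slot designInfo list with counts `t` (treatments), `a` (years),
#'   `n` (replicates), `g` (genotypes).
#' @slot converged,niter optimiser status.
#' @export
setClass("SplitPlotFit",
  representation(components = "numeric", logLik = "numeric",
                 fixef = "numeric", fixefCov = "matrix",
                 blupG = "numeric", blupGT = "matrix", blupGY = "matrix",
                 treatmentMeans = "numeric", designInfo = "list",
                 converged = "logical", niter = "integer"))

#' GwasResult: per-SNP main and interaction association scan
#'
#' Per-SNP Wald tests of the SNP main effect (allelic effect in the
#' non-stress treatment) and the SNP-by-treatment interaction, from the
#' split-plot GWAS model with leave-one-chromosome-out kinship.
#'
#' @slot table data.frame with one row per tested SNP (see [gwasTable()]).
#' @slot mode `"p3d"` (variance components fixed per chromosome) or
#'   `"full"` (re-estimated per SNP).
#' @slot nObs number of phenotype records used.
#' @export
setClass("GwasResult",
  representation(table = "data.frame", mode = "character", nObs = "integer"))
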