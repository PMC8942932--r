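# Per-SNP association scan: SNP main effect and SNP-by-treatment
# interaction Wald tests under the split-plot GWAS model with
# leave-one-chromosome-out kinship, an effective-test-count significance
# threshold, and the interaction-variance-explained statistic.

#' Association scan configuration
#'
#' @param mode `"p3d"`: variance components are estimated once per
#'   chromosome under the no-SNP model and held fixed while each SNP's
#'   effects are estimated by generalised least squares (the scan default);
#'   `"full"`: variance components are re-estimated per SNP.
#' @param alpha significance level for [gaoThreshold()].
#' @param meffEigenFraction eigenvalue fraction of the effective-test-count
#'   rule.
#' @param pruneForKinship prune the panel by LD before computing kinship
#'   (as done for the relationship matrix of the study).
#' @param pruneCutHeight,pruneSeed pruning settings, see [pruneByLD()].
#' @return a list of class `ScanConfig`.
#' @export
scanConfig <- function(mode = c("p3d", "full"), alpha = 0.05,
                       meffEigenFraction = 0.995, pruneForKinship = TRUE,
                       pruneCutHeight = 0.1, pruneSeed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(mode = mode, alpha = alpha,
                 meffEigenFraction = meffEigenFraction,
                 pruneForKinship = pruneForKinship,
                 pruneCutHeight = pruneCutHeight,
                 pruneSeed = pruneSeed),
            class = "ScanConfig")
}

#' Run the SNP main-effect and SNP-by-treatment GWAS
#'
#' For each SNP, the split-plot model gains two fixed effects: the allelic
#' dosage (so the main estimate is the effect of the counted allele in the
#' non-stress treatment) and dosage x indicator(S) (the SNP-by-treatment
#' interaction; the allelic effect in S is their sum).  Each SNP is tested
#' with a kinship matrix computed from all chromosomes except its own.
#' Both terms get 1-df Wald chi-square tests; p-values are floored at
#' 1e-300.
#'
#' @param records phenotype records as in [fitSplitPlot()].
#' @param panel a QC'd, imputed [GenotypePanel-class].
#' @param config a [scanConfig()].
#' @return a [GwasResult-class]; monomorphic SNPs are reported with `NA`
#'   statistics and a `skipReason`.
#' @export
runScan <- function(records, panel, config = scanConfig()) {
  rec <- as.data.frame(records)
  if (!"year" %in% names(rec)) rec$year <- "Y1"
  rec$treatment <- .treatmentFactor(rec$treatment)
  if (nlevels(droplevels(rec$treatment)) < 2)
    stop("phenotypes must cover both treatments")
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (anyNA(d)) stop("the scan requires an imputed panel")
  map <- snpInfo(panel)
  genos <- colnames(panel)
  if (!all(rec$genotype %in% genos))
    stop("panel does not cover all genotypes in the records")

  kinPanel <- if (config$pruneForKinship)
    pruneByLD(panel, cutHeight = config$pruneCutHeight,
              seed = config$pruneSeed) else panel
  multiYear <- length(unique(rec$year)) > 1L
  gi <- match(rec$genotype, genos)
  isS <- as.numeric(rec$treatment == "S")
  pAlt <- rowMeans(d) / 2

  chroms <- unique(map$chrom)
  out <- vector("list", length(chroms))
  init <- NULL
  for (ci in seq_along(chroms)) {
    cc <- chroms[ci]
    Kc <- locoKinship(kinPanel, cc)
    null <- fitSplitPlot(rec, Kc, multiYear = multiYear, init = init)
    init <- unname(varianceComponents(null))   # warm start next chromosome
    snps <- which(map$chrom == cc)
    mono <- apply(d[snps, , drop = FALSE], 1L, stats::sd) == 0
    res <- data.frame(snp_id = map$snp_id[snps], chrom = cc,
                      pos = map$pos[snps], freq = pAlt[snps],
                      effectNS = NA_real_, effectNS_se = NA_real_,
                      effectInt = NA_real_, effectInt_se = NA_real_,
                      effectS = NA_real_,
                      waldMain = NA_real_, waldInt = NA_real_,
                      lodMain = NA_real_, lodInt = NA_real_,
                      nUsed = nrow(rec),
                      skipReason = NA_character_,
                      stringsAsFactors = FALSE)
    res$skipReason[mono] <- "monomorphic"
    use <- which(!mono)
    if (length(use)) {
      if (config$mode == "p3d") {
        res[use, ] <- .scanGls(res[use, , drop = FALSE], rec, d, snps[use],
                               gi, isS, null, Kc, multiYear)
      } else {
        res[use, ] <- .scanFullRefit(res[use, , drop = FALSE], rec, d,
                                     snps[use], gi, isS, Kc, multiYear,
                                     init)
      }
    }
    out[[ci]] <- res
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$chrom, tab$pos), ]
  rownames(tab) <- NULL
  methods::new("GwasResult", table = tab, mode = config$mode,
               nObs = nrow(rec))
}

# P3D: rebuild V at the null components, whiten once, then per-SNP GLS via
# Frisch-Waugh residualisation; coefficient covariance is (X*' V^-1 X*)^-1
# (no residual rescaling: the components are part of V).
.scanGls <- function(res, rec, d, snpCols, gi, isS, null, Kc, multiYear) {
  comp <- varianceComponents(null)
  Ml <- .splitPlotKernels(rec, as.matrix(Kc), rownames(as.matrix(Kc)),
                          multiYear,
                          dropSubblock = !("subblock" %in% names(comp)))
  n <- nrow(rec)
  V <- diag(rep(comp[["residual"]], n))
  for (nm in names(Ml)) V <- V + comp[[nm]] * Ml[[nm]]
  R <- chol(V)
  X <- .splitPlotX(rec, multiYear)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  yt <- backsolve(R, rec$value, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  qX <- qr(Xt)
  S <- t(d[snpCols, , drop = FALSE])[gi, , drop = FALSE]  # n x m dosages
  St <- backsolve(R, S, transpose = TRUE)
  Zt <- backsolve(R, S * isS, transpose = TRUE)
  rY <- stats::setNames(qr.resid(qX, yt), NULL)
  U <- qr.resid(qX, St)
  W <- qr.resid(qX, Zt)
  a11 <- colSums(U * U)
  a12 <- colSums(U * W)
  a22 <- colSums(W * W)
  b1 <- as.numeric(crossprod(U, rY))
  b2 <- as.numeric(crossprod(W, rY))
  det <- a11 * a22 - a12^2
  ok <- is.finite(det) & det > 1e-10 * pmax(a11 * a22, 1e-300)
  bMain <- (a22 * b1 - a12 * b2) / det
  bInt <- (a11 * b2 - a12 * b1) / det
  vMain <- a22 / det
  vInt <- a11 / det
  res$effectNS <- ifelse(ok, bMain, NA_real_)
  res$effectNS_se <- ifelse(ok, sqrt(vMain), NA_real_)
  res$effectInt <- ifelse(ok, bInt, NA_real_)
  res$effectInt_se <- ifelse(ok, sqrt(vInt), NA_real_)
  res$effectS <- res$effectNS + res$effectInt
  res$waldMain <- ifelse(ok, bMain^2 / vMain, NA_real_)
  res$waldInt <- ifelse(ok, bInt^2 / vInt, NA_real_)
  res$lodMain <- .waldLod(res$waldMain)
  res$lodInt <- .waldLod(res$waldInt)
  res$skipReason[!ok] <- "collinear with fixed effects"
  res
}

.scanFullRefit <- function(res, rec, d, snpCols, gi, isS, Kc, multiYear,
                           init) {
  for (j in seq_along(snpCols)) {
    x <- d[snpCols[j], ][gi]
    ef <- cbind(snp = x, snpS = x * isS)
    fit <- fitSplitPlot(rec, Kc, multiYear = multiYear, extraFixed = ef,
                        init = init)
    cf <- fixedEffects(fit)
    i1 <- match("snp", names(cf))
    i2 <- match("snpS", names(cf))
    if (is.na(i1) || is.na(i2)) {
      res$skipReason[j] <- "collinear with fixed effects"
      next
    }
    se <- sqrt(diag(fit@fixefCov))
    res$effectNS[j] <- cf[i1]
    res$effectNS_se[j] <- se[i1]
    res$effectInt[j] <- cf[i2]
    res$effectInt_se[j] <- se[i2]
    res$effectS[j] <- cf[i1] + cf[i2]
    res$waldMain[j] <- (cf[i1] / se[i1])^2
    res$waldInt[j] <- (cf[i2] / se[i2])^2
  }
  res$lodMain <- .waldLod(res$waldMain)
  res$lodInt <- .waldLod(res$waldInt)
  res
}

.waldLod <- function(w) {
  p <- pmax(stats::pchisq(w, df = 1, lower.tail = FALSE), 1e-300)
  -log10(p)
}

#' Accessors for GwasResult
#'
#' @param object a [GwasResult-class].
#' @param ... unused.
#' @name GwasResult-accessors
NULL

#' @rdname GwasResult-accessors
#' @export
setMethod("gwasTable", "GwasResult", function(object, ...) object@table)

setMethod("show", "GwasResult", function(object) {
  tab <- object@table
  cat("GwasResult (", object@mode, " mode): ", nrow(tab), " SNPs, ",
      object@nObs, " records\n", sep = "")
  best <- tab[order(-pmax(tab$lodMain, tab$lodInt, na.rm = TRUE)), ]
  print(utils::head(best[, c("snp_id", "chrom", "pos", "lodMain", "lodInt")],
                    5L), row.names = FALSE)
})

#' Effective-test-count significance threshold
#'
#' Per chromosome, the SNP correlation matrix is eigendecomposed and the
#' effective number of tests is the smallest count of leading eigenvalues
#' whose sum reaches `eigenFraction` of the total; the genome-wide
#' threshold is `-log10(alpha / sum_c Meff_c)` (the simpleM reading of the
#' effective-test-count correction).
#'
#' @param panel an imputed [GenotypePanel-class].
#' @param alpha significance level.
#' @param eigenFraction eigenvalue fraction (default 0.995).
#' @return the -log10(p) threshold, with attribute `"meff"` (per
#'   chromosome).
#' @export
gaoThreshold <- function(panel, alpha = 0.05, eigenFraction = 0.995) {
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (anyNA(d)) stop("the threshold requires an imputed panel")
  chrom <- SummarizedExperiment::rowData(panel)$chrom
  meff <- vapply(unique(chrom), function(cc) {
    dc <- d[chrom == cc, , drop = FALSE]
    sdv <- apply(dc, 1L, stats::sd)
    dc <- dc[sdv > 0, , drop = FALSE]
    m <- nrow(dc)
    if (m <= 1L) return(max(m, 1L))
    ev <- eigen(stats::cor(t(dc)), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    as.integer(which(cumsum(ev) >= eigenFraction * sum(ev))[1])
  }, numeric(1))
  thr <- -log10(alpha / sum(meff))
  attr(thr, "meff") <- meff
  thr
}

#' Variance of the interaction BLUPs explained by a SNP
#'
#' Coefficient of determination of the simple linear regression of the
#' genotype-by-treatment coefficients on the fitted SNP-by-treatment
#' effects -- the share of the panel's differential stress response
#' captured by one SNP.
#'
#' @param gxtBlups genotype-by-treatment coefficients (one per genotype x
#'   treatment cell).
#' @param snpInteractionEffects fitted SNP-by-treatment values for the same
#'   cells (e.g. `effectInt * dosage * indicator(S)`).
#' @return R-squared in [0, 1].
#' @export
interactionVarianceExplained <- function(gxtBlups, snpInteractionEffects) {
  stopifnot(length(gxtBlups) == length(snpInteractionEffects))
  if (stats::sd(snpInteractionEffects) == 0)
    stop("R2 undefined: zero-variance SNP interaction effects")
  fit <- stats::lm(gxtBlups ~ snpInteractionEffects)
  1 - sum(stats::residuals(fit)^2) /
    sum((gxtBlups - mean(gxtBlups))^2)
}
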