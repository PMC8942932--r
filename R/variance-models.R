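# Split-plot mixed models with kinship covariance: REML estimation,
# heritability, gBLUP by treatment, stress index, likelihood-ratio tests.

# Build the n x n covariance kernels for the random terms.
.splitPlotKernels <- function(rec, K, genos, multiYear, dropSubblock) {
  gi <- match(rec$genotype, genos)
  Mg <- K[gi, gi]
  sameT <- outer(rec$treatment, rec$treatment, "==")
  Ml <- list(g = Mg, gt = Mg * sameT)
  if (multiYear) {
    sameY <- outer(rec$year, rec$year, "==")
    Ml$gy <- Mg * sameY
  }
  if (!dropSubblock) {
    sb <- interaction(rec$year, rec$replicate, rec$treatment, rec$subblock,
                      drop = TRUE)
    Ml <- c(list(subblock = outer(sb, sb, "==") * 1), Ml)
  }
  Ml
}

.splitPlotX <- function(rec, multiYear) {
  if (multiYear) {
    stats::model.matrix(~ year + treatment + year:treatment +
                          year:replicate + year:replicate:treatment,
                        data = rec)
  } else {
    stats::model.matrix(~ replicate + treatment + replicate:treatment,
                        data = rec)
  }
}

#' Fit the split-plot mixed model by REML
#'
#' Single-year model: fixed replicate, treatment and treatment-by-replicate
#' effects; random sub-block (i.i.d.), genotype (covariance sigma2_g K),
#' genotype-by-treatment (independent K-structured deviations per
#' treatment, the Hadamard K o I structure) and i.i.d. residual.  The
#' multi-year model adds fixed year, year-by-treatment and
#' replicate-within-year terms and a genotype-by-year random effect
#' (K o I over years); part of the three-way genotype x treatment x year
#' interaction is then confounded with the residual, which is reproduced
#' as-is.  Estimation is average-information REML with EM fallback steps
#' and non-negativity floors.
#'
#' @param records data.frame with columns `genotype`, `year`, `treatment`
#'   (NS/S), `replicate`, `subblock`, `value` (a `year` column may be
#'   omitted for a single-year fit).
#' @param kinship a [KinshipMatrix-class] covering all genotypes.
#' @param multiYear fit the multi-year model; default: autodetect from the
#'   number of year levels.
#' @param dropSubblock omit the sub-block random term; default: autodetect
#'   (dropped when there is at most one sub-block per whole plot, where the
#'   term is confounded with fixed effects).
#' @param components optional named variance components to hold fixed (the
#'   P3D mode of the association scan); when supplied no optimisation is
#'   done.
#' @param init optional starting values.
#' @param extraFixed optional numeric matrix of additional fixed-effect
#'   columns (e.g. SNP dosage and dosage-by-treatment), `nrow(records)`
#'   rows; estimates are reported at the end of the coefficient vector.
#' @param maxit,tolLl REML iteration controls.
#' @return a [SplitPlotFit-class].
#' @export
fitSplitPlot <- function(records, kinship, multiYear = NULL,
                         dropSubblock = NULL, components = NULL, init = NULL,
                         extraFixed = NULL, maxit = 60L, tolLl = 1e-9) {
  rec <- as.data.frame(records)
  if (!"year" %in% names(rec)) rec$year <- "Y1"
  need <- c("genotype", "year", "treatment", "replicate", "subblock", "value")
  if (!"subblock" %in% names(rec)) rec$subblock <- 1L
  stopifnot(all(need %in% names(rec)))
  rec$treatment <- .treatmentFactor(rec$treatment)
  rec$year <- factor(rec$year)
  rec$replicate <- factor(rec$replicate)
  K <- as.matrix(kinship)
  genos <- rownames(K)
  if (is.null(genos)) {
    genos <- sort(unique(rec$genotype))
    if (length(genos) != nrow(K))
      stop("kinship has no rownames and its size does not match the data")
    rownames(K) <- colnames(K) <- genos
  }
  if (!all(rec$genotype %in% genos))
    stop("kinship does not cover all genotypes in the records")
  if (is.null(multiYear)) multiYear <- nlevels(rec$year) > 1L
  wp <- interaction(rec$year, rec$replicate, rec$treatment, drop = TRUE)
  sbPerWp <- tapply(rec$subblock, wp, function(x) length(unique(x)))
  if (is.null(dropSubblock)) dropSubblock <- all(sbPerWp <= 1L)

  X <- .splitPlotX(rec, multiYear)
  if (!is.null(extraFixed)) {
    extraFixed <- as.matrix(extraFixed)
    if (is.null(colnames(extraFixed)))
      colnames(extraFixed) <- paste0("extra", seq_len(ncol(extraFixed)))
    X <- cbind(X, extraFixed)
  }
  Ml <- .splitPlotKernels(rec, K, genos, multiYear, dropSubblock)
  y <- rec$value

  fixedTheta <- NULL
  if (!is.null(components)) {
    fixedTheta <- c(components[names(Ml)], components["residual"])
    if (anyNA(fixedTheta))
      stop("'components' must name ", paste(names(Ml), collapse = ", "),
           " and residual")
  }
  fit <- .aiReml(y, X, Ml, init = init, fixedTheta = unname(fixedTheta),
                 maxit = maxit, tolLl = tolLl)

  comp <- stats::setNames(fit$theta, c(names(Ml), "residual"))
  beta <- stats::setNames(fit$beta, colnames(fit$X))

  # BLUPs: u_hat_i = theta_i K Z_i' P y
  gi <- match(rec$genotype, genos)
  g <- length(genos)
  sumBy <- function(sel) {
    z <- numeric(g)
    tab <- rowsum(fit$Py[sel], gi[sel])
    z[as.integer(rownames(tab))] <- tab
    z
  }
  blupG <- comp["g"] * as.numeric(K %*% sumBy(TRUE))
  trts <- levels(rec$treatment)
  blupGT <- vapply(trts, function(k)
    comp["gt"] * as.numeric(K %*% sumBy(rec$treatment == k)), numeric(g))
  dimnames(blupGT) <- list(genos, trts)
  if (multiYear) {
    yrs <- levels(rec$year)
    blupGY <- vapply(yrs, function(a)
      comp["gy"] * as.numeric(K %*% sumBy(rec$year == a)), numeric(g))
    dimnames(blupGY) <- list(genos, yrs)
  } else {
    blupGY <- matrix(numeric(0), g, 0, dimnames = list(genos, NULL))
  }
  fitted <- as.numeric(fit$X %*% fit$beta)
  trtMeans <- vapply(trts, function(k) mean(fitted[rec$treatment == k]),
                     numeric(1))
  methods::new("SplitPlotFit",
               components = comp, logLik = fit$ll, fixef = beta,
               fixefCov = fit$betaCov, blupG = stats::setNames(blupG, genos),
               blupGT = blupGT, blupGY = blupGY,
               treatmentMeans = trtMeans,
               designInfo = list(t = nlevels(rec$treatment),
                                 a = nlevels(rec$year),
                                 n = nlevels(rec$replicate), g = g,
                                 nObs = nrow(rec), multiYear = multiYear),
               converged = fit$converged, niter = fit$niter)
}

#' Accessors for SplitPlotFit
#'
#' @param object a [SplitPlotFit-class].
#' @param ... unused.
#' @name SplitPlotFit-accessors
NULL

#' @rdname SplitPlotFit-accessors
#' @export
setMethod("varianceComponents", "SplitPlotFit",
          function(object, ...) object@components)

#' @rdname SplitPlotFit-accessors
#' @export
setMethod("fixedEffects", "SplitPlotFit", function(object, ...) object@fixef)

#' @rdname SplitPlotFit-accessors
#' @export
setMethod("blups", "SplitPlotFit", function(object, ...)
  list(g = object@blupG, gt = object@blupGT, gy = object@blupGY))

#' @rdname SplitPlotFit-accessors
#' @export
setMethod("logLik", "SplitPlotFit", function(object, ...) object@logLik)

setMethod("show", "SplitPlotFit", function(object) {
  cat("SplitPlotFit (", if (object@designInfo$multiYear) "multi-year"
      else "single-year", " model, REML)\n", sep = "")
  print(round(object@components, 4))
  cat("logLik:", round(object@logLik, 3),
      if (!object@converged) " [NOT converged]", "\n")
})

#' Broad-sense heritability of the split-plot design
#'
#' Single-year: `H2 = s2_g / (s2_g + s2_gt / t + s2_e / (t n))`.
#' Multi-year (`a` years): `H2 = s2_g / (s2_g + s2_gt / t + s2_gy / a +
#' s2_e / (a t n))`.  The two coincide when `a = 1` and `s2_gy = 0`.
#'
#' @param components named numeric (or [SplitPlotFit-class]) with entries
#'   `g`, `gt`, `residual` and, multi-year, `gy`.
#' @param t number of treatments.
#' @param n number of replicates.
#' @param a number of years (`NULL` for the single-year formula).
#' @return heritability in [0, 1] for non-negative components.
#' @export
heritability <- function(components, t, n, a = NULL) {
  if (methods::is(components, "SplitPlotFit"))
    components <- varianceComponents(components)
  vg <- components[["g"]]
  vgt <- components[["gt"]]
  ve <- components[["residual"]]
  if (is.null(a)) {
    den <- vg + vgt / t + ve / (t * n)
  } else {
    vgy <- components[["gy"]]
    den <- vg + vgt / t + vgy / a + ve / (a * t * n)
  }
  if (den == 0) stop("heritability is undefined: zero denominator")
  vg / den
}

#' Genomic BLUP per genotype and treatment
#'
#' `GGT_ik = mu_k + G_i + (G x T)_ik`, where `mu_k` is the estimated
#' fixed-part mean of treatment `k` (the intercept plus the treatment and
#' averaged design effects, so that the fixed stress impact is carried by
#' the gBLUP table).
#'
#' @param fit a [SplitPlotFit-class].
#' @return data.frame with columns `genotype`, `treatment`, `ggt`.
#' @export
gblupByTreatment <- function(fit) {
  stopifnot(methods::is(fit, "SplitPlotFit"))
  trts <- colnames(fit@blupGT)
  genos <- names(fit@blupG)
  do.call(rbind, lapply(trts, function(k) {
    data.frame(genotype = genos, treatment = k,
               ggt = fit@treatmentMeans[[k]] + fit@blupG + fit@blupGT[, k],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Stress index
#'
#' `SI = 100 (mean_NS - mean_S) / mean_NS`: the percent loss of the trait's
#' gBLUP under stress relative to non-stress (positive = loss under
#' stress, the orientation of the study's reported indices).
#'
#' @param ggt gBLUP table from [gblupByTreatment()].
#' @param level `"panel"` (one index from treatment means) or `"genotype"`
#'   (one index per genotype).
#' @return numeric value, or named vector at genotype level.
#' @export
stressIndex <- function(ggt, level = c("panel", "genotype")) {
  level <- match.arg(level)
  trt <- .treatmentFactor(ggt$treatment)
  si <- function(ns, s) {
    if (mean(ns) == 0) stop("stress index undefined: zero NS mean")
    100 * (mean(ns) - mean(s)) / mean(ns)
  }
  if (level == "panel")
    return(si(ggt$ggt[trt == "NS"], ggt$ggt[trt == "S"]))
  ns <- ggt[trt == "NS", ]
  s <- ggt[trt == "S", ]
  s <- s[match(ns$genotype, s$genotype), ]
  stats::setNames(vapply(seq_len(nrow(ns)), function(i)
    si(ns$ggt[i], s$ggt[i]), numeric(1)), ns$genotype)
}

#' Likelihood-ratio test of a random component
#'
#' `LRT = 2 (Lmax_full - Lmax_reduced)`, floored at 0; the p-value uses the
#' boundary mixture `0.5 chi2_0 + 0.5 chi2_1` by default (a variance tested
#' on the boundary of its parameter space), or a plain chi2_1 with
#' `mixture = FALSE`.
#'
#' @param fullLogLik,reducedLogLik restricted log-likelihoods (numeric or
#'   [SplitPlotFit-class]; the reduced model must be nested in the full).
#' @param mixture use the boundary mixture null distribution.
#' @param tol tolerance for declaring non-nesting.
#' @return list with `statistic` and `p`.
#' @export
lrtRandom <- function(fullLogLik, reducedLogLik, mixture = TRUE,
                      tol = 1e-4) {
  ll <- function(x) if (methods::is(x, "SplitPlotFit")) x@logLik else x
  lf <- ll(fullLogLik)
  lr <- ll(reducedLogLik)
  if (lr > lf + tol)
    stop("reduced log-likelihood exceeds the full one: models not nested")
  stat <- max(0, 2 * (lf - lr))
  p1 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p <- if (mixture) 0.5 * p1 else p1
  if (!mixture && stat == 0) p <- 1
  list(statistic = stat, p = p)
}
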