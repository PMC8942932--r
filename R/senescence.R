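# Logistic senescence modelling: pseudo-point augmentation, two-pass
# nonlinear least squares, quantile-based outlier flagging, Efron
# pseudo-R2 and closed-form stay-green traits.

# the logistic decline; parameterised on log(a) for numerical stability
.logisticChl <- function(t, D, K, la, r) D + K / (1 + exp(la + r * t))

#' Append the dead-plant pseudo observation
#'
#' Adds one observation at 200 degree-days after the last measurement with
#' the CHL value of a fully senesced plant, anchoring the lower asymptote
#' of the logistic fit.
#'
#' @param t,chl thermal time (degree-days, strictly increasing) and CHL
#'   (ug cm-3) vectors of one plant.
#' @param deadChl CHL of the fully senesced plant (default 5 ug cm-3, the
#'   panel-level final value; the constant is configurable because the
#'   study does not state it).
#' @param gap distance after the last measurement (degree-days).
#' @return list with the augmented `t` and `chl`.
#' @export
addPseudoPoint <- function(t, chl, deadChl = 5, gap = 200) {
  stopifnot(length(t) == length(chl), all(diff(t) > 0))
  list(t = c(t, t[length(t)] + gap), chl = c(chl, deadChl))
}

#' Efron pseudo-R-squared
#'
#' `1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)`.
#'
#' @param observed,fitted equal-length numeric vectors (>= 2 values).
#' @return pseudo-R2 (<= 1; can be negative for fits worse than the mean).
#' @export
pseudoR2 <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("pseudo-R2 is undefined for constant observations")
  1 - sum((observed - fitted)^2) / sst
}

#' Flag residual outliers by a fitted-normal tail rule
#'
#' Re-implementation of the quantile-based "method I" rule: a normal
#' distribution is fitted to the central residual quantiles (default
#' 25th-75th) by least squares on the QQ plot, and an observation is
#' flagged when the expected number of observations at least as extreme
#' under that normal is below `rho` (`rho` counts both tails together, so
#' each tail limit is the `rho / (2 n)` quantile).
#'
#' @param residuals numeric vector (>= 5 values).
#' @param quantileWindow central probability window used for the normal fit.
#' @param rho expected-count threshold (default 0.5).
#' @return integer vector of flagged indices (possibly empty).
#' @export
detectOutliers <- function(residuals, quantileWindow = c(0.25, 0.75),
                           rho = 0.5) {
  n <- length(residuals)
  stopifnot(n >= 5)
  o <- order(residuals)
  pp <- stats::ppoints(n)
  keep <- pp >= quantileWindow[1] & pp <= quantileWindow[2]
  if (sum(keep) < 2) keep <- rep(TRUE, n)
  q <- stats::qnorm(pp[keep])
  fit <- stats::lm.fit(cbind(1, q), residuals[o][keep])
  mu <- fit$coefficients[1]
  sigma <- fit$coefficients[2]
  if (!is.finite(sigma) || sigma <= 0)
    return(integer(0))
  hi <- stats::qnorm(1 - rho / (2 * n), mu, sigma)
  lo <- stats::qnorm(rho / (2 * n), mu, sigma)
  which(residuals > hi | residuals < lo)
}

#' Fit the logistic senescence model to one plant
#'
#' Two-pass nonlinear least squares on parameters (D, K, log a, r) with box
#' constraints K > 0, r > 0: pass 1 on all data, outliers flagged on the
#' pass-1 residuals with [detectOutliers()], pass 2 without them;
#' pseudo-R2 is computed on the pass-2 data.  Failures are reported as
#' `converged = FALSE`, never as an error (mirroring the ~5% of plants the
#' model cannot fit).
#'
#' Starting values come from the curve's own geometry: D0 = min CHL,
#' K0 = range, XPI0 = t at half decline, r0 = 4 |steepest slope| / K0,
#' log a0 = -r0 * XPI0.
#'
#' @param t,chl one plant's augmented curve (>= 5 points, `t` increasing).
#' @param plantId identifier stored in the result.
#' @param quantileWindow,rho outlier rule settings, see [detectOutliers()].
#' @param maxOutlierFraction at most this fraction of points is dropped.
#' @return a [LogisticFit-class].
#' @export
fitLogistic <- function(t, chl, plantId = "plant",
                        quantileWindow = c(0.25, 0.75), rho = 0.5,
                        maxOutlierFraction = 0.3) {
  if (length(t) < 5)
    stop("at least 5 observations are required")
  stopifnot(length(t) == length(chl), all(diff(t) > 0))

  fail <- function() methods::new("LogisticFit", plantId = plantId,
    D = NA_real_, K = NA_real_, a = NA_real_, r = NA_real_,
    pseudoR2 = NA_real_, nUsed = 0L, outlierIndices = integer(0),
    converged = FALSE, t = t, chl = chl)
  if (stats::sd(chl) == 0) return(fail())

  # Levenberg-Marquardt on (D, K, log a, r) with box constraints; the
  # geometric initialiser (D0 = min, K0 = range, XPI0 = t at half decline,
  # r0 = 4 |steepest slope| / K0, log a0 = -r0 XPI0) is augmented with two
  # alternative onset candidates because a single noisy dip can fool the
  # closest-to-half rule.
  onePass <- function(ti, yi) {
    D0 <- min(yi)
    K0 <- max(yi) - min(yi)
    xpiGeom <- ti[which.min(abs(yi - (D0 + K0 / 2)))]
    below <- which(yi < D0 + K0 / 2)
    xpiCross <- if (length(below)) ti[below[1]] else ti[length(ti)]
    slope <- diff(yi) / diff(ti)
    r0 <- max(4 * abs(min(slope)) / K0, 1e-4)
    resfn <- function(p) yi - (p[1] + p[2] / (1 + exp(p[3] + p[4] * ti)))
    best <- NULL
    for (xpi0 in unique(c(xpiGeom, xpiCross, stats::median(ti)))) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = c(D0, K0, -r0 * xpi0, r0), fn = resfn,
          lower = c(-Inf, 1e-8, -Inf, 1e-8),
          control = minpack.lm::nls.lm.control(maxiter = 300,
                                               ftol = 1e-14, ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(fit$par)) &&
          (is.null(best) || fit$deviance < best$deviance))
        best <- fit
    }
    if (is.null(best)) return(NULL)
    if (!best$info %in% 1:4) return(NULL)
    list(par = stats::setNames(best$par, c("D", "K", "la", "r")),
         residuals = as.numeric(best$fvec),
         fitted = yi - as.numeric(best$fvec))
  }

  m1 <- onePass(t, chl)
  if (is.null(m1)) return(fail())
  out <- detectOutliers(m1$residuals, quantileWindow, rho)
  if (length(out) > maxOutlierFraction * length(t))
    out <- out[order(abs(m1$residuals)[out],
                     decreasing = TRUE)][seq_len(floor(maxOutlierFraction *
                                                         length(t)))]
  if (length(out) && length(t) - length(out) >= 5) {
    m2 <- onePass(t[-out], chl[-out])
    used <- setdiff(seq_along(t), out)
  } else {
    m2 <- m1
    out <- integer(0)
    used <- seq_along(t)
  }
  if (is.null(m2)) return(fail())
  cf <- m2$par
  r2 <- tryCatch(pseudoR2(chl[used], m2$fitted),
                 error = function(e) NA_real_)
  methods::new("LogisticFit", plantId = plantId,
               D = unname(cf["D"]), K = unname(cf["K"]),
               a = unname(exp(cf["la"])), r = unname(cf["r"]),
               pseudoR2 = r2, nUsed = length(used),
               outlierIndices = as.integer(out), converged = TRUE,
               t = t, chl = chl)
}

setMethod("show", "LogisticFit", function(object) {
  if (!object@converged) {
    cat("LogisticFit", object@plantId, ": did not converge\n")
  } else {
    cat(sprintf(
      "LogisticFit %s: D=%.3g K=%.3g a=%.3g r=%.4g  pseudo-R2=%.3f (n=%d, %d outlier(s))\n",
      object@plantId, object@D, object@K, object@a, object@r,
      object@pseudoR2, object@nUsed, length(object@outlierIndices)))
  }
})

#' Closed-form stay-green traits of a logistic fit
#'
#' With u(t) = a exp(r t), the decline f(t) = D + K/(1+u) has inflection at
#' u = 1, giving XPI = |ln a| / r, YPI = K/2 and maximal senescence rate
#' VIT = f'(XPI) = -K r / 4.  The onset and completion of senescence are the
#' extrema of the third derivative, at u = 5 -/+ 2 sqrt(6)
#' (`rule = "third-derivative"`, the default; the extrema of the second
#' derivative, u = 2 -/+ sqrt(3), are available as
#' `rule = "second-derivative"`).  fSTART and fEND are the CHL values
#' there; AUCK integrates (f - D) from anthesis to END via the analytic
#' antiderivative K [t - ln(1 + a e^{rt}) / r], and AUC integrates the same
#' quantity from START (or from 0 when `aucFrom = "anthesis"`).
#'
#' @param fit a converged [LogisticFit-class], or a list/vector with
#'   elements `D`, `K`, `a`, `r`.
#' @param rule which derivative's extrema define START/END.
#' @param aucFrom lower integration limit of AUC.
#' @return one-row data.frame: `XPI`, `YPI`, `VIT`, `START`, `END`,
#'   `fSTART`, `fEND`, `AUC`, `AUCK`, `preAnthesisOnset` (TRUE when a >= 1
#'   puts the onset before anthesis; traits are still returned).
#' @export
deriveTraits <- function(fit, rule = c("third-derivative",
                                       "second-derivative"),
                         aucFrom = c("start", "anthesis")) {
  rule <- match.arg(rule)
  aucFrom <- match.arg(aucFrom)
  if (methods::is(fit, "LogisticFit")) {
    if (!fit@converged) stop("cannot derive traits from a failed fit")
    D <- fit@D; K <- fit@K; a <- fit@a; r <- fit@r
  } else {
    D <- fit[["D"]]; K <- fit[["K"]]; a <- fit[["a"]]; r <- fit[["r"]]
  }
  stopifnot(K > 0, r > 0, a > 0)
  la <- log(a)
  u <- if (rule == "third-derivative") 5 + c(-2, 2) * sqrt(6) else
    2 + c(-1, 1) * sqrt(3)
  START <- (log(u[1]) - la) / r
  END <- (log(u[2]) - la) / r
  antider <- function(tt) K * (tt - log1p(a * exp(r * tt)) / r)
  data.frame(XPI = abs(la) / r, YPI = K / 2, VIT = -K * r / 4,
             START = START, END = END,
             fSTART = D + K / (1 + u[1]), fEND = D + K / (1 + u[2]),
             AUC = antider(END) -
               antider(if (aucFrom == "start") START else 0),
             AUCK = antider(END) - antider(0),
             preAnthesisOnset = a >= 1 || START < 0)
}

#' Fit senescence curves for a whole panel
#'
#' Convenience batch driver: per plant, appends the pseudo point, runs the
#' two-pass fit, derives the stay-green traits and applies the automated
#' quality rules that replace the study's manual curation (END more than
#' 400 degree-days beyond the last observation, D outside [-5, 20] ug cm-3,
#' or pseudo-R2 < 0.7 flag the plant).
#'
#' @param curves long data.frame with columns `plant_id`, `t`, `chl` (extra
#'   metadata columns are carried through, one value per plant).
#' @param deadChl,gap pseudo-point settings, see [addPseudoPoint()].
#' @param rule,aucFrom trait settings, see [deriveTraits()].
#' @param ... passed to [fitLogistic()].
#' @return data.frame, one row per plant: fit parameters, pseudo-R2,
#'   outlier count, traits, and `qcFlag`.
#' @export
fitSenescence <- function(curves, deadChl = 5, gap = 200,
                          rule = "third-derivative", aucFrom = "start",
                          ...) {
  stopifnot(all(c("plant_id", "t", "chl") %in% names(curves)))
  metaCols <- setdiff(names(curves), c("t", "chl", "is_outlier"))
  ids <- unique(curves$plant_id)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cv <- curves[curves$plant_id == ids[i], , drop = FALSE]
    aug <- addPseudoPoint(cv$t, cv$chl, deadChl = deadChl, gap = gap)
    fit <- fitLogistic(aug$t, aug$chl, plantId = ids[i], ...)
    meta <- cv[1L, metaCols, drop = FALSE]
    tr <- NULL
    if (fit@converged && is.finite(fit@a) && fit@a > 0)
      tr <- tryCatch(deriveTraits(fit, rule = rule, aucFrom = aucFrom),
                     error = function(e) NULL)
    if (!is.null(tr)) {
      qc <- tr$END > max(cv$t) + 400 || fit@D < -5 || fit@D > 20 ||
        (is.finite(fit@pseudoR2) && fit@pseudoR2 < 0.7)
      row <- data.frame(meta, D = fit@D, K = fit@K, a = fit@a, r = fit@r,
                        pseudoR2 = fit@pseudoR2, nUsed = fit@nUsed,
                        nOutliers = length(fit@outlierIndices),
                        converged = TRUE, tr, qcFlag = qc,
                        row.names = NULL)
    } else {
      # non-convergence, or degenerate parameters (e.g. a underflowing to
      # zero when no decline falls inside the measurement window)
      row <- data.frame(meta, D = fit@D, K = fit@K, a = fit@a, r = fit@r,
                        pseudoR2 = fit@pseudoR2, nUsed = fit@nUsed,
                        nOutliers = length(fit@outlierIndices),
                        converged = fit@converged,
                        XPI = NA_real_, YPI = NA_real_, VIT = NA_real_,
                        START = NA_real_, END = NA_real_, fSTART = NA_real_,
                        fEND = NA_real_, AUC = NA_real_, AUCK = NA_real_,
                        preAnthesisOnset = NA, qcFlag = TRUE,
                        row.names = NULL)
    }
    res[[i]] <- row
  }
  do.call(rbind, res)
}
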