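# REML split-plot models: oracle equivalence, heritability, gBLUP,
# stress index and likelihood-ratio tests.

test_that("REML equals closed-form ANOVA estimators on a balanced design", {
  rec <- balancedRecords(g = 40, r = 3, seed = 99)
  fit <- fitSplitPlot(rec, identityKinship(40), tolLl = 1e-12, maxit = 200)
  ems <- emsComponents(rec)
  est <- varianceComponents(fit)[c("g", "gt", "residual")]
  expect_true(fit@converged)
  expect_lt(max(abs(est - ems)), 1e-6)
  # fixed effects equal the OLS stratum means when K = I and data balanced
  ols <- stats::lm(value ~ replicate * treatment, data = rec)
  cf <- fixedEffects(fit)
  expect_equal(cf, stats::coef(ols)[names(cf)], tolerance = 1e-8)
})

test_that("REML log-likelihood trace is monotone and components non-negative", {
  rec <- balancedRecords(g = 30, r = 2, seed = 3)
  fit <- fitSplitPlot(rec, identityKinship(30))
  expect_true(all(varianceComponents(fit) >= 0))
  ll <- staygreenGT:::.aiReml(rec$value,
                              stats::model.matrix(~ replicate * treatment,
                                                  rec),
                              staygreenGT:::.splitPlotKernels(
                                transform(rec,
                                          treatment = factor(treatment)),
                                diag(30), sprintf("G%03d", 1:30),
                                FALSE, TRUE))$llTrace
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("a truly zero genotype variance is estimated at the boundary", {
  atBoundary <- vapply(1:20, function(s) {
    rec <- balancedRecords(g = 100, r = 3, vg = 0, vgt = 0, ve = 10,
                           seed = 100 + s)
    fit <- fitSplitPlot(rec, identityKinship(100))
    unname(varianceComponents(fit)["g"] <=
             0.05 * varianceComponents(fit)["residual"])
  }, logical(1))
  expect_gte(mean(atBoundary), 0.9)
})

test_that("kinship-structured REML agrees with lme4 when K is identity", {
  rec <- balancedRecords(g = 35, r = 3, seed = 12)
  fit <- fitSplitPlot(rec, identityKinship(35), tolLl = 1e-12, maxit = 200)
  lmm <- lme4::lmer(value ~ replicate * treatment + (1 | genotype) +
                      (1 | genotype:treatment), data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  ref <- c(g = vc$vcov[vc$grp == "genotype"],
           gt = vc$vcov[vc$grp == "genotype:treatment"],
           residual = vc$vcov[vc$grp == "Residual"])
  est <- varianceComponents(fit)[names(ref)]
  expect_equal(unname(est), unname(ref), tolerance = 1e-4)
})

test_that("heritability reproduces the published worked examples", {
  # multi-year formula on printed variance components, t = a = 2, n = 3
  expect_equal(round(heritability(c(g = 12.3, gt = 4.24, gy = 4.39,
                                    residual = 32.20), t = 2, n = 3, a = 2),
                     2), 0.64)
  expect_equal(round(heritability(c(g = 24.29, gt = 0.14, gy = 5.03,
                                    residual = 9.04), t = 2, n = 3, a = 2),
                     2), 0.88)
  expect_equal(heritability(c(g = 0, gt = 1, gy = 1, residual = 2),
                            t = 2, n = 3, a = 2), 0)
  # single-year formula is the a = 1, gy = 0 special case
  comp <- c(g = 5, gt = 2, gy = 0, residual = 12)
  expect_equal(heritability(comp, t = 2, n = 3),
               heritability(comp, t = 2, n = 3, a = 1))
  # bounded in [0, 1] for non-negative components
  withr::with_seed(4, {
    for (i in 1:25) {
      cmp <- c(g = stats::runif(1, 0, 50), gt = stats::runif(1, 0, 20),
               gy = stats::runif(1, 0, 20), residual = stats::runif(1, 0, 60))
      h <- heritability(cmp, t = 2, n = 3, a = 2)
      expect_true(h >= 0 && h <= 1)
    }
  })
})

test_that("gBLUP table degenerates correctly and tracks the truth", {
  rec <- balancedRecords(g = 30, r = 2, seed = 7)
  K <- identityKinship(30)
  # zero interaction variance: both treatments share the genotype ranking
  fit0 <- fitSplitPlot(rec, K, components = c(g = 2, gt = 0, residual = 3))
  g0 <- gblupByTreatment(fit0)
  ns <- g0[g0$treatment == "NS", ]
  s <- g0[g0$treatment == "S", ]
  expect_equal(ns$ggt - mean(ns$ggt), s$ggt - mean(s$ggt), tolerance = 1e-10)
  # all variances zero: gBLUP collapses to the treatment means
  fitF <- fitSplitPlot(rec, K, components = c(g = 0, gt = 0, residual = 1))
  gF <- gblupByTreatment(fitF)
  expect_equal(stats::sd(gF$ggt[gF$treatment == "NS"]), 0, tolerance = 1e-12)
  # BLUPs of each random term sum to ~0
  fit <- fitSplitPlot(rec, K)
  expect_lt(abs(sum(blups(fit)$g)), 1e-6)
  expect_lt(max(abs(colSums(blups(fit)$gt))), 1e-6)

  # high-heritability simulation: gBLUP correlates > 0.9 with the truth
  recH <- balancedRecords(g = 80, r = 3, vg = 12, vgt = 2, ve = 6, seed = 55)
  tru <- attr(recH, "truth")
  fitH <- fitSplitPlot(recH, identityKinship(80))
  gg <- gblupByTreatment(fitH)
  truth <- c(tru$g + tru$gt[, 1], tru$g + tru$gt[, 2])
  est <- c(gg$ggt[gg$treatment == "NS"], gg$ggt[gg$treatment == "S"])
  expect_gt(stats::cor(est, truth), 0.9)
})

test_that("stress index arithmetic and orientation", {
  gg <- data.frame(genotype = rep(c("a", "b"), 2),
                   treatment = rep(c("NS", "S"), each = 2),
                   ggt = c(41, 39, 31, 29))
  expect_equal(stressIndex(gg), 25)          # NS 40, S 30
  expect_equal(unname(stressIndex(gg, "genotype")),
               c(100 * 10 / 41, 100 * 10 / 39))
  same <- transform(gg, ggt = c(40, 40, 40, 40))
  expect_equal(stressIndex(same), 0)
})

test_that("planted fixed stress loss is recovered by the panel index", {
  g <- 100
  K <- identityKinship(g)
  des <- simDesign(nGenotypes = g, nYears = 2, nReplicates = 3, seed = 1)
  eff <- simEffectSpec()       # -10.5 on a NS mean of 44.4 => SI ~ 23.6%
  si <- vapply(1:5, function(s) {
    ph <- simulatePhenotypes(des, NULL, eff, K, seed = 40 + s)
    fit <- fitSplitPlot(ph, K)
    stressIndex(gblupByTreatment(fit))
  }, numeric(1))
  expect_lt(abs(mean(si) - 100 * 10.5 / 44.4), 2.5)
})

test_that("likelihood-ratio test follows the boundary mixture", {
  expect_equal(lrtRandom(-100, -100),
               list(statistic = 0, p = 0.5))
  out <- lrtRandom(-98, -100)
  expect_equal(out$statistic, 4)
  expect_equal(out$p, 0.5 * stats::pchisq(4, 1, lower.tail = FALSE))
  expect_equal(lrtRandom(-98, -100, mixture = FALSE)$p,
               stats::pchisq(4, 1, lower.tail = FALSE))
  expect_error(lrtRandom(-100, -98), "not nested")
})

test_that("the mixture LRT is calibrated under a null variance component", {
  pvals <- vapply(1:150, function(s) {
    rec <- balancedRecords(g = 25, r = 2, vg = 2, vgt = 0, ve = 4,
                           seed = 500 + s)
    rec$treatment <- factor(rec$treatment, levels = c("NS", "S"))
    X <- stats::model.matrix(~ replicate * treatment, rec)
    Ml <- staygreenGT:::.splitPlotKernels(rec, diag(25),
                                          sprintf("G%03d", 1:25),
                                          FALSE, TRUE)
    full <- staygreenGT:::.aiReml(rec$value, X, Ml)
    red <- staygreenGT:::.aiReml(rec$value, X, Ml["g"])
    lrtRandom(full$ll, red$ll)$p
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.08)
})
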