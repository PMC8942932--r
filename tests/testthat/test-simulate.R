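# Synthetic-data generator: determinism, effect structure, curve geometry.

test_that("genotype simulation is deterministic and respects error rates", {
  gs <- simGenotypeSpec(nChromosomes = 3, snpsPerChromosome = 30)
  p1 <- simulateGenotypes(gs, 40, seed = 7)
  p2 <- simulateGenotypes(gs, 40, seed = 7)
  expect_identical(dosageMatrix(p1), dosageMatrix(p2))
  expect_identical(snpInfo(p1), snpInfo(p2))

  gs0 <- simGenotypeSpec(nChromosomes = 2, snpsPerChromosome = 25,
                         missingRate = 0, hetRate = 0)
  p0 <- simulateGenotypes(gs0, 30, seed = 1)
  d <- dosageMatrix(p0)
  expect_false(anyNA(d))
  expect_true(all(d %in% c(0, 2)))

  info <- snpInfo(p1)
  for (cc in unique(info$chrom))
    expect_true(all(diff(info$pos[info$chrom == cc]) > 0))
  expect_error(simulateGenotypes(gs, 0), "nGenotypes")
})

test_that("block size one gives independent SNPs (r2 at the 1/(n-1) level)", {
  n <- 120
  obs <- exp <- c()
  for (s in 1:10) {
    gs <- simGenotypeSpec(nChromosomes = 1, snpsPerChromosome = 40,
                          ldBlockMeanSnps = 1, missingRate = 0, hetRate = 0)
    d <- dosageMatrix(simulateGenotypes(gs, n, seed = s))
    r2 <- suppressWarnings(stats::cor(d)^2)
    obs <- c(obs, r2[cbind(1:39, 2:40)])
    # oracle: r2 of independently drawn SNPs with the same frequencies
    withr::with_seed(1000 + s, {
      di <- vapply(colMeans(d) / 2, function(p) 2 * stats::rbinom(n, 1, p),
                   numeric(n))
    })
    r2i <- suppressWarnings(stats::cor(di)^2)
    exp <- c(exp, r2i[cbind(1:39, 2:40)])
  }
  # both should sit near E[r2] = 1/(n-1) under independence
  expect_lt(abs(mean(obs, na.rm = TRUE) - 1 / (n - 1)), 2 / (n - 1))
  expect_lt(abs(mean(obs, na.rm = TRUE) - mean(exp, na.rm = TRUE)),
            2 / (n - 1))
})

test_that("larger LD blocks give high within-block, low between-block r2", {
  gs <- simGenotypeSpec(nChromosomes = 1, snpsPerChromosome = 60,
                        ldBlockMeanSnps = 8, missingRate = 0, hetRate = 0,
                        mafRange = c(0.2, 0.5))
  p <- simulateGenotypes(gs, 150, seed = 3)
  d <- dosageMatrix(p)
  r2 <- suppressWarnings(stats::cor(d)^2)
  adj <- r2[cbind(seq_len(ncol(d) - 1), seq(2, ncol(d)))]
  # adjacent pairs are mostly within-block: mean far above independence
  expect_gt(mean(adj, na.rm = TRUE), 0.2)
  far <- r2[1, ncol(d)]
  expect_lt(far, 0.2)
})

test_that("phenotype structure: degenerate cases are exact", {
  g <- 12
  K <- identityKinship(g)
  des <- simDesign(nGenotypes = g, nYears = 1, nReplicates = 2,
                   nSubblocks = 2, seed = 1)
  effNull <- simEffectSpec(mu = 7, varG = 0, varGT = 0, varGY = 0,
                           varSubblock = 0, varRes = 0,
                           fixedYearEffects = 0, fixedTreatmentEffect = 0)
  ph <- simulatePhenotypes(des, NULL, effNull, K, seed = 4)
  expect_equal(nrow(ph), g * 1 * 2 * 2)
  expect_true(all(ph$value == 7))

  # a single additive QTL with main effect 1: dosage-2 minus dosage-0
  # genotypes differ by exactly 2 in both treatments
  dos <- matrix(rep(c(0, 2), each = g / 2), ncol = 1,
                dimnames = list(sprintf("G%03d", 1:g), "q1"))
  panel <- toyPanel(dos)
  effQ <- simEffectSpec(mu = 0, varG = 0, varGT = 0, varGY = 0,
                        varSubblock = 0, varRes = 0, fixedYearEffects = 0,
                        fixedTreatmentEffect = 0,
                        qtlList = data.frame(chrom = "1A", pos = 1e5,
                                             mainEffect = 1,
                                             interactionEffect = 0))
  phQ <- simulatePhenotypes(des, panel, effQ, K, seed = 4)
  for (k in c("NS", "S")) {
    v2 <- phQ$value[phQ$treatment == k & phQ$genotype %in%
                      rownames(dos)[dos == 2]]
    v0 <- phQ$value[phQ$treatment == k & phQ$genotype %in%
                      rownames(dos)[dos == 0]]
    expect_true(all(abs(outer(v2, v0, "-") - 2) < 1e-12))
  }
  expect_error(simulatePhenotypes(des, NULL, effNull, identityKinship(5),
                                  seed = 1), "dimension")
})

test_that("generated variance components match method-of-moments ANOVA", {
  g <- 199
  K <- identityKinship(g)
  des <- simDesign(nGenotypes = g, nYears = 2, nReplicates = 3,
                   nSubblocks = 1, seed = 1)
  eff <- simEffectSpec(varSubblock = 0)   # TKW-like 12.3/4.24/4.39/32.2
  nSeeds <- 25
  est <- matrix(NA_real_, nSeeds, 4)
  for (s in seq_len(nSeeds)) {
    ph <- simulatePhenotypes(des, NULL, eff, K, seed = s)
    a <- stats::aov(value ~ year * replicate * treatment + genotype +
                      genotype:treatment + genotype:year, data = ph)
    sm <- summary(a)[[1]]
    rn <- trimws(rownames(sm))
    ms <- sm[, "Mean Sq"]
    msE <- ms[rn == "Residuals"]
    msG <- ms[rn == "genotype"]
    msGT <- ms[grepl("genotype", rn) & grepl("treatment", rn)]
    msGY <- ms[grepl("genotype", rn) & grepl("year", rn)]
    est[s, ] <- c((msG - msGT - msGY + msE) / 12, (msGT - msE) / 6,
                  (msGY - msE) / 6, msE)
  }
  truth <- c(12.3, 4.24, 4.39, 32.2)
  expect_true(all(abs(colMeans(est) - truth) < 0.10 * truth))
})

test_that("senescence curves: exactness, treatment shift and trait order", {
  des <- simDesign(nGenotypes = 10, nYears = 1, nReplicates = 1, seed = 1)
  clean <- simSenescenceSpec(noiseSd = 0, outlierRate = 0)
  sim <- simulateSenescenceCurves(des, clean, seed = 2)
  tr <- sim$truth
  cv <- sim$curves
  i <- match(cv$plant_id, tr$plant_id)
  mu <- tr$D[i] + tr$K[i] / (1 + tr$a[i] * exp(tr$r[i] * cv$t))
  expect_equal(cv$chl, mu, tolerance = 1e-12)
  expect_true(all(tr$START < tr$XPI & tr$XPI < tr$END))

  # zero shift leaves the S draws untouched; a shift moves only S onsets,
  # by exactly the requested amount (same seed stream per plant)
  s0 <- simulateSenescenceCurves(des, simSenescenceSpec(
    treatmentShiftOnStart = 0, noiseSd = 0, outlierRate = 0), seed = 9)
  s28 <- simulateSenescenceCurves(des, simSenescenceSpec(
    treatmentShiftOnStart = 28, noiseSd = 0, outlierRate = 0), seed = 9)
  ns <- s0$truth$treatment == "NS"
  expect_equal(s0$truth$START[ns], s28$truth$START[ns])
  expect_equal(s0$truth$START[!ns] - 28, s28$truth$START[!ns])
})

test_that("mean onset stress index sits near the planted 28/532 ratio", {
  des <- simDesign(nGenotypes = 60, nYears = 1, nReplicates = 1, seed = 1)
  sp <- simSenescenceSpec()
  si <- vapply(1:20, function(s) {
    tr <- simulateSenescenceCurves(des, sp, seed = s)$truth
    100 * (mean(tr$START[tr$treatment == "NS"]) -
             mean(tr$START[tr$treatment == "S"])) /
      mean(tr$START[tr$treatment == "NS"])
  }, numeric(1))
  expect_lt(abs(mean(si) - 5.26), 1)
})
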