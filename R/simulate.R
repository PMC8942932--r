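# Synthetic-data generator: genotype panels with block LD, split-plot
# phenotypes with kinship-structured polygenic and interaction effects, and
# per-plant logistic senescence curves.  Defaults emulate the study design:
# ~199 elite winter-wheat varieties, 21 chromosomes, two treatments (NS/S),
# three replicates, five sub-blocks per whole plot.

#' Simulation design: the split-plot layout
#'
#' @param nGenotypes,nYears,nTreatments,nReplicates,nSubblocks design counts;
#'   treatments are always labelled NS (non-stress) and S (stress).
#' @param seed base RNG seed.
#' @return validated list of class `SimDesign`.
#' @export
simDesign <- function(nGenotypes = 199L, nYears = 2L, nTreatments = 2L,
                      nReplicates = 3L, nSubblocks = 5L, seed = 1L) {
  for (nm in c("nGenotypes", "nYears", "nTreatments", "nReplicates",
               "nSubblocks"))
    .assertCount(get(nm), nm)
  if (nTreatments != 2L)
    stop("the design supports exactly 2 treatments (NS, S)")
  structure(list(nGenotypes = as.integer(nGenotypes),
                 nYears = as.integer(nYears),
                 nTreatments = 2L,
                 nReplicates = as.integer(nReplicates),
                 nSubblocks = as.integer(nSubblocks),
                 seed = as.integer(seed)),
            class = "SimDesign")
}

#' Genotype panel simulation settings
#'
#' LD is induced by a block-haplotype scheme: SNPs are partitioned into
#' blocks (geometric lengths, mean `ldBlockMeanSnps`); each block has two
#' founder haplotypes and each inbred line inherits one of them per block,
#' with recombination only at block borders.  Per-SNP minor-allele
#' frequencies are drawn from `mafRange`; heterozygous calls (genotyping
#' error in an inbred panel) and missing calls are injected uniformly at
#' random, independent of dosage.
#'
#' @param nChromosomes,snpsPerChromosome,chromLengthBp panel dimensions.
#' @param ldBlockMeanSnps mean SNPs per LD block (1 = independent SNPs).
#' @param mafRange minor-allele frequency interval within (0, 0.5].
#' @param missingRate,hetRate per-call missing and heterozygous proportions.
#' @return validated list of class `SimGenotypeSpec`.
#' @export
simGenotypeSpec <- function(nChromosomes = 21L, snpsPerChromosome = 100L,
                            chromLengthBp = 6e8, ldBlockMeanSnps = 5,
                            mafRange = c(0.05, 0.5), missingRate = 0.08,
                            hetRate = 0.01) {
  .assertCount(nChromosomes, "nChromosomes")
  .assertCount(snpsPerChromosome, "snpsPerChromosome")
  .assertCount(chromLengthBp, "chromLengthBp")
  if (ldBlockMeanSnps < 1) stop("'ldBlockMeanSnps' must be >= 1")
  .assertProp(missingRate, "missingRate")
  .assertProp(hetRate, "hetRate")
  if (length(mafRange) != 2L || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("'mafRange' must be an interval within (0, 0.5]")
  structure(list(nChromosomes = as.integer(nChromosomes),
                 snpsPerChromosome = as.integer(snpsPerChromosome),
                 chromLengthBp = as.numeric(chromLengthBp),
                 ldBlockMeanSnps = as.numeric(ldBlockMeanSnps),
                 mafRange = as.numeric(mafRange),
                 missingRate = as.numeric(missingRate),
                 hetRate = as.numeric(hetRate)),
            class = "SimGenotypeSpec")
}

#' Phenotype effect-structure settings
#'
#' Generative form of the multi-year split-plot model: fixed year and
#' treatment effects, i.i.d. sub-block effects, polygenic genotype effect
#' with covariance `varG * K`, genotype-by-treatment deviations (independent
#' `varGT * K` vectors per treatment), genotype-by-year deviations
#' (`varGY * K` per year), planted QTL with main and QTL-by-treatment
#' effects, and i.i.d. residual.  Defaults are thousand-kernel-weight-like:
#' variance components 12.3 / 4.24 / 4.39 / 32.20 and a fixed stress effect
#' of about -24% of the non-stress mean.
#'
#' @param mu general mean.
#' @param varG,varGT,varGY,varSubblock,varRes variance components (>= 0).
#' @param fixedYearEffects numeric vector, one entry per year.
#' @param fixedTreatmentEffect shift added to the S treatment.
#' @param qtlList data.frame with columns `chrom`, `pos`, `mainEffect`,
#'   `interactionEffect` (effects per alternate-allele dosage unit; the
#'   interaction effect is added in the S treatment only), or `NULL`.
#' @return validated list of class `SimEffectSpec`.
#' @export
simEffectSpec <- function(mu = 44.4, varG = 12.3, varGT = 4.24, varGY = 4.39,
                          varSubblock = 2, varRes = 32.2,
                          fixedYearEffects = c(2.4, -2.4),
                          fixedTreatmentEffect = -10.5, qtlList = NULL) {
  v <- c(varG = varG, varGT = varGT, varGY = varGY,
         varSubblock = varSubblock, varRes = varRes)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all variances must be finite and >= 0")
  if (!is.null(qtlList))
    stopifnot(is.data.frame(qtlList),
              all(c("chrom", "pos", "mainEffect", "interactionEffect") %in%
                    names(qtlList)))
  structure(list(mu = mu, varG = varG, varGT = varGT, varGY = varGY,
                 varSubblock = varSubblock, varRes = varRes,
                 fixedYearEffects = fixedYearEffects,
                 fixedTreatmentEffect = fixedTreatmentEffect,
                 qtlList = qtlList),
            class = "SimEffectSpec")
}

#' Senescence-curve simulation settings
#'
#' Per plant, true logistic parameters are drawn around the spec means:
#' `a` log-normally (senescence parameters are near-normal except `a`),
#' `D`, `K`, `r` Gaussian truncated to valid ranges.  Stress plants have
#' their onset of senescence shifted earlier by `treatmentShiftOnStart`
#' degree-days (implemented as `a <- a * exp(r * shift)`, which translates
#' the whole curve left).  Observations are the logistic values on a
#' regular thermal-time schedule plus Gaussian noise; outliers are injected
#' at `outlierRate` with a random-sign offset of `outlierMagnitude`.
#'
#' Default means are back-derived from the panel means of the study traits
#' (final CHL ~5.1, amplitude ~46.1 ug cm-3, onset ~532 degree-days) and are
#' synthetic defaults, not reported between-genotype variances.
#'
#' @param meanD,meanK means of final CHL and amplitude (ug cm-3).
#' @param meanLogA mean of log(a) (must be < 0: onset after anthesis).
#' @param meanR mean senescence rate parameter (per degree-day, > 0).
#' @param sdD,sdK,sdLogA,sdR between-plant standard deviations.
#' @param treatmentShiftOnStart earlier onset under stress (degree-days).
#' @param measurementInterval,nMeasurements sampling schedule (>= 5 dates).
#' @param noiseSd measurement noise (ug cm-3); the default is calibrated so
#'   that fitted pseudo-R2 lands in the study's printed 0.94-0.98 band.
#' @param outlierRate,outlierMagnitude outlier process.
#' @return validated list of class `SimSenescenceSpec`.
#' @export
simSenescenceSpec <- function(meanD = 5.1, meanK = 46.1, meanLogA = -14.42,
                              meanR = 0.0228, sdD = 1.0, sdK = 3.2,
                              sdLogA = 0.9, sdR = 0.0022,
                              treatmentShiftOnStart = 28,
                              measurementInterval = 50, nMeasurements = 19L,
                              noiseSd = 3.8, outlierRate = 0.05,
                              outlierMagnitude = 15) {
  if (meanK <= 0) stop("'meanK' must be > 0")
  if (meanR <= 0) stop("'meanR' must be > 0")
  if (meanLogA >= 0) stop("'meanLogA' must be < 0")
  .assertCount(nMeasurements, "nMeasurements", min = 5L)
  .assertProp(outlierRate, "outlierRate")
  structure(list(meanD = meanD, meanK = meanK, meanLogA = meanLogA,
                 meanR = meanR, sdD = sdD, sdK = sdK, sdLogA = sdLogA,
                 sdR = sdR, treatmentShiftOnStart = treatmentShiftOnStart,
                 measurementInterval = measurementInterval,
                 nMeasurements = as.integer(nMeasurements),
                 noiseSd = noiseSd, outlierRate = outlierRate,
                 outlierMagnitude = outlierMagnitude),
            class = "SimSenescenceSpec")
}

#' Simulate a genotype panel with block LD
#'
#' Inbred lines: each genotype carries a single haplotype per block, so
#' true dosages are 0 or 2; heterozygous calls are injected as errors.
#' Within a block all SNPs share the founder-haplotype indicator, giving
#' high within-block r2 and near-zero between-block r2.
#'
#' @param spec a [simGenotypeSpec()].
#' @param nGenotypes number of genotypes.
#' @param seed RNG seed; identical seeds reproduce the panel bit-identically.
#' @return a [GenotypePanel-class].
#' @export
simulateGenotypes <- function(spec, nGenotypes, seed = 1L) {
  stopifnot(inherits(spec, "SimGenotypeSpec"))
  .assertCount(nGenotypes, "nGenotypes")
  chroms <- paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
  chroms <- rep_len(chroms, spec$nChromosomes)
  if (spec$nChromosomes > 21L)
    chroms <- make.unique(chroms)
  g <- nGenotypes
  m <- spec$snpsPerChromosome
  withr::with_seed(.subSeed(seed, 1L), {
    dosList <- vector("list", spec$nChromosomes)
    mapList <- vector("list", spec$nChromosomes)
    for (cc in seq_len(spec$nChromosomes)) {
      pos <- sort(sample.int(spec$chromLengthBp, m))
      # geometric block lengths, mean ldBlockMeanSnps
      p <- 1 / spec$ldBlockMeanSnps
      len <- 1L + stats::rgeom(m, p)
      blocks <- rep.int(seq_along(len), len)[seq_len(m)]
      dos <- matrix(0L, g, m)
      for (b in unique(blocks)) {
        idx <- which(blocks == b)
        q <- stats::runif(1, spec$mafRange[1], spec$mafRange[2])
        founder <- stats::rbinom(g, 1L, q)   # which founder haplotype
        for (s in idx) {
          ps <- stats::runif(1, spec$mafRange[1], spec$mafRange[2])
          # maximal-correlation coupling of the SNP allele to the founder
          if (ps <= q) {
            allele <- founder * stats::rbinom(g, 1L, ps / q)
          } else {
            allele <- founder +
              (1L - founder) * stats::rbinom(g, 1L, (ps - q) / (1 - q))
          }
          dos[, s] <- 2L * allele
        }
      }
      dosList[[cc]] <- dos
      mapList[[cc]] <- data.frame(
        snp_id = sprintf("%s_%09d", chroms[cc], pos),
        chrom = chroms[cc], pos = pos, ref = "A", alt = "B",
        stringsAsFactors = FALSE)
    }
    dos <- do.call(cbind, dosList)
    map <- do.call(rbind, mapList)
    rownames(dos) <- sprintf("G%03d", seq_len(g))
    colnames(dos) <- map$snp_id
    # error processes: missing overrides het; independent of dosage
    u <- matrix(stats::runif(length(dos)), nrow(dos))
    dos[u < spec$missingRate + spec$hetRate &
          u >= spec$missingRate] <- 1L
    dos[u < spec$missingRate] <- NA_integer_
  })
  GenotypePanel(dos, map,
                chromLengths = stats::setNames(
                  rep(spec$chromLengthBp, length(unique(map$chrom))),
                  unique(map$chrom)))
}

#' Simulate split-plot phenotypes
#'
#' One record per genotype x year x treatment x replicate; genotypes are
#' allocated to sub-blocks within each whole plot (year x replicate x
#' treatment) by a seeded shuffle.  The phenotype is
#' mu + year + treatment(S) + sub-block + g + g.t + g.y + QTL + residual
#' with the covariance structure described in [simEffectSpec()].
#'
#' @param design a [simDesign()].
#' @param panel a [GenotypePanel-class] (used for QTL dosages; missing calls
#'   are mean-filled for effect computation).
#' @param eff a [simEffectSpec()].
#' @param kinship a [KinshipMatrix-class] over the panel's genotypes.
#' @param seed RNG seed.
#' @return data.frame with columns `genotype`, `year`, `treatment`,
#'   `replicate`, `subblock`, `value`, plus attribute `"truth"` (list with
#'   the drawn `g`, `gt`, `gy` effects).
#' @export
simulatePhenotypes <- function(design, panel, eff, kinship, seed = 1L) {
  stopifnot(inherits(design, "SimDesign"), inherits(eff, "SimEffectSpec"))
  K <- as.matrix(kinship)
  g <- design$nGenotypes
  if (nrow(K) != g)
    stop("kinship dimension must equal the number of genotypes")
  if (!is.null(panel) && ncol(panel) != g)
    stop("panel must hold one column per design genotype")
  genos <- rownames(K)
  if (is.null(genos)) genos <- sprintf("G%03d", seq_len(g))
  years <- paste0("Y", seq_len(design$nYears))
  trts <- c("NS", "S")
  reps <- paste0("R", seq_len(design$nReplicates))
  if (length(eff$fixedYearEffects) != design$nYears)
    stop("'fixedYearEffects' must have one entry per year")

  rec <- expand.grid(genotype = genos, year = years, treatment = trts,
                     replicate = reps, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  L <- .cholPSD(K)
  withr::with_seed(.subSeed(seed, 2L), {
    gEff <- .mvnK(L, eff$varG)
    gtEff <- vapply(trts, function(k) .mvnK(L, eff$varGT), numeric(g))
    gyEff <- vapply(years, function(a) .mvnK(L, eff$varGY), numeric(g))
    # sub-block allocation: seeded shuffle per whole plot
    rec$subblock <- NA_integer_
    wp <- interaction(rec$year, rec$treatment, rec$replicate, drop = TRUE)
    for (w in levels(wp)) {
      i <- which(wp == w)
      rec$subblock[i] <- sample(rep_len(seq_len(design$nSubblocks),
                                        length(i)))
    }
    sbFac <- interaction(rec$year, rec$treatment, rec$replicate,
                         rec$subblock, drop = TRUE)
    sbEff <- stats::rnorm(nlevels(sbFac), 0, sqrt(eff$varSubblock))
    resid <- stats::rnorm(nrow(rec), 0, sqrt(eff$varRes))
  })
  gi <- match(rec$genotype, genos)
  yi <- match(rec$year, years)
  isS <- rec$treatment == "S"
  value <- eff$mu + eff$fixedYearEffects[yi] +
    ifelse(isS, eff$fixedTreatmentEffect, 0) +
    sbEff[as.integer(sbFac)] +
    gEff[gi] + gtEff[cbind(gi, ifelse(isS, 2L, 1L))] + gyEff[cbind(gi, yi)] +
    resid

  qtlDosage <- NULL
  if (!is.null(eff$qtlList) && nrow(eff$qtlList)) {
    map <- snpInfo(panel)
    dos <- dosageMatrix(panel)
    p2 <- colMeans(dos, na.rm = TRUE)
    qtlDosage <- matrix(NA_real_, g, nrow(eff$qtlList))
    for (q in seq_len(nrow(eff$qtlList))) {
      onChrom <- which(map$chrom == eff$qtlList$chrom[q])
      if (!length(onChrom))
        stop("QTL chromosome not present in panel: ", eff$qtlList$chrom[q])
      s <- onChrom[which.min(abs(map$pos[onChrom] - eff$qtlList$pos[q]))]
      x <- dos[, s]
      x[is.na(x)] <- p2[s]
      qtlDosage[, q] <- x
      value <- value + x[gi] * (eff$qtlList$mainEffect[q] +
                                  eff$qtlList$interactionEffect[q] * isS)
    }
  }
  rec$value <- value
  rec <- rec[, c("genotype", "year", "treatment", "replicate", "subblock",
                 "value")]
  attr(rec, "truth") <- list(g = stats::setNames(gEff, genos),
                             gt = `dimnames<-`(gtEff, list(genos, trts)),
                             gy = `dimnames<-`(gyEff, list(genos, years)),
                             qtlDosage = qtlDosage)
  rec
}

#' Simulate per-plant chlorophyll senescence curves
#'
#' @param design a [simDesign()] (one plant per genotype x year x treatment
#'   x replicate).
#' @param spec a [simSenescenceSpec()].
#' @param seed RNG seed.
#' @return list with `curves` (long data.frame: `plant_id`, `genotype`,
#'   `year`, `treatment`, `replicate`, `t` in degree-days, `chl`,
#'   `is_outlier`) and `truth` (per-plant true parameters and closed-form
#'   START / XPI / END).
#' @export
simulateSenescenceCurves <- function(design, spec, seed = 1L) {
  stopifnot(inherits(design, "SimDesign"), inherits(spec, "SimSenescenceSpec"))
  genos <- sprintf("G%03d", seq_len(design$nGenotypes))
  plants <- expand.grid(genotype = genos,
                        year = paste0("Y", seq_len(design$nYears)),
                        treatment = c("NS", "S"),
                        replicate = paste0("R", seq_len(design$nReplicates)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  np <- nrow(plants)
  plants$plant_id <- sprintf("P%05d", seq_len(np))
  tgrid <- (seq_len(spec$nMeasurements) - 1L) * spec$measurementInterval

  rtrunc <- function(n, mean, sd, lower) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lower))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  withr::with_seed(.subSeed(seed, 3L), {
    D <- stats::rnorm(np, spec$meanD, spec$sdD)
    K <- rtrunc(np, spec$meanK, spec$sdK, 1e-3)
    logA <- stats::rnorm(np, spec$meanLogA, spec$sdLogA)
    logA[logA >= -1e-6] <- -1e-6            # keep onset after anthesis
    r <- rtrunc(np, spec$meanR, spec$sdR, 1e-5)
    isS <- plants$treatment == "S"
    logA[isS] <- logA[isS] + r[isS] * spec$treatmentShiftOnStart
    noise <- matrix(stats::rnorm(np * spec$nMeasurements, 0, spec$noiseSd),
                    np)
    isOut <- matrix(stats::runif(np * spec$nMeasurements) < spec$outlierRate,
                    np)
    outSign <- matrix(sign(stats::runif(np * spec$nMeasurements) - 0.5), np)
  })
  mu <- outer(seq_len(np), tgrid,
              function(i, t) D[i] + K[i] / (1 + exp(logA[i] + r[i] * t)))
  chl <- mu + noise + isOut * outSign * spec$outlierMagnitude

  curves <- data.frame(
    plant_id = rep(plants$plant_id, each = spec$nMeasurements),
    genotype = rep(plants$genotype, each = spec$nMeasurements),
    year = rep(plants$year, each = spec$nMeasurements),
    treatment = rep(plants$treatment, each = spec$nMeasurements),
    replicate = rep(plants$replicate, each = spec$nMeasurements),
    t = rep(tgrid, np),
    chl = as.numeric(t(chl)),
    is_outlier = as.logical(t(isOut)),
    stringsAsFactors = FALSE)

  uS <- 5 - 2 * sqrt(6)
  uE <- 5 + 2 * sqrt(6)
  truth <- data.frame(plants[, c("plant_id", "genotype", "year", "treatment",
                                 "replicate")],
                      D = D, K = K, a = exp(logA), r = r,
                      START = (log(uS) - logA) / r,
                      XPI = -logA / r,
                      END = (log(uE) - logA) / r,
                      stringsAsFactors = FALSE)
  list(curves = curves, truth = truth)
}
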