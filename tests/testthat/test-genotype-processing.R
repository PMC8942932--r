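# QC filters, imputation, LD, pruning and kinship.

test_that("qc applies het-to-missing, missingness and MAF rules in order", {
  g <- 20
  d <- matrix(0, g, 4,
              dimnames = list(sprintf("G%03d", 1:g), paste0("s", 1:4)))
  d[1:5, 1] <- NA          # 25% missing -> dropped
  d[6:12, 1] <- 2
  d[1, 2] <- 2             # MAF exactly 2/40 = 0.05 -> retained
  d[1, 3] <- 1             # het -> missing (5%); MAF 4/38 > 0.05 -> retained
  d[2:3, 3] <- 2
  # s4 monomorphic -> dropped
  panel <- toyPanel(d)
  out <- qcFilter(panel)
  expect_setequal(snpInfo(out)$snp_id, c("s2", "s3"))
  expect_true(is.na(dosageMatrix(out)["G001", "s3"]))

  # a clean panel passes unchanged, and QC is idempotent
  dc <- matrix(rep(c(0, 2, 2, 0), 5), 10, 2)
  clean <- toyPanel(dc)
  expect_equal(dosageMatrix(qcFilter(clean)), dosageMatrix(clean))
  once <- qcFilter(panel)
  expect_equal(dosageMatrix(qcFilter(once)), dosageMatrix(once))
  mono <- toyPanel(matrix(0, 10, 1))
  expect_error(qcFilter(mono), "empty")
})

test_that("qc retained set equals a brute-force per-SNP recount", {
  gs <- simGenotypeSpec(nChromosomes = 3, snpsPerChromosome = 60,
                        missingRate = 0.08, hetRate = 0.01,
                        mafRange = c(0.02, 0.5))
  p <- simulateGenotypes(gs, 100, seed = 13)
  out <- qcFilter(p)
  d <- dosageMatrix(p)
  d[d == 1] <- NA
  keep <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    if (mean(is.na(x)) > 0.10) return(FALSE)
    pj <- mean(x, na.rm = TRUE) / 2
    min(pj, 1 - pj) >= 0.05
  }, logical(1))
  expect_equal(nrow(out), sum(keep))
  expect_setequal(snpInfo(out)$snp_id, colnames(d)[keep])
})

test_that("binomial imputation fills at the observed frequency", {
  d <- matrix(2, 10, 2, dimnames = list(sprintf("G%03d", 1:10), c("a", "b")))
  d[3:5, 1] <- NA          # observed p = 1 -> all imputed calls are 2
  d[1, 2] <- 0
  panel <- toyPanel(d)
  imp <- imputeMissing(panel, seed = 3)
  expect_true(all(dosageMatrix(imp)[, "a"] == 2))
  clean <- toyPanel(matrix(c(0, 2, 2, 0), 2, 2))
  expect_identical(dosageMatrix(imputeMissing(clean)), dosageMatrix(clean))

  # sampling distribution: 1000 imputed calls stay inside the binomial CI
  p0 <- 0.3
  dbig <- matrix(NA_real_, 1100, 1, dimnames = list(NULL, "s"))
  withr::with_seed(5, dbig[1:100, 1] <- 2 * stats::rbinom(100, 1, p0))
  phat <- mean(dbig[1:100, 1]) / 2
  big <- imputeMissing(toyPanel(dbig), seed = 8)
  freq <- mean(dosageMatrix(big)[101:1100, 1]) / 2
  ci <- phat + c(-1, 1) * 3 * sqrt(phat * (1 - phat) / (2 * 1000))
  expect_true(freq > ci[1] && freq < ci[2])
})

test_that("ld r2 equals the squared Pearson correlation", {
  d <- cbind(a = c(0, 1, 2, 1, 0), b = c(0, 2, 2, 1, 0),
             c = c(0, 0, 2, 2, 0), e = c(2, 2, 0, 0, 2))
  panel <- toyPanel(d)
  expect_equal(ldR2(panel, "a", "a"), 1)
  expect_equal(ldR2(panel, "c", "e"), 1)   # perfect negative correlation
  # direct Pearson arithmetic for (0,1,2,1,0) vs (0,2,2,1,0)
  x <- d[, "a"]; y <- d[, "b"]
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ldR2(panel, "a", "b"), (num / den)^2)
  panel0 <- toyPanel(cbind(d, z = rep(1, 5)))
  expect_error(ldR2(panel0, "a", "z"), "zero-variance")
})

test_that("pruning keeps one SNP per LD cluster", {
  # all mutually r2 = 1 -> single SNP survives
  base <- c(0, 0, 2, 2, 0, 2, 0, 2)
  dup <- toyPanel(matrix(rep(base, 4), ncol = 4))
  expect_equal(nrow(pruneByLD(dup, seed = 1)), 1L)

  # mutually independent SNPs all survive
  withr::with_seed(17, {
    ind <- matrix(2 * stats::rbinom(300 * 6, 1, 0.4), 300, 6)
  })
  pInd <- toyPanel(ind)
  expect_equal(nrow(pruneByLD(pInd, seed = 1)), 6L)

  # two perfect blocks + three independent SNPs -> 5 kept, one per block
  withr::with_seed(18, {
    b1 <- 2 * stats::rbinom(200, 1, 0.5)
    b2 <- 2 * stats::rbinom(200, 1, 0.3)
    free <- matrix(2 * stats::rbinom(200 * 3, 1, 0.4), 200, 3)
  })
  d <- cbind(b1, b1, b1, b2, b2, free)
  colnames(d) <- paste0("s", 1:8)
  panel <- toyPanel(d)
  kept <- pruneByLD(panel, seed = 2)
  expect_equal(nrow(kept), 5L)
  # oracle: connected components at r2 > 0.9
  r2 <- stats::cor(d)^2
  gr <- (r2 > 0.9)
  comp <- seq_len(ncol(d))
  for (i in seq_len(ncol(d))) for (j in seq_len(ncol(d)))
    if (gr[i, j]) comp[comp == comp[j]] <- comp[i]
  expect_equal(length(unique(comp)), 5L)
  keptIds <- snpInfo(kept)$snp_id
  expect_equal(length(unique(comp[match(keptIds, colnames(d))])), 5L)
})

test_that("pruning is invariant to input SNP order and keeps every chromosome", {
  gs <- simGenotypeSpec(nChromosomes = 3, snpsPerChromosome = 40,
                        ldBlockMeanSnps = 6, missingRate = 0, hetRate = 0)
  p <- simulateGenotypes(gs, 120, seed = 5)
  k1 <- snpInfo(pruneByLD(p, seed = 9))$snp_id
  # rebuild the panel with shuffled columns; constructor restores map order
  d <- dosageMatrix(p)
  info <- snpInfo(p)
  withr::with_seed(1, o <- sample(ncol(d)))
  p2 <- GenotypePanel(d[, o], info[o, ])
  k2 <- snpInfo(pruneByLD(p2, seed = 9))$snp_id
  expect_identical(k1, k2)
  expect_setequal(unique(snpInfo(pruneByLD(p, seed = 9))$chrom),
                  unique(info$chrom))
})

test_that("VanRaden kinship matches hand arithmetic and its identities", {
  # 3 genotypes x 2 SNPs: dosages ((0,2),(2,0),(1,1))
  d <- matrix(c(0, 2, 1, 2, 0, 1), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  K <- as.matrix(vanRadenKinship(toyPanel(d)))
  # p = (0.5, 0.5); Z rows (-1,1),(1,-1),(0,0); denom = 2(0.25+0.25) = 1
  expect_equal(unname(K), matrix(c(2, -2, 0, -2, 2, 0, 0, 0, 0), 3, 3))
  expect_equal(rowSums(K), c(g1 = 0, g2 = 0, g3 = 0))

  # duplicated genotypes give equal rows with K[i,j] = K[i,i]
  d2 <- rbind(d, g4 = d["g1", ])
  K2 <- as.matrix(vanRadenKinship(toyPanel(d2)))
  expect_equal(K2["g1", ], K2["g4", ])
  expect_equal(K2["g1", "g4"], K2["g1", "g1"])
  expect_error(vanRadenKinship(toyPanel(d[, 1, drop = FALSE])), "2 SNPs")
})

test_that("kinship is symmetric PSD on simulated panels", {
  gs <- simGenotypeSpec(nChromosomes = 4, snpsPerChromosome = 40)
  p <- imputeMissing(qcFilter(simulateGenotypes(gs, 80, seed = 21)), seed = 1)
  K <- as.matrix(vanRadenKinship(p))
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("leave-one-chromosome-out equals the manual subset", {
  gs <- simGenotypeSpec(nChromosomes = 21, snpsPerChromosome = 10,
                        missingRate = 0, hetRate = 0)
  p <- simulateGenotypes(gs, 50, seed = 2)
  l <- locoKinship(p, "4B")
  expect_identical(excludedChromosome(l), "4B")
  manual <- p[SummarizedExperiment::rowData(p)$chrom != "4B", ]
  expect_equal(as.matrix(l), as.matrix(vanRadenKinship(manual)))
  expect_equal(nSnpsUsed(l), 200L)
  one <- p[SummarizedExperiment::rowData(p)$chrom == "1A", ]
  expect_error(locoKinship(one, "1A"), "2 chromosomes")
  expect_equal(as.matrix(vanRadenKinship(p, excludeChromosome = NULL)),
               as.matrix(vanRadenKinship(p)))
})

test_that("vcf and csv round trips preserve the panel", {
  gs <- simGenotypeSpec(nChromosomes = 2, snpsPerChromosome = 15,
                        missingRate = 0.1, hetRate = 0.05)
  p <- simulateGenotypes(gs, 25, seed = 31)
  tmp <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(p, tmp)
  p2 <- readGenotypeVcf(tmp)
  expect_equal(dosageMatrix(p2), dosageMatrix(p))
  expect_equal(snpInfo(p2)[, c("snp_id", "chrom", "pos")],
               snpInfo(p)[, c("snp_id", "chrom", "pos")])
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeDosageCsv(p, f1, f2)
  p3 <- readDosageCsv(f1, f2)
  expect_equal(dosageMatrix(p3), dosageMatrix(p))
  unlink(c(tmp, f1, f2))
})
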