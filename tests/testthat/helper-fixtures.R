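# Fixtures built in code: tiny panels, identity kinship, balanced records.

toyPanel <- function(dosage, chrom = rep("1A", ncol(dosage)), pos = NULL) {
  if (is.null(pos)) {
    pos <- integer(ncol(dosage))
    for (cc in unique(chrom)) {
      i <- which(chrom == cc)
      pos[i] <- seq(1e5, by = 1e5, length.out = length(i))
    }
  }
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  GenotypePanel(dosage,
                data.frame(snp_id = colnames(dosage), chrom = chrom,
                           pos = pos, stringsAsFactors = FALSE))
}

identityKinship <- function(g, ids = sprintf("G%03d", seq_len(g))) {
  K <- diag(g)
  rownames(K) <- colnames(K) <- ids
  methods::new("KinshipMatrix", mat = K,
               excludedChromosome = NA_character_, nSnpsUsed = 1L)
}

# balanced split-plot records without sub-blocks, K = identity truth
balancedRecords <- function(g = 40, r = 3, years = 1, vg = 4, vgt = 2,
                            vgy = 0, ve = 3, seed = 1) {
  ids <- sprintf("G%03d", seq_len(g))
  rec <- expand.grid(genotype = ids,
                     year = paste0("Y", seq_len(years)),
                     replicate = paste0("R", seq_len(r)),
                     treatment = c("NS", "S"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    G <- stats::rnorm(g, 0, sqrt(vg))
    GT <- matrix(stats::rnorm(g * 2, 0, sqrt(vgt)), g)
    GY <- matrix(stats::rnorm(g * years, 0, sqrt(vgy)), g)
    e <- stats::rnorm(nrow(rec), 0, sqrt(ve))
  })
  gi <- match(rec$genotype, ids)
  ti <- as.integer(rec$treatment == "S") + 1L
  yi <- as.integer(factor(rec$year))
  rec$value <- 10 + 0.5 * (rec$replicate == "R2") +
    1.5 * (rec$treatment == "S") + G[gi] + GT[cbind(gi, ti)] +
    GY[cbind(gi, yi)] + e
  rec$subblock <- 1L
  attr(rec, "truth") <- list(g = G, gt = GT)
  rec
}

# expected-mean-square (ANOVA) estimators for the balanced single-year
# split-plot with K = identity: the independent closed-form oracle
emsComponents <- function(rec) {
  r <- length(unique(rec$replicate))
  t <- length(unique(rec$treatment))
  a <- stats::aov(value ~ replicate * treatment + genotype +
                    genotype:treatment, data = rec)
  s <- summary(a)[[1]]
  rn <- trimws(rownames(s))
  ms <- s[, "Mean Sq"]
  msG <- ms[rn == "genotype"]
  msGT <- ms[grepl("genotype", rn) & grepl("treatment", rn)]
  msE <- ms[rn == "Residuals"]
  c(g = (msG - msGT) / (r * t), gt = (msGT - msE) / r, residual = msE)
}
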