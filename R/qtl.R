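# Grouping significant SNPs into QTL by LD clustering and delimiting
# physical confidence intervals extended by local LD decay.

#' Cluster significant SNPs into candidate QTL
#'
#' Per chromosome, average-linkage hierarchical clustering of the
#' significant SNPs on the distance 1 - r2; the tree is cut at one
#' "critical LD unit", read as height `1 - criticalLd` (default 0.76; the
#' alternative reading, cutting at height `criticalLd`, is available via
#' `cutAt = "critical"`).  Each cluster is one candidate QTL.
#'
#' @param sigSnps SNP ids (must exist in the panel).
#' @param panel an imputed [GenotypePanel-class].
#' @param criticalLd the critical r2 level (default 0.24).
#' @param cutAt `"one-minus"` (height 1 - criticalLd) or `"critical"`.
#' @return data.frame: `snp_id`, `chrom`, `pos`, `qtl` (cluster label).
#' @export
clusterSignificantSnps <- function(sigSnps, panel, criticalLd = 0.24,
                                   cutAt = c("one-minus", "critical")) {
  cutAt <- match.arg(cutAt)
  stopifnot(length(sigSnps) >= 1)
  map <- snpInfo(panel)
  i <- match(sigSnps, map$snp_id)
  if (anyNA(i)) stop("unknown SNP id: ",
                     paste(sigSnps[is.na(i)], collapse = ", "))
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (anyNA(d)) stop("clustering requires an imputed panel")
  h <- if (cutAt == "one-minus") 1 - criticalLd else criticalLd
  out <- lapply(split(i, map$chrom[i]), function(idx) {
    cl <- if (length(idx) == 1L) 1L else {
      r2 <- .ldMatrix(d[idx, , drop = FALSE])
      r2[is.na(r2)] <- 0
      diag(r2) <- 1
      stats::cutree(stats::hclust(stats::as.dist(1 - r2),
                                  method = "average"), h = h)
    }
    data.frame(snp_id = map$snp_id[idx], chrom = map$chrom[idx],
               pos = map$pos[idx],
               qtl = paste0(map$chrom[idx], ".", cl),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$pos), ]
}

# Hill-Weir expectation of r2 at recombination intensity C = beta * d,
# with the finite-sample term for n sampled lines.
.hillWeirER2 <- function(C, n) {
  (10 + C) / ((2 + C) * (11 + C)) *
    (1 + (3 + C) * (12 + 12 * C + C^2) / (n * (2 + C) * (11 + C)))
}

#' Local LD decay distance
#'
#' Least-squares fit of the expected r2 versus distance curve (Hill-Weir
#' drift expectation with finite-sample correction) on SNP pairs within
#' `windowBp` of `center` (whole chromosome when `center` is `NULL`);
#' returns the distance at which the expected r2 drops below `criticalLd`.
#' With fewer than 20 pairs in the window the fit falls back to the whole
#' chromosome (attribute `"fallback"`); if the model fit degenerates the
#' empirical binned-median crossing is used (attribute `"method"`).
#'
#' @param panel an imputed [GenotypePanel-class].
#' @param chromosome chromosome label.
#' @param windowBp window width in bp (default 10 Mb).
#' @param criticalLd critical r2 level (default 0.24).
#' @param center window centre in bp, or `NULL`.
#' @return decay distance in bp (0 when expected r2 is below the critical
#'   level at any positive distance).
#' @export
ldDecay <- function(panel, chromosome, windowBp = 1e7, criticalLd = 0.24,
                    center = NULL) {
  map <- snpInfo(panel)
  d <- SummarizedExperiment::assay(panel, "dosage")
  if (anyNA(d)) stop("LD decay requires an imputed panel")
  onC <- which(map$chrom == chromosome)
  if (!length(onC)) stop("unknown chromosome label: ", chromosome)
  inWin <- onC
  fallback <- FALSE
  if (!is.null(center)) {
    inWin <- onC[abs(map$pos[onC] - center) <= windowBp / 2]
    if (length(inWin) < 2 || choose(length(inWin), 2) < 20) {
      inWin <- onC
      fallback <- TRUE
    }
  }
  sdv <- apply(d[inWin, , drop = FALSE], 1L, stats::sd)
  inWin <- inWin[sdv > 0]
  if (length(inWin) < 2) stop("not enough polymorphic SNPs for LD decay")
  r2 <- .ldMatrix(d[inWin, , drop = FALSE])
  dist <- abs(outer(map$pos[inWin], map$pos[inWin], "-"))
  ut <- upper.tri(r2)
  rr <- r2[ut]
  dd <- dist[ut]
  keep <- is.finite(rr)
  rr <- rr[keep]
  dd <- dd[keep]
  n <- ncol(d)

  sse <- function(logBeta) {
    e <- .hillWeirER2(exp(logBeta) * dd, n)
    sum((rr - e)^2)
  }
  opt <- stats::optimize(sse, interval = c(-25, 8))
  beta <- exp(opt$minimum)
  e0 <- .hillWeirER2(0, n)
  decay <- if (e0 <= criticalLd) 0 else {
    f <- function(x) .hillWeirER2(beta * x, n) - criticalLd
    upper <- max(dd, 1)
    if (f(upper) > 0) upper else
      stats::uniroot(f, c(.Machine$double.eps, upper))$root
  }
  method <- "hill-weir"
  # degenerate fit guard: fall back to the empirical binned-median crossing
  if (!is.finite(decay)) {
    method <- "empirical"
    br <- stats::quantile(dd, probs = seq(0, 1, 0.1))
    bins <- cut(dd, unique(br), include.lowest = TRUE)
    med <- tapply(rr, bins, stats::median)
    mid <- tapply(dd, bins, stats::median)
    below <- which(med < criticalLd)
    decay <- if (length(below)) mid[below[1]] else max(dd)
  }
  if (decay < 1) decay <- 0
  structure(as.numeric(decay), fallback = fallback, method = method)
}

#' QTL interval from a SNP cluster and a decay distance
#'
#' Boundaries are the minimal and maximal member positions extended by
#' `decayBp` on each side, clipped to `[1, chromLength]`.
#'
#' @param cluster one cluster's rows from [clusterSignificantSnps()].
#' @param decayBp LD-decay extension in bp.
#' @param lod optional named vector of -log10(p) used to pick the lead SNP
#'   (first member otherwise).
#' @param chromLength chromosome length for clipping (default `Inf`).
#' @return one-row data.frame: `qtl`, `chrom`, `nSnps`, `minBp`, `maxBp`,
#'   `leadSnp`, `decayBp`.
#' @export
qtlBoundaries <- function(cluster, decayBp, lod = NULL, chromLength = Inf) {
  stopifnot(nrow(cluster) >= 1)
  lead <- if (!is.null(lod)) {
    l <- lod[cluster$snp_id]
    cluster$snp_id[which.max(l)]
  } else cluster$snp_id[1]
  data.frame(qtl = cluster$qtl[1], chrom = cluster$chrom[1],
             nSnps = nrow(cluster),
             minBp = max(1, min(cluster$pos) - decayBp),
             maxBp = min(chromLength, max(cluster$pos) + decayBp),
             leadSnp = lead, decayBp = as.numeric(decayBp),
             stringsAsFactors = FALSE)
}

#' Delimit QTL from a GWAS result
#'
#' Selects the SNPs whose -log10(p) for the chosen test exceeds the
#' threshold, clusters them per chromosome at the critical LD level,
#' estimates the local LD decay in a window centred on each cluster and
#' returns the extended physical intervals.
#'
#' @param gwas a [GwasResult-class].
#' @param panel the imputed [GenotypePanel-class] used for the scan.
#' @param test `"interaction"` or `"main"`.
#' @param threshold -log10(p) significance threshold (e.g.
#'   [gaoThreshold()]).
#' @param criticalLd critical r2 (default 0.24).
#' @param windowBp LD-decay window (default 10 Mb).
#' @return data.frame of QTL intervals (possibly empty), one row per QTL.
#' @export
delimitQtl <- function(gwas, panel, test = c("interaction", "main"),
                       threshold, criticalLd = 0.24, windowBp = 1e7) {
  test <- match.arg(test)
  tab <- gwasTable(gwas)
  lodCol <- if (test == "interaction") "lodInt" else "lodMain"
  sig <- tab$snp_id[!is.na(tab[[lodCol]]) & tab[[lodCol]] >= threshold]
  if (!length(sig))
    return(data.frame(qtl = character(), chrom = character(),
                      nSnps = integer(), minBp = numeric(),
                      maxBp = numeric(), leadSnp = character(),
                      decayBp = numeric(), stringsAsFactors = FALSE))
  cl <- clusterSignificantSnps(sig, panel, criticalLd = criticalLd)
  lod <- stats::setNames(tab[[lodCol]], tab$snp_id)
  lens <- chromosomeLengths(panel)
  out <- lapply(split(cl, cl$qtl), function(cluster) {
    centre <- mean(range(cluster$pos))
    dec <- ldDecay(panel, cluster$chrom[1], windowBp = windowBp,
                   criticalLd = criticalLd, center = centre)
    qtlBoundaries(cluster, dec, lod = lod,
                  chromLength = lens[[cluster$chrom[1]]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$minBp), ]
}
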