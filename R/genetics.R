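#' Per-SNP allele statistics
#'
#' A2 allele frequency over non-missing calls, minor allele frequency,
#' call rate and the three genotype counts.
#'
#' @param g a [GenotypeMatrix-class].
#' @param j SNP column index.
#' @return list with `a2Freq`, `maf` (`NA` when all calls are missing),
#'   `callRate`, and `counts` = c(n0, n1, n2).
#' @export
alleleStats <- function(g, j) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- g@dosage[, j]
  obs <- d[!is.na(d)]
  counts <- c(n0 = sum(obs == 0L), n1 = sum(obs == 1L), n2 = sum(obs == 2L))
  if (!length(obs))
    return(list(a2Freq = NA_real_, maf = NA_real_, callRate = 0,
                counts = counts))
  f <- (counts[["n1"]] + 2 * counts[["n2"]]) / (2 * length(obs))
  list(a2Freq = f, maf = min(f, 1 - f),
       callRate = length(obs) / length(d), counts = counts)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test: conditioning on the observed allele counts, the
#' p-value is the sum of the probabilities of every attainable heterozygote
#' count whose conditional probability does not exceed that of the observed
#' count.  Probabilities are evaluated in log space through the standard
#' recurrence over heterozygote counts, so large samples stay stable.
#'
#' @param n0,n1,n2 genotype counts (hom A1, het, hom A2).
#' @return p-value in (0, 1].
#' @export
hweExact <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0)) stop("genotype counts must be non-negative")
  n <- n0 + n1 + n2
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2 * n0 + n1
  r <- min(nA, 2 * n2 + n1)          # rare allele count
  hs <- seq.int(r %% 2, r, by = 2)   # attainable heterozygote counts
  lp <- numeric(length(hs))
  if (length(hs) > 1L) {
    for (t in seq_len(length(hs) - 1L)) {
      h <- hs[t]
      homR <- (r - h) / 2            # rare-homozygote count at h
      homC <- (2 * n - r - h) / 2    # common-homozygote count at h
      lp[t + 1L] <- lp[t] + log(4 * homR * homC) -
        log((h + 2) * (h + 1))
    }
  }
  lp <- lp - max(lp)
  lp <- lp - log(sum(exp(lp)))       # normalize
  lobs <- lp[match(n1, hs)]
  if (is.na(lobs)) stop("observed heterozygote count inconsistent with alleles")
  min(1, sum(exp(lp[lp <= lobs + 1e-9])))
}

#' Genotype quality-control filtering
#'
#' Filters are applied in a fixed, documented order so that the report's
#' counts are reproducible: (1) variants with any multi-character allele
#' code; (2) samples with missing fraction above `mindMax`; (3) SNPs with
#' missing fraction above `genoMax` (recomputed on the remaining samples);
#' (4) SNPs with minor allele frequency below `mafMin` (an all-missing SNP
#' fails here); (5) SNPs with HWE exact-test p below `hwePMin`.
#'
#' @param g a [GenotypeMatrix-class].
#' @param thresholds a [QCThresholds-class].
#' @return list with `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `report`, a data.frame of per-step removal counts plus the surviving
#'   totals as attributes `nInput`, `mInput`, `n`, `m`.
#' @export
qcFilter <- function(g, thresholds = qcThresholds()) {
  stopifnot(is(g, "GenotypeMatrix"), is(thresholds, "QCThresholds"))
  d <- g@dosage
  snps <- g@snps; samples <- g@samples
  nIn <- nrow(d); mIn <- ncol(d)
  steps <- data.frame(step = c("snps_only", "mind", "geno", "maf", "hwe"),
                      axis = c("snp", "sample", "snp", "snp", "snp"),
                      removed = 0L, stringsAsFactors = FALSE)

  if (thresholds@snpsOnly && ncol(d)) {
    keep <- nchar(snps$a1) == 1L & nchar(snps$a2) == 1L
    steps$removed[1L] <- sum(!keep)
    d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]
  }
  if (nrow(d)) {
    missFrac <- if (ncol(d)) rowMeans(is.na(d)) else rep(0, nrow(d))
    keep <- missFrac <= thresholds@mindMax
    steps$removed[2L] <- sum(!keep)
    d <- d[keep, , drop = FALSE]; samples <- samples[keep, , drop = FALSE]
  }
  if (ncol(d)) {
    missFrac <- if (nrow(d)) colMeans(is.na(d)) else rep(0, ncol(d))
    keep <- missFrac <= thresholds@genoMax
    steps$removed[3L] <- sum(!keep)
    d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]
  }
  if (ncol(d)) {
    maf <- apply(d, 2L, function(col) {
      obs <- col[!is.na(col)]
      if (!length(obs)) return(NA_real_)
      f <- sum(obs) / (2 * length(obs))
      min(f, 1 - f)
    })
    keep <- !is.na(maf) & maf >= thresholds@mafMin
    steps$removed[4L] <- sum(!keep)
    d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]
  }
  if (ncol(d)) {
    hweP <- apply(d, 2L, function(col) {
      obs <- col[!is.na(col)]
      if (!length(obs)) return(1)
      hweExact(sum(obs == 0L), sum(obs == 1L), sum(obs == 2L))
    })
    keep <- hweP >= thresholds@hwePMin
    steps$removed[5L] <- sum(!keep)
    d <- d[, keep, drop = FALSE]; snps <- snps[keep, , drop = FALSE]
  }
  if (!ncol(d) || !nrow(d))
    warning("QC filtering removed all ",
            if (!ncol(d)) "SNPs" else "samples")
  out <- new("GenotypeMatrix", dosage = d, snps = snps, samples = samples)
  attr(steps, "nInput") <- nIn; attr(steps, "mInput") <- mIn
  attr(steps, "n") <- nrow(d); attr(steps, "m") <- ncol(d)
  list(genotypes = out, report = steps)
}

#' Write a QC report as TSV
#' @param report the data.frame returned by [qcFilter()].
#' @param path output file.
#' @export
writeQCReport <- function(report, path) {
  tab <- rbind(report,
               data.frame(step = "surviving", axis = "both",
                          removed = NA_integer_))
  tab$n <- c(rep(NA_integer_, nrow(report)), attr(report, "n"))
  tab$m <- c(rep(NA_integer_, nrow(report)), attr(report, "m"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Leading genetic principal components
#'
#' Standard population-stratification PCs: missing dosages are mean-imputed
#' per SNP, each SNP column is centered at `2f` and scaled by
#' `sqrt(2f(1-f))` (monomorphic SNPs are dropped), and the leading
#' eigenvectors of the sample-space covariance of the standardized matrix
#' are returned as orthonormal, unit-length score vectors with the same
#' deterministic sign rule used for the morphometric components.
#'
#' @param g a (post-QC) [GenotypeMatrix-class].
#' @param nPcs number of components (default 10).
#' @return numeric matrix n x nPcs with columns `PC1..PCnPcs`.
#' @export
geneticPCs <- function(g, nPcs = 10L) {
  stopifnot(is(g, "GenotypeMatrix"))
  d <- g@dosage
  n <- nrow(d)
  f <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  d <- d[, poly, drop = FALSE]; f <- f[poly]
  m <- ncol(d)
  if (nPcs >= min(n, m))
    stop("nPcs must be smaller than min(samples, polymorphic SNPs) = ",
         min(n, m))
  G <- sweep(d, 2L, 2 * f)
  G[is.na(G)] <- 0                       # mean imputation after centering
  G <- sweep(G, 2L, sqrt(2 * f * (1 - f)), `/`)
  eg <- eigen(tcrossprod(G) / m, symmetric = TRUE)
  scores <- .applySignConvention(eg$vectors[, seq_len(nPcs), drop = FALSE])
  colnames(scores) <- sprintf("PC%d", seq_len(nPcs))
  rownames(scores) <- g@samples$iid
  scores
}
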