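#' Build a covariate table
#'
#' @param age numeric, age in months.
#' @param sex integer coded 0 (female) / 1 (male).
#' @param pcs n x nPcs matrix of genetic principal components.
#' @param ids subject ids aligned with the trait rows.
#' @return data.frame with rownames `ids` and columns `age`, `sex`,
#'   `PC1..`.
#' @export
covariateTable <- function(age, sex, pcs, ids = NULL) {
  tab <- data.frame(age = as.numeric(age), sex = as.numeric(sex))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(colnames(pcs)))
      colnames(pcs) <- sprintf("PC%d", seq_len(ncol(pcs)))
    tab <- cbind(tab, as.data.frame(pcs))
  }
  if (!is.null(ids)) rownames(tab) <- ids
  tab
}

#' Residualize trait columns against covariates
#'
#' Replaces every trait column by its least-squares residual against the
#' design matrix `[1, covariates]`, removing (exactly, in-sample) any
#' linear association between traits and the covariates.
#'
#' @param scores n x k trait matrix (component scores).
#' @param covars data.frame or matrix of covariates (rows aligned; when
#'   both carry ids, they are matched by name).
#' @return residual trait matrix, same shape as `scores`.
#' @export
residualize <- function(scores, covars) {
  scores <- as.matrix(scores)
  cv <- as.matrix(covars)
  if (!is.null(rownames(scores)) && !is.null(rownames(cv)) &&
      !identical(rownames(scores), rownames(cv))) {
    if (!all(rownames(scores) %in% rownames(cv)))
      stop("covariate rows do not cover all subjects")
    cv <- cv[rownames(scores), , drop = FALSE]
  }
  if (nrow(cv) != nrow(scores))
    stop("covariates and traits have different row counts")
  if (any(is.na(cv))) stop("covariates contain missing values")
  X <- cbind(`(Intercept)` = 1, cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qrX, scores)
  dimnames(res) <- dimnames(scores)
  res
}

#' Per-SNP canonical correlation test
#'
#' With a single SNP on one side, canonical correlation analysis reduces to
#' the multiple correlation of the trait block with the dosage: `r^2` is
#' the R-squared of regressing the centered dosage on the centered traits,
#' Wilks' lambda is `1 - r^2`, and
#' `F = ((n - k - 1)/k) * r^2/(1 - r^2)` is tested against
#' `F(k, n - k - 1)`.  Loadings are structure correlations: the Pearson
#' correlation of each trait with the fitted canonical variate (the
#' trait-side linear combination).
#'
#' Missing dosages are handled per SNP by complete-case removal.  SNPs with
#' too few complete cases (`n_used <= k + 1`) or a constant dosage after
#' removal are untestable: `p` is `NA`.
#'
#' @param dosage numeric vector of length n (0/1/2 with `NA` missing).
#' @param traits n x k numeric matrix (residualized component scores).
#' @return list with `nUsed`, `r`, `wilks`, `F`, `df1`, `df2`, `p`,
#'   `loadings` (length k).
#' @export
ccaSnp <- function(dosage, traits) {
  traits <- as.matrix(traits)
  k <- ncol(traits)
  ok <- !is.na(dosage)
  nUsed <- sum(ok)
  untestable <- list(nUsed = nUsed, r = NA_real_, wilks = NA_real_,
                     F = NA_real_, df1 = k, df2 = nUsed - k - 1L,
                     p = NA_real_, loadings = rep(NA_real_, k),
                     coefs = rep(NA_real_, k))
  if (nUsed <= k + 1L) return(untestable)
  d <- dosage[ok]
  if (length(unique(d)) < 2L) return(untestable)
  Tm <- traits[ok, , drop = FALSE]
  d <- d - mean(d)
  Tm <- sweep(Tm, 2L, colMeans(Tm))
  fit <- lm.fit(Tm, d)
  u <- fit$fitted.values                 # canonical variate (trait side)
  ssTot <- sum(d^2)
  r2 <- if (ssTot > 0) sum(u^2) / ssTot else 0
  r2 <- min(max(r2, 0), 1)
  df1 <- k; df2 <- nUsed - k - 1L
  Fstat <- if (r2 >= 1) Inf else (df2 / df1) * r2 / (1 - r2)
  p <- max(pf(Fstat, df1, df2, lower.tail = FALSE), 1e-300)
  su <- sd(u)
  loadings <- if (su > 0)
    as.vector(cor(Tm, u)) else rep(0, k)
  loadings[is.na(loadings)] <- 0
  coefs <- fit$coefficients        # trait-side canonical weights
  coefs[is.na(coefs)] <- 0
  list(nUsed = nUsed, r = sqrt(r2), wilks = 1 - r2, F = Fstat,
       df1 = df1, df2 = df2, p = p, loadings = loadings,
       coefs = unname(coefs))
}

#' Multivariate genome-wide scan
#'
#' Applies [ccaSnp()] to every SNP against the residualized component
#' scores.  The result table is sorted by (chromosome, position); the
#' per-SNP loading vectors are attached as a `loadings` attribute
#' (m x k matrix, rows aligned with the table).
#'
#' @param g a post-QC [GenotypeMatrix-class].
#' @param traits n x k residualized score matrix, rows aligned with the
#'   genotype samples.
#' @param verbose log progress every 1000 SNPs.
#' @return data.frame (`GwasTable`) with columns chrom, pos, id, nUsed, r,
#'   wilks, F, df1, df2, p.
#' @export
gwasScan <- function(g, traits, verbose = FALSE) {
  stopifnot(is(g, "GenotypeMatrix"))
  traits <- as.matrix(traits)
  d <- g@dosage
  if (nrow(d) != nrow(traits))
    stop("genotypes and traits have different sample counts")
  m <- ncol(d); k <- ncol(traits)
  if (anyDuplicated(g@snps$id)) stop("duplicate SNP ids")
  res <- vector("list", m)
  for (j in seq_len(m)) {
    res[[j]] <- ccaSnp(d[, j], traits)
    if (verbose && j %% 1000L == 0L)
      message("scanned ", j, "/", m, " SNPs")
  }
  tab <- data.frame(chrom = g@snps$chrom, pos = g@snps$pos, id = g@snps$id,
                    nUsed = vapply(res, `[[`, 0L, "nUsed"),
                    r = vapply(res, `[[`, 0, "r"),
                    wilks = vapply(res, `[[`, 0, "wilks"),
                    F = vapply(res, `[[`, 0, "F"),
                    df1 = vapply(res, `[[`, 0L, "df1"),
                    df2 = vapply(res, `[[`, 0L, "df2"),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  L <- do.call(rbind, lapply(res, `[[`, "loadings"))
  B <- do.call(rbind, lapply(res, `[[`, "coefs"))
  ord <- order(.chromRank(tab$chrom), tab$pos)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "loadings") <- L[ord, , drop = FALSE]
  attr(tab, "coefs") <- B[ord, , drop = FALSE]
  nUntest <- sum(is.na(tab$p))
  if (nUntest == nrow(tab) && nrow(tab))
    warning("no testable SNPs in scan")
  if (verbose && nUntest)
    message(nUntest, " untestable SNP(s) excluded from p-values")
  tab
}

# numeric chromosomes first in numeric order, then others lexically
.chromRank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  r <- rank(num, na.last = "keep", ties.method = "min")
  isChr <- !is.na(num)
  out <- numeric(length(chrom))
  out[isChr] <- num[isChr]
  if (any(!isChr)) {
    lex <- match(chrom[!isChr], sort(unique(chrom[!isChr])))
    out[!isChr] <- max(c(0, num[isChr])) + lex
  }
  out
}

#' Select components linked to a SNP
#'
#' Applies the absolute-loading threshold rule: components with
#' `|loading| > primary` are selected; when none passes, the rule falls
#' back to `|loading| > fallback`.  May return an empty set.
#'
#' @param loadings numeric vector of per-component structure correlations.
#' @param primary primary threshold (default 0.2).
#' @param fallback fallback threshold (default 0.15).
#' @return integer vector of selected (1-based) component indices.
#' @export
selectComponents <- function(loadings, primary = 0.2, fallback = 0.15) {
  a <- abs(loadings)
  a[is.na(a)] <- 0
  sel <- which(a > primary)
  if (!length(sel)) sel <- which(a > fallback)
  sel
}

#' Manhattan table and figure
#'
#' Builds the plot-ready table (`-log10(p)` against a cumulative genome
#' coordinate, chromosomes ordered numerically then lexically) and
#' optionally writes a PNG Manhattan plot with a horizontal reference at
#' the significance line.  Untestable SNPs (`NA` p) are excluded.
#'
#' @param tab a GwasTable from [gwasScan()].
#' @param significanceLine genome-wide significance level (default 1e-8).
#' @param file optional PNG path; when `NULL` no figure is written.
#' @return data.frame with columns chrom, pos, id, p, logp, coord.
#' @export
manhattanTable <- function(tab, significanceLine = 1e-8, file = NULL) {
  if (!nrow(tab)) stop("empty GWAS table")
  keep <- !is.na(tab$p)
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no testable SNPs")
  ord <- order(.chromRank(tab$chrom), tab$pos)
  tab <- tab[ord, , drop = FALSE]
  chroms <- unique(tab$chrom)
  offset <- 0
  coord <- numeric(nrow(tab))
  gap <- max(tab$pos) * 0.02 + 1
  for (ch in chroms) {
    i <- tab$chrom == ch
    # strictly increasing within chromosome even at duplicate positions
    coord[i] <- offset + tab$pos[i] + seq_len(sum(i)) * 1e-9
    offset <- max(coord[i]) + gap
  }
  out <- data.frame(chrom = tab$chrom, pos = tab$pos, id = tab$id,
                    p = tab$p, logp = -log10(tab$p), coord = coord,
                    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 1400, height = 500)
    on.exit(grDevices::dev.off())
    cols <- c("grey30", "steelblue")[(match(out$chrom, chroms) %% 2L) + 1L]
    graphics::plot(out$coord, out$logp, pch = 20, col = cols,
                   xlab = "genome position", ylab = "-log10(p)",
                   main = "Manhattan plot", xaxt = "n")
    graphics::abline(h = -log10(significanceLine), col = "red", lty = 2)
    mids <- vapply(chroms, function(ch) mean(out$coord[out$chrom == ch]), 0)
    graphics::axis(1, at = mids, labels = chroms)
  }
  out
}

#' Write a GWAS table (and selected-SNP loadings) as TSV
#'
#' @param tab GwasTable from [gwasScan()].
#' @param path output TSV.
#' @param loadingsPath optional TSV for the per-SNP loading matrix.
#' @export
writeGwasTable <- function(tab, path, loadingsPath = NULL) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(loadingsPath)) {
    L <- attr(tab, "loadings")
    if (!is.null(L)) {
      out <- data.frame(id = tab$id, L)
      names(out) <- c("id", sprintf("comp%d", seq_len(ncol(L))))
      write.table(out, loadingsPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  invisible(NULL)
}
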