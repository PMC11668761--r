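#' Symbolic GLOBAL locality setting
#'
#' `GLOBAL` (infinite fraction) makes the locality kernel identically 1, so
#' the localized decomposition reduces exactly to standard PCA.
#' @export
GLOBAL <- Inf

#' Construct a locality parameter
#'
#' The kernel standard deviation is `fraction * diagonalMm`, where
#' `diagonalMm` is the bounding-box diagonal of the analysis mask (see
#' [boundingBoxDiagonal()]).  Kernel weights below
#' `exp(-truncationSigmaMult^2 / 2)` are truncated to 0 to keep the kernel
#' sparse; the default cutoff at 3 sigma drops weights under ~0.011.
#'
#' @param fraction positive real, or `GLOBAL` / `Inf` for standard PCA.
#' @param diagonalMm bounding-box diagonal in mm.
#' @param truncationSigmaMult kernel support cutoff in units of sigma.
#' @return A [LocalityParam-class].
#' @export
localityParam <- function(fraction, diagonalMm, truncationSigmaMult = 3) {
  if (is.character(fraction)) fraction <- parseFraction(fraction)
  if (is.infinite(fraction))
    return(new("LocalityParam", fraction = Inf, sigmaMm = Inf,
               truncationMm = Inf))
  if (!is.finite(diagonalMm) || diagonalMm <= 0)
    stop("diagonalMm must be positive and finite")
  sigma <- fraction * diagonalMm
  new("LocalityParam", fraction = fraction, sigmaMm = sigma,
      truncationMm = truncationSigmaMult * sigma)
}

#' Gaussian locality weight
#'
#' `exp(-d^2 / (2 sigma^2))`: the down-weighting applied to a covariance
#' entry between two features `d` mm apart.  An infinite sigma (the GLOBAL
#' setting) returns 1 for every distance.
#'
#' @param d non-negative distance(s) in mm.
#' @param sigmaMm kernel standard deviation in mm (> 0, may be `Inf`).
#' @return weight(s) in (0, 1].
#' @export
gaussianLocalityWeight <- function(d, sigmaMm) {
  if (any(d < 0)) stop("distances must be non-negative")
  if (length(sigmaMm) != 1L || is.na(sigmaMm) || sigmaMm <= 0)
    stop("sigmaMm must be a single positive value")
  if (is.infinite(sigmaMm)) return(rep(1, length(d)))
  exp(-d^2 / (2 * sigmaMm^2))
}

#' Sparse Gaussian kernel over a set of locations
#'
#' @param loc q x 3 matrix of mm locations.
#' @param sigma kernel sd (mm); `Inf` returns a dense all-ones matrix.
#' @param trunc support cutoff (mm); weights beyond it are stored as 0.
#' @return symmetric q x q Matrix with unit diagonal.
#' @noRd
.sparseKernel <- function(loc, sigma, trunc) {
  q <- nrow(loc)
  if (is.infinite(sigma))
    return(Matrix::Matrix(1, q, q))
  blk <- max(1L, floor(2e6 / max(q, 1L)))
  ii <- vector("list", 0L); jj <- vector("list", 0L); xx <- vector("list", 0L)
  t2 <- trunc^2
  for (s in seq(1L, q, by = blk)) {
    e <- min(q, s + blk - 1L)
    rows <- s:e
    # squared distances rows x all
    d2 <- outer(loc[rows, 1L], loc[, 1L], `-`)^2 +
          outer(loc[rows, 2L], loc[, 2L], `-`)^2 +
          outer(loc[rows, 3L], loc[, 3L], `-`)^2
    hit <- which(d2 <= t2, arr.ind = TRUE)
    ii[[length(ii) + 1L]] <- rows[hit[, 1L]]
    jj[[length(jj) + 1L]] <- hit[, 2L]
    xx[[length(xx) + 1L]] <- exp(-d2[hit] / (2 * sigma^2))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(q, q))
}

#' Build the feature-level locality kernel
#'
#' Entry (i, j) is [gaussianLocalityWeight()] of the distance between the
#' two features' voxel centers; pairs farther apart than the truncation
#' radius are stored as exact zeros.  The diagonal is exactly 1 and the
#' three axis features of one voxel have pairwise weight 1.  For the GLOBAL
#' parameter a dense all-ones matrix is returned (no truncation).
#'
#' Intended for inspection and small-problem verification; the model fit
#' never materializes this matrix at the feature level (it uses the
#' voxel-level kernel and the Hadamard mat-vec identity instead).
#'
#' @param locations p x 3 matrix of feature locations in mm.
#' @param param a [LocalityParam-class].
#' @return symmetric p x p Matrix.
#' @export
buildLocalityKernel <- function(locations, param) {
  stopifnot(is(param, "LocalityParam"))
  K <- .sparseKernel(as.matrix(locations), param@sigmaMm, param@truncationMm)
  # exact unit diagonal (guards against rounding in exp at d ~ 0)
  diag(K) <- 1
  K
}

#' Localized PCA of a deformation-field cohort
#'
#' Standard PCA diagonalizes the sample covariance `C` of the vectorized
#' fields; its components are spatially global.  Here `C` is manipulated
#' element-wise with a distance-based Gaussian kernel `K` of unit diagonal
#' (`C o K`, the Hadamard product), which suppresses covariance between
#' spatially distant features and yields spatially compact components.
#' Because `K` is positive semidefinite with unit diagonal, `C o K` is PSD
#' (Schur product theorem) and has the same trace as `C`, so retained
#' variance fractions remain comparable across kernel widths.
#'
#' The manipulated matrix is never materialized: its action on a vector `v`
#' is `(C o K) v = (1/(n-1)) sum_r z_r o (K (z_r o v))` over centered
#' training rows `z_r`, and leading eigenpairs are extracted with an
#' iterative (ARPACK) solver, requesting components in doubling blocks until
#' the variance target is met.  With `fraction = GLOBAL` the kernel is
#' identically 1 and the fit is computed exactly in sample space (the n x n
#' Gram matrix), which is standard PCA.
#'
#' Components carry a deterministic sign: the entry of largest absolute
#' value (ties: lowest feature index) is made positive.  Eigenvalues below
#' `1e-12 * trace(C)` are treated as zero and dropped.
#'
#' @param cohort a [MorphCohort-class].
#' @param mask the [BrainMask-class] the cohort was assembled on (provides
#'   the bounding-box diagonal that scales the kernel width).
#' @param fraction positive locality fraction or `GLOBAL`.
#' @param varianceTarget fraction of total variance to retain (default 0.9).
#' @param trainFraction fraction of subjects used to fit (default 0.8); the
#'   held-out remainder is only projected, to report generalization.
#' @param truncationSigmaMult kernel cutoff in sigmas (default 3).
#' @param seed integer seed for the train/test split and solver start.
#' @return list with elements `model` ([LocalizedPCAModel-class]),
#'   `trainScores`, `heldoutScores` (matrices with subject-id rownames),
#'   and `heldoutRMSE` (reconstruction root-mean-square error per feature
#'   on the held-out subjects; `NA` when none).
#' @export
localizedPCA <- function(cohort, mask, fraction, varianceTarget = 0.90,
                         trainFraction = 0.8, truncationSigmaMult = 3,
                         seed = 0L) {
  stopifnot(is(cohort, "MorphCohort"), is(mask, "BrainMask"))
  if (is.character(fraction)) fraction <- parseFraction(fraction)
  if (varianceTarget <= 0 || varianceTarget > 1)
    stop("varianceTarget must lie in (0, 1]")
  X <- cohort@X
  n <- nrow(X); p <- ncol(X)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nTrain <- if (trainFraction >= 1) n else
    max(2L, as.integer(round(trainFraction * n)))
  if (nTrain < 2L) stop("need at least 2 training subjects")
  trainIdx <- sort(perm[seq_len(nTrain)])
  testIdx <- sort(perm[-seq_len(nTrain)])
  mu <- colMeans(X[trainIdx, , drop = FALSE])
  Z <- sweep(X[trainIdx, , drop = FALSE], 2L, mu)
  trace <- sum(Z^2) / (nTrain - 1L)
  param <- localityParam(fraction, boundingBoxDiagonal(mask),
                         truncationSigmaMult)

  if (trace <= 0) {
    ev <- numeric(0L); W <- matrix(0, p, 0L)
    retained <- 1; rankLim <- FALSE
  } else if (is.infinite(fraction)) {
    G <- tcrossprod(Z) / (nTrain - 1L)
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > 1e-12 * trace
    lam <- eg$values[keep]
    k <- .pickK(lam, varianceTarget * trace)
    rankLim <- is.na(k)
    if (rankLim) k <- length(lam)
    ev <- lam[seq_len(k)]
    W <- crossprod(Z, eg$vectors[, seq_len(k), drop = FALSE])
    W <- sweep(W, 2L, sqrt((nTrain - 1L) * ev), `/`)
    retained <- sum(ev) / trace
  } else {
    fit <- .localizedEigs(Z, cohort, param, varianceTarget * trace, trace,
                          seed)
    ev <- fit$values; W <- fit$vectors; rankLim <- fit$rankLimited
    retained <- sum(ev) / trace
  }

  W <- .applySignConvention(W)
  model <- new("LocalizedPCAModel", mean = mu, components = W,
               eigenvalues = ev, param = param, totalVariance = trace,
               retainedFraction = min(retained, 1), rankLimited = rankLim,
               nTrain = nTrain, locations = cohort@locations,
               featureVoxel = cohort@featureVoxel,
               featureAxis = cohort@featureAxis, dims = cohort@dims,
               spacing = cohort@spacing, maskIdx = cohort@maskIdx)
  if (rankLim)
    warning(sprintf("variance target %.3f not reachable; retained %.3f",
                    varianceTarget, retained))
  trainScores <- projectScores(model, X[trainIdx, , drop = FALSE])
  rownames(trainScores) <- cohort@subjectIds[trainIdx]
  if (length(testIdx)) {
    heldScores <- projectScores(model, X[testIdx, , drop = FALSE])
    rownames(heldScores) <- cohort@subjectIds[testIdx]
    recon <- tcrossprod(heldScores, W)
    resid <- sweep(X[testIdx, , drop = FALSE], 2L, mu) - recon
    heldRMSE <- sqrt(mean(resid^2))
  } else {
    heldScores <- matrix(0, 0L, ncol(W))
    heldRMSE <- NA_real_
  }
  list(model = model, trainScores = trainScores,
       heldoutScores = heldScores, heldoutRMSE = heldRMSE,
       trainIdx = trainIdx, heldoutIdx = testIdx)
}

# smallest k with cumsum(lam) >= target; NA if unreachable
.pickK <- function(lam, target) {
  if (!length(lam)) return(NA_integer_)
  cs <- cumsum(lam)
  k <- which(cs >= target * (1 - 1e-12))[1L]
  if (is.na(k)) NA_integer_ else k
}

.applySignConvention <- function(W) {
  if (!ncol(W)) return(W)
  for (j in seq_len(ncol(W))) {
    a <- abs(W[, j])
    i <- which(a == max(a))[1L]
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

#' Iterative leading eigenpairs of the Hadamard-manipulated covariance
#'
#' Driven by the identity `(C o K) v = (1/(n-1)) sum_r z_r o (K (z_r o v))`
#' evaluated at the voxel level: the kernel depends only on voxel centers,
#' so `K = Kv (x) J3` (J3 the 3x3 all-ones block for a voxel's axis
#' features), and each subject term collapses to one sparse `Kv` product.
#' @noRd
.localizedEigs <- function(Z, cohort, param, targetSum, trace, seed) {
  nTr <- nrow(Z); p <- ncol(Z)
  V <- length(cohort@maskIdx)
  voxLoc <- cohort@locations[seq(1L, p, by = 3L), , drop = FALSE]
  Kv <- .sparseKernel(voxLoc, param@sigmaMm, param@truncationMm)
  diag(Kv) <- 1
  ix <- seq(1L, p, by = 3L); iy <- ix + 1L; iz <- ix + 2L
  Zx <- Z[, ix, drop = FALSE]; Zy <- Z[, iy, drop = FALSE]
  Zz <- Z[, iz, drop = FALSE]
  scale <- 1 / (nTr - 1L)
  matvec <- function(v, extra = NULL) {
    S <- Zx * matrix(v[ix], nTr, V, byrow = TRUE) +
         Zy * matrix(v[iy], nTr, V, byrow = TRUE) +
         Zz * matrix(v[iz], nTr, V, byrow = TRUE)
    Tm <- as.matrix(S %*% Kv)
    y <- numeric(p)
    y[ix] <- colSums(Zx * Tm)
    y[iy] <- colSums(Zy * Tm)
    y[iz] <- colSums(Zz * Tm)
    y * scale
  }
  floorEv <- 1e-12 * trace
  nevMax <- p - 2L
  nev <- min(nevMax, max(16L, min(nTr, 64L)))
  repeat {
    ncv <- min(p, 2L * nev + 1L)
    set.seed(as.integer(seed) + 1L)
    res <- igraph::arpack(matvec, sym = TRUE,
                          options = list(n = p, nev = nev, ncv = ncv,
                                         which = "LA", maxiter = 10000))
    lam <- pmax(res$values, 0)
    keep <- lam > floorEv
    lam <- lam[keep]
    cs <- cumsum(lam)
    w <- which(cs >= targetSum * (1 - 1e-12))
    k <- if (length(w)) w[1L] else NA_integer_
    if (!is.na(k))
      return(list(values = lam[seq_len(k)],
                  vectors = res$vectors[, which(keep)[seq_len(k)], drop = FALSE],
                  rankLimited = FALSE))
    if (nev >= nevMax || sum(keep) < length(res$values))
      # spectrum numerically exhausted (trailing eigenvalues at the floor)
      return(list(values = lam,
                  vectors = res$vectors[, keep, drop = FALSE],
                  rankLimited = TRUE))
    nev <- min(nevMax, nev * 2L)
  }
}

#' Project data onto a fitted model
#'
#' Orthogonal projection of centered data onto the component basis:
#' `scores = (x - mean) %*% components`.
#'
#' @param model a [LocalizedPCAModel-class].
#' @param x a [MorphCohort-class], numeric matrix (n x p), numeric vector
#'   (length p), or [VectorField-class] on the model's grid.
#' @return numeric matrix n x k of component scores.
#' @export
projectScores <- function(model, x) {
  stopifnot(is(model, "LocalizedPCAModel"))
  M <- .asFeatureMatrix(model, x)
  if (ncol(M) != length(model@mean))
    stop("feature count ", ncol(M), " does not match model p = ",
         length(model@mean))
  sweep(M, 2L, model@mean) %*% model@components
}

.asFeatureMatrix <- function(model, x) {
  if (is(x, "MorphCohort")) {
    M <- x@X
    rownames(M) <- x@subjectIds
    M
  } else if (is(x, "VectorField")) {
    nvox <- prod(model@dims)
    dat <- x@data
    Mv <- cbind(dat[model@maskIdx], dat[model@maskIdx + nvox],
                dat[model@maskIdx + 2L * nvox])
    matrix(as.vector(t(Mv)), nrow = 1L)
  } else if (is.matrix(x)) x
  else matrix(x, nrow = 1L)
}

#' Reconstruct a field vector from component scores
#'
#' `mean + components %*% scores`: the point of the model's affine subspace
#' addressed by the scores.
#'
#' @param model a [LocalizedPCAModel-class].
#' @param scores numeric vector of length k, or an n x k matrix.
#' @return numeric vector of length p (or n x p matrix).
#' @export
reconstructField <- function(model, scores) {
  stopifnot(is(model, "LocalizedPCAModel"))
  k <- ncol(model@components)
  if (is.matrix(scores)) {
    if (ncol(scores) != k) stop("scores must have k = ", k, " columns")
    sweep(tcrossprod(scores, model@components), 2L, model@mean, `+`)
  } else {
    if (length(scores) != k) stop("scores must have length k = ", k)
    model@mean + as.vector(model@components %*% scores)
  }
}

#' Sample a deformation field along one component axis
#'
#' Generates the field `mean + alpha * sqrt(lambda_j) * v_j`: `alpha` is in
#' units of the component's standard deviation, so `alpha = 2` walks two
#' SDs of the cohort's variation along component `j`.  Voxels outside the
#' mask are 0.
#'
#' @param model a [LocalizedPCAModel-class].
#' @param componentIndex 1-based component index.
#' @param alpha displacement along the axis in SD units.
#' @return A [VectorField-class] on the model's grid.
#' @export
sampleComponent <- function(model, componentIndex, alpha) {
  stopifnot(is(model, "LocalizedPCAModel"))
  k <- ncol(model@components)
  if (componentIndex < 1L || componentIndex > k)
    stop("componentIndex must be in 1..", k)
  s <- numeric(k)
  s[componentIndex] <- alpha * sqrt(model@eigenvalues[componentIndex])
  v <- reconstructField(model, s)
  vectorField(.vectorToGrid(v, model@dims, model@maskIdx),
              spacing = model@spacing)
}

#' Serialize / restore a fitted model
#'
#' The archive is a single RDS file holding a versioned schema (mean,
#' components, eigenvalues, locality parameter, feature geometry).
#'
#' @param model a [LocalizedPCAModel-class].
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "LocalizedPCAModel"))
  obj <- list(schema = "locmorph-model-1",
              mean = model@mean, components = model@components,
              eigenvalues = model@eigenvalues,
              fraction = model@param@fraction, sigmaMm = model@param@sigmaMm,
              truncationMm = model@param@truncationMm,
              totalVariance = model@totalVariance,
              retainedFraction = model@retainedFraction,
              rankLimited = model@rankLimited, nTrain = model@nTrain,
              locations = model@locations, featureVoxel = model@featureVoxel,
              featureAxis = model@featureAxis, dims = model@dims,
              spacing = model@spacing, maskIdx = model@maskIdx)
  saveRDS(obj, path)
  invisible(NULL)
}

#' @rdname saveModel
#' @return `loadModel` returns the restored [LocalizedPCAModel-class].
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "locmorph-model-1"))
    stop("unrecognized model schema: ", obj$schema)
  new("LocalizedPCAModel", mean = obj$mean, components = obj$components,
      eigenvalues = obj$eigenvalues,
      param = new("LocalityParam", fraction = obj$fraction,
                  sigmaMm = obj$sigmaMm, truncationMm = obj$truncationMm),
      totalVariance = obj$totalVariance,
      retainedFraction = obj$retainedFraction,
      rankLimited = obj$rankLimited, nTrain = obj$nTrain,
      locations = obj$locations, featureVoxel = obj$featureVoxel,
      featureAxis = obj$featureAxis, dims = obj$dims,
      spacing = obj$spacing, maskIdx = obj$maskIdx)
}
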