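test_that("Gaussian locality weight follows its closed form", {
  expect_equal(gaussianLocalityWeight(0, 5), 1)
  expect_equal(gaussianLocalityWeight(5, 5), exp(-0.5))
  expect_equal(gaussianLocalityWeight(c(0, 3, 100), Inf), c(1, 1, 1))
  expect_error(gaussianLocalityWeight(1, 0), "positive")
  expect_error(gaussianLocalityWeight(-1, 1), "non-negative")
})

test_that("locality kernel matches a brute-force dense computation", {
  set.seed(5)
  st <- smallStudy(seed = 5, n = 4)
  loc <- featureLocations(st$cohort)[1:60, ]
  diag <- boundingBoxDiagonal(st$mask)
  param <- localityParam(1/8, diag)
  K <- as.matrix(buildLocalityKernel(loc, param))
  D <- as.matrix(dist(loc))
  dense <- exp(-D^2 / (2 * param@sigmaMm^2))
  inside <- D <= param@truncationMm
  expect_lt(max(abs(K[inside] - dense[inside])), 1e-12)
  expect_true(all(K[!inside] == 0))
  expect_true(all(diag(K) == 1))
  # the three features of one voxel have pairwise weight 1
  expect_equal(K[1, 2], 1); expect_equal(K[2, 3], 1)
  # GLOBAL: dense all-ones
  KG <- buildLocalityKernel(loc[1:9, ], localityParam(GLOBAL, diag))
  expect_true(all(as.matrix(KG) == 1))
})

test_that("GLOBAL localized PCA reproduces standard PCA exactly", {
  st <- smallStudy(seed = 0)
  fit <- localizedPCA(st$cohort, st$mask, GLOBAL, trainFraction = 1,
                      seed = 0)
  m <- fit$model
  C <- denseCovariance(cohortMatrix(st$cohort))
  eg <- eigen(C, symmetric = TRUE)
  k <- nComponents(m)
  expect_gt(k, 0)
  expect_lt(max(abs(modelEigenvalues(m) - eg$values[1:k]) /
                  eg$values[1:k]), 1e-8)
  expect_lt(maxPrincipalAngle(modelComponents(m),
                              eg$vectors[, 1:k, drop = FALSE]), 1e-6)
  expect_lt(max(abs(crossprod(modelComponents(m)) - diag(k))), 1e-8)
  expect_gte(retainedFraction(m), 0.9)
})

test_that("kernel-manipulated spectra match the dense Hadamard oracle", {
  st <- smallStudy(seed = 2)
  X <- cohortMatrix(st$cohort)
  C <- denseCovariance(X)
  trace <- sum(diag(C))
  diagMm <- boundingBoxDiagonal(st$mask)
  for (fr in c(1/2, 1/8)) {
    fit <- suppressWarnings(
      localizedPCA(st$cohort, st$mask, fr, trainFraction = 1, seed = 2))
    m <- fit$model
    K <- as.matrix(buildLocalityKernel(featureLocations(st$cohort),
                                       localityParam(fr, diagMm)))
    ev <- eigen(C * K, symmetric = TRUE, only.values = TRUE)$values
    # trace is conserved by the manipulation and the spectrum is PSD
    expect_lt(abs(sum(ev) - trace) / trace, 1e-8)
    expect_gte(min(ev), -1e-10 * trace)
    k <- nComponents(m)
    expect_lt(max(abs(modelEigenvalues(m) - ev[1:k]) / ev[1:k]), 1e-6)
    expect_lt(max(abs(crossprod(modelComponents(m)) - diag(k))), 1e-8)
    expect_lte(retainedFraction(m), 1)
  }
})

test_that("zero-variance cohorts yield the k = 0 convention", {
  dims <- c(3L, 3L, 3L)
  mask <- fullMask(dims)
  fld <- vectorField(array(1, dim = c(dims, 3L)))
  coh <- assembleCohort(list(fld, fld, fld), mask)
  fit <- localizedPCA(coh, mask, GLOBAL, trainFraction = 1)
  expect_equal(nComponents(fit$model), 0L)
  expect_equal(retainedFraction(fit$model), 1)
})

test_that("projection and reconstruction are exact inverses on the subspace", {
  st <- smallStudy(seed = 3)
  fit <- localizedPCA(st$cohort, st$mask, GLOBAL, trainFraction = 1,
                      varianceTarget = 1)
  m <- fit$model
  # the mean projects to zero
  expect_lt(max(abs(projectScores(m, modelMean(m)))), 1e-8)
  # mean + sqrt(lambda_1) v_1 scores exactly (sqrt(lambda_1), 0, ...)
  lam1 <- modelEigenvalues(m)[1]
  x <- modelMean(m) + sqrt(lam1) * modelComponents(m)[, 1]
  sc <- projectScores(m, x)
  expect_lt(abs(sc[1] - sqrt(lam1)), 1e-8)
  expect_lt(max(abs(sc[-1])), 1e-8)
  # full-rank retention reconstructs training data
  X <- cohortMatrix(st$cohort)
  rec <- reconstructField(m, projectScores(m, X))
  expect_lt(max(abs(rec - X)), 1e-6)
  # affine linearity of reconstruction
  a <- rnorm(nComponents(m)); b <- rnorm(nComponents(m))
  expect_equal(reconstructField(m, a + b),
               reconstructField(m, a) + reconstructField(m, b) - modelMean(m),
               tolerance = 1e-10)
})

test_that("component sampling walks the axis linearly about the mean", {
  st <- smallStudy(seed = 4)
  fit <- localizedPCA(st$cohort, st$mask, GLOBAL, trainFraction = 1)
  m <- fit$model
  meanField <- fieldData(sampleComponent(m, 1, 0))
  plus <- fieldData(sampleComponent(m, 1, 1))
  minus <- fieldData(sampleComponent(m, 1, -1))
  expect_equal(plus + minus, 2 * meanField, tolerance = 1e-10)
  # doubling alpha doubles every voxel's deviation magnitude
  d1 <- magnitudeMap(vectorField(plus - meanField))
  d2 <- magnitudeMap(vectorField(fieldData(sampleComponent(m, 1, 2)) -
                                   meanField))
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  expect_error(sampleComponent(m, nComponents(m) + 1L, 1), "componentIndex")
})

test_that("the train/test split reports held-out generalization", {
  st <- smallStudy(seed = 6, n = 20)
  fit <- suppressWarnings(
    localizedPCA(st$cohort, st$mask, GLOBAL, trainFraction = 0.8, seed = 1))
  expect_equal(nrow(fit$trainScores), 16L)
  expect_equal(nrow(fit$heldoutScores), 4L)
  expect_true(is.finite(fit$heldoutRMSE))
  expect_equal(sort(c(rownames(fit$trainScores), rownames(fit$heldoutScores))),
               sort(subjectIds(st$cohort)))
})

test_that("model archives round-trip through serialization", {
  st <- smallStudy(seed = 8)
  fit <- localizedPCA(st$cohort, st$mask, 1/2, trainFraction = 1, seed = 0)
  p <- tempfile(fileext = ".rds")
  saveModel(fit$model, p)
  back <- loadModel(p)
  expect_equal(modelComponents(back), modelComponents(fit$model))
  expect_equal(modelEigenvalues(back), modelEigenvalues(fit$model))
  expect_equal(back@param@fraction, 1/2)
  # a restored model projects identically
  expect_equal(projectScores(back, cohortMatrix(st$cohort)),
               projectScores(fit$model, cohortMatrix(st$cohort)))
})
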