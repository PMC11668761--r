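test_that("vector fields survive NIfTI round trips in both dialects", {
  set.seed(42)
  fld <- randomField(c(8L, 8L, 8L), spacing = c(1.5, 2, 2.5))
  path5 <- tempfile(fileext = ".nii.gz")
  saveVectorField(fld, path5)
  back <- loadVectorField(path5)
  expect_identical(gridDims(back), c(8L, 8L, 8L))
  expect_equal(gridSpacing(back), c(1.5, 2, 2.5))
  expect_identical(fieldData(back), fieldData(fld))

  # equivalent 4-D X,Y,Z,3 file loads to the same object
  path4 <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(fieldData(fld))
  RNifti::pixdim(img) <- c(1.5, 2, 2.5, 1)
  RNifti::writeNifti(img, path4)
  back4 <- loadVectorField(path4)
  expect_equal(fieldData(back4), fieldData(fld))

  # degenerate single-voxel grid
  tiny <- vectorField(array(c(1, -2, 3), dim = c(1L, 1L, 1L, 3L)))
  p1 <- tempfile(fileext = ".nii")
  saveVectorField(tiny, p1)
  expect_equal(fieldData(loadVectorField(p1)), fieldData(tiny))

  # zero field writes a file whose data sum is 0
  zf <- vectorField(array(0, dim = c(4L, 4L, 4L, 3L)))
  pz <- tempfile(fileext = ".nii")
  saveVectorField(zf, pz)
  expect_equal(sum(as.array(RNifti::readNifti(pz))), 0)
})

test_that("malformed vector-field files are rejected with the offending shape", {
  bad <- array(rnorm(4 * 4 * 4 * 2), dim = c(4L, 4L, 4L, 2L))
  p <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(bad), p)
  expect_error(loadVectorField(p), "3-component")
  expect_error(loadVectorField(tempfile()), "no such file")
  expect_error(vectorField(array(c(1, NaN, 1), c(1L, 1L, 1L, 3L))), "finite")
})

test_that("cohort assembly vectorizes masked fields deterministically", {
  dims <- c(4L, 3L, 2L)
  set.seed(7)
  voxels <- array(runif(prod(dims)) > 0.4, dim = dims)
  voxels[1L] <- TRUE
  mask <- brainMask(voxels, spacing = c(2, 2, 2))
  fields <- lapply(1:3, function(i) randomField(dims, c(2, 2, 2)))
  coh <- assembleCohort(fields, mask, ids = c("a", "b", "c"))

  expect_equal(ncol(cohortMatrix(coh)), 3L * sum(voxels))
  # the three features of one voxel share one location row
  loc <- featureLocations(coh)
  expect_equal(loc[1, ], loc[2, ]); expect_equal(loc[2, ], loc[3, ])

  # row i is field i: check via explicit per-voxel lookup
  idx <- which(voxels)
  v1 <- idx[1L]
  ijk <- arrayInd(v1, dims) - 1L
  expect_equal(cohortMatrix(coh)[2, 1:3],
               as.numeric(fieldData(fields[[2]])[ijk[1] + 1, ijk[2] + 1,
                                                 ijk[3] + 1, ]))
  expect_equal(loc[1, ], as.numeric(ijk * c(2, 2, 2)))

  # permuting subjects permutes rows identically
  coh2 <- assembleCohort(fields[c(3, 1, 2)], mask, ids = c("c", "a", "b"))
  expect_equal(cohortMatrix(coh2), cohortMatrix(coh)[c(3, 1, 2), ])

  # mismatched grid names the subject
  bad <- randomField(c(4L, 3L, 3L), c(2, 2, 2))
  expect_error(assembleCohort(list(fields[[1]], bad), mask,
                              ids = c("ok", "oops")), "oops")
  expect_error(assembleCohort(fields[1], mask, ids = "a"), "at least 2")
})

test_that("bounding-box diagonal uses voxel centers in mm", {
  expect_equal(boundingBoxDiagonal(fullMask(c(10L, 10L, 10L))), 9 * sqrt(3))
  single <- array(FALSE, dim = c(5L, 5L, 5L)); single[3, 3, 3] <- TRUE
  expect_equal(boundingBoxDiagonal(brainMask(single)), 0)
  # 4 x 5 x 1 span of TRUE voxels: 3-4-5 triangle
  v <- array(FALSE, dim = c(6L, 6L, 6L))
  v[2:5, 1:5, 4] <- TRUE
  expect_equal(boundingBoxDiagonal(brainMask(v)), 5)
  # invariant to extra FALSE voxels, monotone when TRUE voxels are added
  vBig <- array(FALSE, dim = c(9L, 9L, 9L)); vBig[2:5, 1:5, 4] <- TRUE
  expect_equal(boundingBoxDiagonal(brainMask(vBig)), 5)
  vBig[9, 9, 9] <- TRUE
  expect_gte(boundingBoxDiagonal(brainMask(vBig)), 5)
  # spacing-aware
  expect_equal(boundingBoxDiagonal(fullMask(c(2L, 1L, 1L), c(3, 1, 1))), 3)
})

test_that("magnitude map equals the per-voxel Euclidean norm", {
  a <- array(0, dim = c(2L, 2L, 2L, 3L))
  a[1, 1, 1, ] <- c(3, 4, 0)
  expect_equal(magnitudeMap(vectorField(a))[1, 1, 1], 5)
  expect_true(all(magnitudeMap(vectorField(array(0, c(3L, 3L, 3L, 3L)))) == 0))

  set.seed(11)
  fld <- randomField(c(5L, 4L, 3L))
  mag <- magnitudeMap(fld)
  for (i in 1:5) for (j in 1:4) for (k in 1:3)
    expect_lt(abs(mag[i, j, k] - sqrt(sum(fieldData(fld)[i, j, k, ]^2))),
              1e-12)

  # pointwise triangle inequality under field addition
  g <- randomField(c(5L, 4L, 3L))
  s <- vectorField(fieldData(fld) + fieldData(g))
  expect_true(all(magnitudeMap(s) <= magnitudeMap(fld) + magnitudeMap(g)
                  + 1e-12))
})

test_that("region attribution ranks regions with deterministic ties", {
  dims <- c(6L, 6L, 6L)
  lab <- array(0L, dim = dims)
  lab[1:2, , ] <- 5L; lab[3:4, , ] <- 7L; lab[5:6, , ] <- 2L
  atlas <- labelVolume(lab, names = c(`5` = "left", `7` = "mid",
                                      `2` = "right"))
  mag <- array(0, dim = dims)
  mag[3:4, , ] <- 1.5
  out <- regionAttribution(mag, atlas, stat = "mean")
  expect_equal(out$label[1], 7L)
  expect_equal(out$value[1], 1.5)
  expect_equal(out$value[-1], c(0, 0))

  # uniform map: every region equal, order ascending label id
  outU <- regionAttribution(array(2, dim = dims), atlas, stat = "mean")
  expect_equal(outU$label, c(2L, 5L, 7L))
  expect_equal(outU$value, rep(2, 3))

  # random map vs masked-average oracle per label
  set.seed(3)
  magR <- array(runif(prod(dims)), dim = dims)
  outR <- regionAttribution(magR, atlas, stat = "mean")
  for (r in seq_len(nrow(outR)))
    expect_lt(abs(outR$value[r] -
                    mean(magR[lab == outR$label[r]])), 1e-12)
  expect_error(regionAttribution(array(0, c(2L, 2L, 2L)), atlas), "differ")
})

test_that("backward warping interpolates trilinearly with zero padding", {
  dims <- c(7L, 7L, 7L)
  img <- array(seq_len(prod(dims)), dim = dims)
  zero <- vectorField(array(0, dim = c(dims, 3L)))
  expect_equal(warpImage(img, zero), img, ignore_attr = TRUE)

  # +1 voxel shift along x on a linear x-ramp: interior shifted by one
  ramp <- array(rep(seq_len(dims[1]), times = prod(dims[2:3])), dim = dims)
  shift <- array(0, dim = c(dims, 3L)); shift[, , , 1] <- 1
  warped <- warpImage(ramp, vectorField(shift, spacing = c(1, 1, 1)))
  expect_equal(warped[1:6, 4, 4], ramp[2:7, 4, 4])

  # random small field vs independent per-voxel interpolation oracle
  set.seed(9)
  fld <- randomField(dims, sd = 0.4)
  w <- warpImage(img, fld)
  interp1 <- function(p) {
    f <- floor(p); t <- p - f
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      q <- f + c(dx, dy, dz)
      val <- if (all(q >= 0) && all(q < dims)) img[q[1] + 1, q[2] + 1, q[3] + 1] else 0
      wt <- prod(ifelse(c(dx, dy, dz) == 1, t, 1 - t))
      acc <- acc + wt * val
    }
    acc
  }
  for (trial in 1:25) {
    v <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    p <- (v - 1) + fieldData(fld)[v[1], v[2], v[3], ]
    expect_lt(abs(w[v[1], v[2], v[3]] - interp1(p)), 1e-10)
  }
})

test_that("masks, scalar volumes and label volumes round-trip with sidecars", {
  dims <- c(5L, 5L, 5L)
  set.seed(21)
  vox <- array(runif(prod(dims)) > 0.5, dim = dims); vox[1] <- TRUE
  mask <- brainMask(vox, spacing = c(2, 2, 2))
  pm <- tempfile(fileext = ".nii.gz")
  saveScalarVolume(maskVoxels(mask), gridSpacing(mask), pm)
  back <- loadBrainMask(pm)
  expect_identical(maskVoxels(back), maskVoxels(mask))

  lab <- array(sample(0:3, prod(dims), replace = TRUE), dim = dims)
  atlas <- labelVolume(lab, spacing = c(2, 2, 2),
                       names = c(`1` = "one", `2` = "two", `3` = "three"))
  pa <- tempfile(fileext = ".nii.gz")
  saveLabelVolume(atlas, pa)
  back2 <- loadLabelVolume(pa)
  expect_identical(back2@labels, atlas@labels)
  expect_equal(back2@names[["2"]], "two")
})
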