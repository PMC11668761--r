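#' Read a 3-D displacement field from NIfTI
#'
#' Accepts the two common on-disk layouts for vector-valued warps: the 5-D
#' `X x Y x Z x 1 x 3` dialect used by registration toolkits and the plain
#' 4-D `X x Y x Z x 3` layout.  Both are normalized to a [VectorField-class]
#' holding an `X x Y x Z x 3` array.
#'
#' @param path path to a NIfTI file.
#' @return A [VectorField-class].
#' @export
loadVectorField <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 5L && d[4L] == 1L && d[5L] == 3L) {
    a <- array(a, dim = c(d[1:3], 3L))
  } else if (length(d) == 4L && d[4L] == 3L) {
    a <- array(a, dim = d)          # strip the niftiImage class
  } else {
    stop(sprintf("not a 3-component vector field: shape (%s) in %s",
                 paste(d, collapse = ", "), path))
  }
  if (any(!is.finite(a)))
    stop("non-finite displacement values in ", path)
  pd <- RNifti::pixdim(img)[1:3]
  vectorField(a, spacing = pd, affine = .xformOrIdentity(img))
}

.xformOrIdentity <- function(img) {
  xf <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  if (is.null(xf) || !identical(dim(xf), c(4L, 4L))) diag(4) else {
    attributes(xf) <- list(dim = c(4L, 4L))
    xf
  }
}

#' Write a displacement field as 5-D NIfTI
#'
#' Writes the `X x Y x Z x 1 x 3` layout with grid spacing in the header;
#' [loadVectorField()] inverts it exactly.
#'
#' @param field a [VectorField-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
saveVectorField <- function(field, path) {
  stopifnot(is(field, "VectorField"))
  a <- array(field@data, dim = c(field@dims, 1L, 3L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(field@spacing, 1, 1)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("failed writing ", path, ": ",
                                    conditionMessage(e)))
  invisible(NULL)
}

#' Read/write a scalar volume (mask, magnitude map, label image)
#'
#' Masks are thresholded at > 0.5; labels are rounded to integer.
#'
#' @param path NIfTI file path.
#' @return `loadBrainMask` returns a [BrainMask-class]; `loadScalarVolume`
#'   a list with `data` (3-D array) and `spacing`.
#' @export
loadBrainMask <- function(path) {
  v <- loadScalarVolume(path)
  brainMask(v$data > 0.5, spacing = v$spacing)
}

#' @rdname loadBrainMask
#' @export
loadScalarVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L)
      stop("expected a scalar volume, got shape (",
           paste(d, collapse = ", "), ") in ", path)
    a <- array(a, dim = d[1:3])
  }
  list(data = a, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname loadBrainMask
#' @param data 3-D array (logical for masks).
#' @param spacing numeric(3) mm.
#' @export
saveScalarVolume <- function(data, spacing, path) {
  img <- RNifti::asNifti(array(as.numeric(data), dim = dim(data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(NULL)
}

#' Read a label volume plus its name sidecar
#'
#' Region names come from a two-column tab-separated sidecar
#' (`label_id`, `name`); when absent, labels are named `region_<id>`.
#'
#' @param path NIfTI label image.
#' @param namesPath optional TSV sidecar; defaults to `<path>.labels.tsv`
#'   next to the image.
#' @return A [LabelVolume-class].
#' @export
loadLabelVolume <- function(path, namesPath = NULL) {
  v <- loadScalarVolume(path)
  lab <- array(as.integer(round(v$data)), dim = dim(v$data))
  if (is.null(namesPath))
    namesPath <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.tsv")
  nm <- character()
  if (file.exists(namesPath)) {
    tab <- read.table(namesPath, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
    nm <- setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
  }
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  missing <- setdiff(as.character(ids), names(nm))
  if (length(missing))
    nm[missing] <- sprintf("region_%s", missing)
  labelVolume(lab, spacing = v$spacing, names = nm)
}

#' @rdname loadLabelVolume
#' @param atlas a [LabelVolume-class].
#' @export
saveLabelVolume <- function(atlas, path, namesPath = NULL) {
  saveScalarVolume(atlas@labels, atlas@spacing, path)
  if (is.null(namesPath))
    namesPath <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.tsv")
  ids <- names(atlas@names)
  write.table(data.frame(label_id = ids, name = unname(atlas@names)),
              namesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Feature geometry of a mask
#'
#' Internal: masked voxel linear indices (column-major, x fastest), their
#' 0-based grid coordinates and mm locations.
#' @noRd
.maskGeometry <- function(mask) {
  idx <- which(as.vector(mask@voxels))
  d <- mask@dims
  i0 <- (idx - 1L) %% d[1L]
  j0 <- ((idx - 1L) %/% d[1L]) %% d[2L]
  k0 <- (idx - 1L) %/% (d[1L] * d[2L])
  vox <- cbind(i0, j0, k0)
  dimnames(vox) <- NULL
  loc <- sweep(vox, 2L, mask@spacing, `*`)
  list(idx = as.integer(idx), vox = vox, loc = loc)
}

#' Assemble a cohort matrix from deformation fields
#'
#' Each field is restricted to the mask and vectorized in the package's
#' fixed feature order: masked voxels in column-major (x-fastest) grid
#' order, the three axis components of a voxel contiguous.  Voxel-center
#' locations are `0-based index * spacing` (the affine applies when a field
#' carries a non-identity one, but only relative distances matter
#' downstream).
#'
#' @param fields list of [VectorField-class], all on the mask's grid.
#' @param mask a [BrainMask-class].
#' @param ids character vector of subject ids (same length as `fields`).
#' @return A [MorphCohort-class] with `n = length(fields)` and
#'   `p = 3 * sum(mask)` features.
#' @export
assembleCohort <- function(fields, mask, ids = NULL) {
  stopifnot(is(mask, "BrainMask"))
  n <- length(fields)
  if (n < 2L) stop("need at least 2 subjects")
  if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
  if (length(ids) != n) stop("ids must match the number of fields")
  g <- .maskGeometry(mask)
  V <- length(g$idx)
  p <- 3L * V
  X <- matrix(0, n, p)
  nvox <- prod(mask@dims)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (!identical(f@dims, mask@dims) ||
        max(abs(f@spacing - mask@spacing)) > 1e-9)
      stop("field grid mismatch for subject ", ids[i])
    dat <- f@data
    # interleave x,y,z per voxel: feature 3(v-1)+axis
    M <- cbind(dat[g$idx], dat[g$idx + nvox], dat[g$idx + 2L * nvox])
    X[i, ] <- as.vector(t(M))
  }
  loc <- g$loc[rep(seq_len(V), each = 3L), , drop = FALSE]
  new("MorphCohort", X = X, locations = loc,
      featureVoxel = rep(seq_len(V), each = 3L),
      featureAxis = rep(1:3, V), subjectIds = as.character(ids),
      dims = mask@dims, spacing = mask@spacing, maskIdx = g$idx)
}

#' Reshape a feature vector back onto the grid
#'
#' Inverse of the cohort vectorization: unmasked voxels are 0.
#' @param v numeric(p) in the cohort feature order.
#' @param dims,maskIdx grid geometry.
#' @return array of dim `c(dims, 3)`.
#' @noRd
.vectorToGrid <- function(v, dims, maskIdx) {
  V <- length(maskIdx)
  a <- array(0, dim = c(dims, 3L))
  M <- matrix(v, nrow = 3L)           # 3 x V, axis fastest
  nvox <- prod(dims)
  a[maskIdx] <- M[1L, ]
  a[maskIdx + nvox] <- M[2L, ]
  a[maskIdx + 2L * nvox] <- M[3L, ]
  a
}

#' Diagonal of the mask's bounding box
#'
#' Euclidean length, in mm, of the diagonal of the axis-aligned box spanned
#' by the centers of the TRUE voxels (center-to-center, so a single-voxel
#' mask has diagonal 0).  The locality fraction multiplies this diagonal to
#' obtain the kernel width.
#'
#' @param mask a [BrainMask-class].
#' @return non-negative scalar (mm).
#' @export
boundingBoxDiagonal <- function(mask) {
  stopifnot(is(mask, "BrainMask"))
  g <- .maskGeometry(mask)
  if (!nrow(g$vox)) stop("mask is empty")
  ext <- (apply(g$vox, 2L, max) - apply(g$vox, 2L, min)) * mask@spacing
  sqrt(sum(ext^2))
}

#' Per-voxel displacement magnitude
#'
#' @param field a [VectorField-class].
#' @return 3-D array of dim `dims`: Euclidean norm (mm) of each voxel's
#'   displacement vector.
#' @export
magnitudeMap <- function(field) {
  stopifnot(is(field, "VectorField"))
  d <- field@data
  sqrt(d[, , , 1L]^2 + d[, , , 2L]^2 + d[, , , 3L]^2)
}

#' Rank atlas regions by a magnitude statistic
#'
#' Summarizes a scalar map (typically a [magnitudeMap()]) within every
#' nonzero atlas label and ranks regions by the statistic, descending; ties
#' break by ascending label id.
#'
#' @param mag 3-D numeric array.
#' @param atlas a [LabelVolume-class] on the same grid.
#' @param stat `"mean"` or `"max"`.
#' @return data.frame with columns `label`, `region`, `value`, sorted.
#' @export
regionAttribution <- function(mag, atlas, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(is(atlas, "LabelVolume"))
  if (!identical(dim(mag), dim(atlas@labels)))
    stop("magnitude map and atlas grids differ: (",
         paste(dim(mag), collapse = ","), ") vs (",
         paste(dim(atlas@labels), collapse = ","), ")")
  lab <- as.vector(atlas@labels)
  keep <- lab > 0L
  vals <- tapply(as.vector(mag)[keep], lab[keep],
                 if (stat == "mean") mean else max)
  ids <- as.integer(names(vals))
  nm <- atlas@names[as.character(ids)]
  nm[is.na(nm)] <- sprintf("region_%d", ids[is.na(nm)])
  out <- data.frame(label = ids, region = unname(nm),
                    value = as.numeric(vals), stringsAsFactors = FALSE)
  out[order(-out$value, out$label), , drop = FALSE]
}

#' Warp a scalar image by a displacement field
#'
#' Backward warping: output voxel `v` takes the trilinearly interpolated
#' input intensity at mm position `center(v) + displacement(v)`.  Samples
#' falling outside the grid contribute 0.
#'
#' @param image 3-D numeric array on the field's grid.
#' @param field a [VectorField-class] (displacements in mm).
#' @return 3-D numeric array, same dim as `image`.
#' @export
warpImage <- function(image, field) {
  stopifnot(is(field, "VectorField"))
  d <- field@dims
  if (!identical(dim(image), d))
    stop("image and field grids differ")
  sp <- field@spacing
  nvox <- prod(d)
  idx <- seq_len(nvox) - 1L
  i0 <- idx %% d[1L]; j0 <- (idx %/% d[1L]) %% d[2L]; k0 <- idx %/% (d[1L] * d[2L])
  # sample position in (0-based) voxel coordinates
  px <- i0 + field@data[seq_len(nvox)] / sp[1L]
  py <- j0 + field@data[seq_len(nvox) + nvox] / sp[2L]
  pz <- k0 + field@data[seq_len(nvox) + 2L * nvox] / sp[3L]
  fx <- floor(px); fy <- floor(py); fz <- floor(pz)
  wx <- px - fx; wy <- py - fy; wz <- pz - fz
  sample1 <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix < d[1L] & iy >= 0 & iy < d[2L] & iz >= 0 & iz < d[3L]
    out <- numeric(nvox)
    lin <- (iz[ok] * d[2L] + iy[ok]) * d[1L] + ix[ok] + 1
    out[ok] <- image[lin]
    out
  }
  acc <- (1 - wx) * (1 - wy) * (1 - wz) * sample1(fx,     fy,     fz) +
         wx       * (1 - wy) * (1 - wz) * sample1(fx + 1, fy,     fz) +
         (1 - wx) * wy       * (1 - wz) * sample1(fx,     fy + 1, fz) +
         wx       * wy       * (1 - wz) * sample1(fx + 1, fy + 1, fz) +
         (1 - wx) * (1 - wy) * wz       * sample1(fx,     fy,     fz + 1) +
         wx       * (1 - wy) * wz       * sample1(fx + 1, fy,     fz + 1) +
         (1 - wx) * wy       * wz       * sample1(fx,     fy + 1, fz + 1) +
         wx       * wy       * wz       * sample1(fx + 1, fy + 1, fz + 1)
  array(acc, dim = d)
}
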