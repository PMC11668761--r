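#' @import methods
#' @importFrom stats pf rnorm rbinom rbeta runif sd var cor lm.fit setNames
#' @importFrom utils head read.table write.table
#' @importFrom tools md5sum
NULL

#' VectorField: one subject's 3-D displacement field
#'
#' A dense displacement field on a regular grid: one 3-vector (mm) per voxel.
#' Deformation fields of this kind are the output of non-linear registration
#' of a subject image to a common atlas and encode the subject's morphology
#' relative to that atlas.
#'
#' @slot dims integer(3), grid size in voxels.
#' @slot spacing numeric(3), voxel size in mm.
#' @slot data numeric array of dim `c(dims, 3)`; displacement in mm along
#'   x, y, z.
#' @slot affine 4x4 grid-to-world matrix; identity by default.  Only used to
#'   place voxel centers in world space; the analysis needs relative
#'   distances only.
#' @exportClass VectorField
setClass("VectorField",
  representation(dims = "integer", spacing = "numeric",
                 data = "array", affine = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be three integers >= 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive reals")
    if (!identical(dim(object@data), c(object@dims, 3L)))
      msg <- c(msg, sprintf("data must have dim (%s, 3)",
                            paste(object@dims, collapse = ", ")))
    if (any(!is.finite(object@data)))
      msg <- c(msg, "displacement data must be finite (no NaN/Inf)")
    if (!identical(dim(object@affine), c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    if (length(msg)) msg else TRUE
  })

#' BrainMask: boolean voxel mask on the atlas grid
#'
#' @slot dims integer(3) grid size.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot voxels logical array of dim `dims`; TRUE marks in-brain voxels.
#' @exportClass BrainMask
setClass("BrainMask",
  representation(dims = "integer", spacing = "numeric", voxels = "array"),
  validity = function(object) {
    msg <- character()
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be three integers >= 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive reals")
    if (!is.logical(object@voxels) ||
        !identical(dim(object@voxels), object@dims))
      msg <- c(msg, "voxels must be a logical array of dim `dims`")
    else if (!any(object@voxels))
      msg <- c(msg, "mask must contain at least one TRUE voxel")
    if (length(msg)) msg else TRUE
  })

#' LabelVolume: integer region labels on the atlas grid
#'
#' Label 0 is reserved for background.  Region names are attached as a named
#' character vector keyed by label id.
#'
#' @slot dims integer(3) grid size.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot labels integer array of dim `dims`.
#' @slot names named character vector mapping label id to region name.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(dims = "integer", spacing = "numeric",
                 labels = "array", names = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@labels), object@dims))
      msg <- c(msg, "labels must be an array of dim `dims`")
    if (any(object@labels < 0L))
      msg <- c(msg, "labels must be non-negative (0 = background)")
    if (length(msg)) msg else TRUE
  })

#' MorphCohort: vectorized masked deformation fields of n subjects
#'
#' Row i of `X` is subject i's field restricted to the mask and flattened in
#' a fixed feature order: masked voxels are taken in column-major (x-fastest)
#' grid order, and the three axis components of a voxel are contiguous
#' (x, y, z).  One location row is shared by the three features of a voxel,
#' so `locations` has `p = 3 * nVoxels` rows.
#'
#' @slot X numeric matrix n x p of displacements (mm).
#' @slot locations numeric matrix p x 3, mm position of each feature's voxel
#'   center.
#' @slot featureVoxel integer(p), 1-based index into `maskIdx` of the voxel
#'   each feature belongs to.
#' @slot featureAxis integer(p) in 1:3 (x, y, z).
#' @slot subjectIds character(n).
#' @slot dims,spacing grid geometry shared with the mask.
#' @slot maskIdx integer vector of linear (column-major) indices of TRUE
#'   mask voxels.
#' @exportClass MorphCohort
setClass("MorphCohort",
  representation(X = "matrix", locations = "matrix",
                 featureVoxel = "integer", featureAxis = "integer",
                 subjectIds = "character", dims = "integer",
                 spacing = "numeric", maskIdx = "integer"),
  validity = function(object) {
    msg <- character()
    p <- ncol(object@X)
    if (p != 3L * length(object@maskIdx))
      msg <- c(msg, "p must equal 3 x number of mask voxels")
    if (nrow(object@locations) != p)
      msg <- c(msg, "locations must have one row per feature")
    if (length(object@subjectIds) != nrow(object@X))
      msg <- c(msg, "subjectIds must match rows of X")
    if (length(msg)) msg else TRUE
  })

#' LocalityParam: width of the distance kernel
#'
#' The locality fraction expresses the Gaussian kernel width as a fraction of
#' the diagonal of the bounding box around the mask; `Inf` encodes the GLOBAL
#' setting (kernel identically 1, i.e. standard PCA).
#'
#' @slot fraction positive real or `Inf` (GLOBAL).
#' @slot sigmaMm kernel standard deviation in mm (`Inf` for GLOBAL).
#' @slot truncationMm kernel support cutoff in mm (`Inf` for GLOBAL).
#' @exportClass LocalityParam
setClass("LocalityParam",
  representation(fraction = "numeric", sigmaMm = "numeric",
                 truncationMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fraction) != 1L || is.na(object@fraction) ||
        object@fraction <= 0)
      msg <- c(msg, "fraction must be a single positive real or Inf")
    if (object@sigmaMm <= 0) msg <- c(msg, "sigmaMm must be > 0")
    if (object@truncationMm <= 0) msg <- c(msg, "truncationMm must be > 0")
    if (length(msg)) msg else TRUE
  })

#' LocalizedPCAModel: fitted localized (or global) PCA model
#'
#' @slot mean numeric(p) training mean field.
#' @slot components p x k matrix with orthonormal columns.
#' @slot eigenvalues numeric(k), non-increasing, >= 0.
#' @slot param the [LocalityParam-class] used.
#' @slot totalVariance trace of the (unmanipulated) training covariance;
#'   preserved by the kernel manipulation because the kernel diagonal is 1.
#' @slot retainedFraction sum(eigenvalues)/totalVariance in `[0, 1]`.
#' @slot rankLimited TRUE when the variance target could not be reached
#'   before the spectrum was exhausted.
#' @slot nTrain number of training subjects.
#' @slot locations,featureVoxel,featureAxis,dims,spacing,maskIdx feature
#'   geometry copied from the training cohort (needed to reshape sampled
#'   fields back onto the grid).
#' @exportClass LocalizedPCAModel
setClass("LocalizedPCAModel",
  representation(mean = "numeric", components = "matrix",
                 eigenvalues = "numeric", param = "LocalityParam",
                 totalVariance = "numeric", retainedFraction = "numeric",
                 rankLimited = "logical", nTrain = "integer",
                 locations = "matrix", featureVoxel = "integer",
                 featureAxis = "integer", dims = "integer",
                 spacing = "numeric", maskIdx = "integer"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@components)
    if (length(object@eigenvalues) != k)
      msg <- c(msg, "eigenvalues length must equal component count")
    if (k && any(diff(object@eigenvalues) > 1e-8 * max(object@eigenvalues)))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < 0))
      msg <- c(msg, "eigenvalues must be non-negative")
    if (k && nrow(object@components) != length(object@mean))
      msg <- c(msg, "components rows must match mean length")
    if (object@retainedFraction < 0 || object@retainedFraction > 1 + 1e-8)
      msg <- c(msg, "retainedFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' GenotypeMatrix: biallelic dosages with SNP and sample metadata
#'
#' Dosage counts copies of the A2 allele (the second allele of the .bim
#' record): 0, 1, 2, or `NA` for a missing call.
#'
#' @slot dosage integer matrix n x m; values 0/1/2/NA.
#' @slot snps data.frame with columns chrom, id, cm, pos, a1, a2 (one row
#'   per SNP).
#' @slot samples data.frame with columns fid, iid, pat, mat, sex, pheno.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(dosage = "matrix", snps = "data.frame",
                 samples = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- object@dosage
    if (!all(d %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    if (nrow(object@snps) != ncol(d))
      msg <- c(msg, "snps rows must match dosage columns")
    if (nrow(object@samples) != nrow(d))
      msg <- c(msg, "samples rows must match dosage rows")
    if (length(msg)) msg else TRUE
  })

#' QCThresholds: genotype quality-control thresholds
#'
#' Defaults follow standard array-QC practice: MAF > 0.05, per-SNP
#' missingness <= 0.1, per-sample missingness <= 0.1, HWE exact p >= 0.001,
#' and exclusion of variants with multi-character allele codes.
#'
#' @slot mafMin minimum minor allele frequency (SNPs with maf < mafMin drop).
#' @slot genoMax maximum per-SNP missing fraction.
#' @slot mindMax maximum per-sample missing fraction.
#' @slot hwePMin minimum HWE exact-test p-value.
#' @slot snpsOnly drop variants with multi-character allele codes.
#' @exportClass QCThresholds
setClass("QCThresholds",
  representation(mafMin = "numeric", genoMax = "numeric",
                 mindMax = "numeric", hwePMin = "numeric",
                 snpsOnly = "logical"),
  prototype(mafMin = 0.05, genoMax = 0.1, mindMax = 0.1, hwePMin = 0.001,
            snpsOnly = TRUE),
  validity = function(object) {
    vals <- c(object@mafMin, object@genoMax, object@mindMax, object@hwePMin)
    if (any(vals < 0 | vals > 1))
      "all thresholds must lie in [0, 1]" else TRUE
  })

setMethod("show", "VectorField", function(object) {
  cat(sprintf("VectorField: %s voxels, spacing %s mm, |d| max %.4g mm\n",
              paste(object@dims, collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              max(abs(object@data))))
})

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask: %s grid, %d voxels in mask\n",
              paste(object@dims, collapse = "x"), sum(object@voxels)))
})

setMethod("show", "MorphCohort", function(object) {
  cat(sprintf("MorphCohort: %d subjects x %d features (%d masked voxels)\n",
              nrow(object@X), ncol(object@X), length(object@maskIdx)))
})

setMethod("show", "LocalizedPCAModel", function(object) {
  fr <- object@param@fraction
  cat(sprintf(paste0("LocalizedPCAModel: fraction %s, k = %d components, ",
                     "retained %.3f of variance%s\n"),
              if (is.infinite(fr)) "GLOBAL" else format(fr),
              ncol(object@components), object@retainedFraction,
              if (object@rankLimited) " (rank-limited)" else ""))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs, %.3f%% missing\n",
              nrow(object@dosage), ncol(object@dosage),
              100 * mean(is.na(object@dosage))))
})

setMethod("show", "LocalityParam", function(object) {
  if (is.infinite(object@fraction)) cat("LocalityParam: GLOBAL\n")
  else cat(sprintf("LocalityParam: fraction %g, sigma %.3f mm, cutoff %.3f mm\n",
                   object@fraction, object@sigmaMm, object@truncationMm))
})
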