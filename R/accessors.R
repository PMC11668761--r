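#' Construct a VectorField
#'
#' @param data numeric array of dim `c(dims, 3)` (mm displacements).
#' @param spacing numeric(3) voxel size in mm.
#' @param affine optional 4x4 grid-to-world matrix.
#' @return A [VectorField-class].
#' @export
vectorField <- function(data, spacing = c(1, 1, 1), affine = diag(4)) {
  dims <- dim(data)
  if (length(dims) != 4L || dims[4L] != 3L)
    stop("data must be a 4-D array with 3 components in the last dimension")
  new("VectorField", dims = as.integer(dims[1:3]),
      spacing = as.numeric(spacing), data = data, affine = affine)
}

#' Construct a BrainMask
#'
#' @param voxels logical 3-D array.
#' @param spacing numeric(3) voxel size in mm.
#' @return A [BrainMask-class].
#' @export
brainMask <- function(voxels, spacing = c(1, 1, 1)) {
  new("BrainMask", dims = as.integer(dim(voxels)),
      spacing = as.numeric(spacing), voxels = voxels)
}

#' Construct a LabelVolume
#'
#' @param labels integer 3-D array (0 = background).
#' @param spacing numeric(3) voxel size in mm.
#' @param names named character vector, names are label ids.
#' @return A [LabelVolume-class].
#' @export
labelVolume <- function(labels, spacing = c(1, 1, 1),
                        names = character()) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", dims = as.integer(dim(labels)),
      spacing = as.numeric(spacing), labels = labels, names = names)
}

#' Construct QC thresholds
#'
#' @param mafMin,genoMax,mindMax,hwePMin,snpsOnly see
#'   [QCThresholds-class]; defaults are the standard array-QC settings.
#' @return A [QCThresholds-class].
#' @export
qcThresholds <- function(mafMin = 0.05, genoMax = 0.1, mindMax = 0.1,
                         hwePMin = 0.001, snpsOnly = TRUE) {
  new("QCThresholds", mafMin = mafMin, genoMax = genoMax, mindMax = mindMax,
      hwePMin = hwePMin, snpsOnly = snpsOnly)
}

#' @describeIn vectorField displacement array accessor.
#' @param x object.
#' @export
fieldData <- function(x) x@data

#' @describeIn brainMask logical voxel array accessor.
#' @export
maskVoxels <- function(x) x@voxels

#' Grid spacing accessor (mm per voxel)
#' @param x a VectorField, BrainMask, LabelVolume or MorphCohort.
#' @export
gridSpacing <- function(x) x@spacing

#' Grid dimensions accessor (voxels)
#' @param x a VectorField, BrainMask, LabelVolume or MorphCohort.
#' @export
gridDims <- function(x) x@dims

#' Cohort data matrix accessor (subjects x features)
#' @param x a MorphCohort.
#' @export
cohortMatrix <- function(x) x@X

#' Feature locations accessor (p x 3, mm)
#' @param x a MorphCohort or LocalizedPCAModel.
#' @export
featureLocations <- function(x) x@locations

#' Subject ids accessor
#' @param x a MorphCohort.
#' @export
subjectIds <- function(x) x@subjectIds

#' Model components accessor (p x k, orthonormal columns)
#' @param x a LocalizedPCAModel.
#' @export
modelComponents <- function(x) x@components

#' Model eigenvalues accessor (non-increasing, >= 0)
#' @param x a LocalizedPCAModel.
#' @export
modelEigenvalues <- function(x) x@eigenvalues

#' Model mean field accessor (length p)
#' @param x a LocalizedPCAModel.
#' @export
modelMean <- function(x) x@mean

#' Retained variance fraction accessor
#' @param x a LocalizedPCAModel.
#' @export
retainedFraction <- function(x) x@retainedFraction

#' Number of retained components
#' @param x a LocalizedPCAModel.
#' @export
nComponents <- function(x) ncol(x@components)

#' Dosage matrix accessor (n x m; 0/1/2/NA copies of A2)
#' @param x a GenotypeMatrix.
#' @export
dosageMatrix <- function(x) x@dosage

#' SNP metadata accessor (.bim-style data.frame)
#' @param x a GenotypeMatrix.
#' @export
snpInfo <- function(x) x@snps

#' Sample metadata accessor (.fam-style data.frame)
#' @param x a GenotypeMatrix.
#' @export
sampleInfo <- function(x) x@samples

#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix n x m with values 0/1/2/NA (copies of A2).
#' @param snps data.frame with columns chrom, id, cm, pos, a1, a2;
#'   default metadata is generated when omitted.
#' @param samples data.frame with columns fid, iid, pat, mat, sex, pheno.
#' @return A [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosage, snps = NULL, samples = NULL) {
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(snps))
    snps <- data.frame(chrom = rep("1", m),
                       id = if (m) sprintf("snp%d", seq_len(m)) else character(),
                       cm = numeric(m), pos = seq_len(m),
                       a1 = rep("A", m), a2 = rep("G", m),
                       stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- data.frame(fid = sprintf("F%d", seq_len(n)),
                          iid = sprintf("S%d", seq_len(n)),
                          pat = rep("0", n), mat = rep("0", n),
                          sex = rep(0L, n), pheno = rep(-9, n),
                          stringsAsFactors = FALSE)
  new("GenotypeMatrix", dosage = dosage, snps = snps, samples = samples)
}
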