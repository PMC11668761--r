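#' Simulation configuration
#'
#' Study conditions for the synthetic cohort generator: biallelic SNP
#' genotypes with configurable allele frequencies and missingness, and
#' smooth displacement-field cohorts carrying a spatially localized,
#' genotype-dose-dependent deformation bump plus shared smooth background
#' modes and smooth per-subject noise.
#'
#' @param n subjects.
#' @param m SNPs.
#' @param mafRange interval the per-SNP allele frequency is drawn from.
#' @param missingRate independent per-call missing probability.
#' @param grid integer(3) voxel grid.
#' @param spacing numeric(3) mm per voxel.
#' @param causalSnpIndex column of the causal SNP (`NA` for none).
#' @param causalMaf allele frequency forced at the causal SNP.
#' @param effectCenter voxel triple (1-based) of the bump center; default
#'   picks a masked voxel offset along +x from the mask centroid.
#' @param effectRadiusMm compact support radius of the bump.
#' @param effectBeta peak displacement (mm) added per A2 allele.
#' @param effectNaturalAmplitudeMm SD of the effect region's natural
#'   (genotype-independent) variability along the bump shape; the causal
#'   allele shifts this naturally varying mode, the way heritable regional
#'   anatomy behaves.
#' @param effectPartner when TRUE the effect region's natural variability
#'   co-varies (one shared coefficient) with a diffuse pattern over the
#'   rest of the brain, so global components mix the effect region with
#'   distant anatomy while localized components can separate them.
#' @param smoothNoiseScaleMm per-feature SD of the smooth subject noise.
#' @param smoothnessFwhmMm Gaussian smoothing FWHM applied to all
#'   stochastic field components.
#' @param nBackgroundModes number of shared smooth background modes.
#' @param backgroundAmplitudeMm per-feature RMS amplitude of each mode.
#' @param blobsPerMode number of compact Gaussian blobs composing each
#'   background mode (anatomical variability is regionally concentrated,
#'   and multi-blob modes are what makes global components mix distant
#'   regions).
#' @param blobSdMm spatial SD (mm) of each background blob.
#' @param populationStructure optional Fst-like divergence of two equal
#'   subpopulations (`NULL` = unstructured).
#' @param covariateEffects optional `list(age = , sex = )` of mm-scale
#'   coefficients adding age/sex-driven smooth modes to the fields.
#' @param seed integer master seed.
#' @return validated list of class `SimConfig`.
#' @export
simConfig <- function(n = 300L, m = 200L, mafRange = c(0.05, 0.5),
                      missingRate = 0.01, grid = c(16L, 16L, 16L),
                      spacing = c(2, 2, 2), causalSnpIndex = 1L,
                      causalMaf = 0.3, effectCenter = NULL,
                      effectRadiusMm = 6, effectBeta = 0.5,
                      effectNaturalAmplitudeMm = 1.4, effectPartner = TRUE,
                      smoothNoiseScaleMm = 0.25, smoothnessFwhmMm = 6,
                      nBackgroundModes = 2L, backgroundAmplitudeMm = 0.65,
                      blobsPerMode = 2L, blobSdMm = 2,
                      populationStructure = NULL, covariateEffects = NULL,
                      seed = 0L) {
  cfg <- list(n = as.integer(n), m = as.integer(m), mafRange = mafRange,
              missingRate = missingRate, grid = as.integer(grid),
              spacing = as.numeric(spacing),
              causalSnpIndex = if (is.null(causalSnpIndex) ||
                                   is.na(causalSnpIndex)) NA_integer_
                               else as.integer(causalSnpIndex),
              causalMaf = causalMaf, effectCenter = effectCenter,
              effectRadiusMm = effectRadiusMm, effectBeta = effectBeta,
              effectNaturalAmplitudeMm = effectNaturalAmplitudeMm,
              effectPartner = isTRUE(effectPartner),
              smoothNoiseScaleMm = smoothNoiseScaleMm,
              smoothnessFwhmMm = smoothnessFwhmMm,
              nBackgroundModes = as.integer(nBackgroundModes),
              backgroundAmplitudeMm = backgroundAmplitudeMm,
              blobsPerMode = as.integer(blobsPerMode), blobSdMm = blobSdMm,
              populationStructure = populationStructure,
              covariateEffects = covariateEffects,
              seed = as.integer(seed))
  if (!is.na(cfg$causalSnpIndex) &&
      (cfg$causalSnpIndex < 1L || cfg$causalSnpIndex > cfg$m))
    stop("causalSnpIndex must lie in 1..m")
  if (cfg$effectRadiusMm <= 0) stop("effectRadiusMm must be > 0")
  if (cfg$missingRate < 0 || cfg$missingRate > 1)
    stop("missingRate must lie in [0, 1]")
  if (any(cfg$mafRange <= 0) || any(cfg$mafRange > 0.5) ||
      diff(cfg$mafRange) < 0)
    stop("mafRange must be an interval within (0, 0.5]")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate biallelic genotypes
#'
#' Per-SNP allele frequency drawn uniformly from `mafRange` (the causal SNP
#' is forced to `causalMaf`); dosages are Binomial(2, f) per subject;
#' optional two-group structure perturbs group frequencies with a
#' Balding-Nichols Beta draw at the configured divergence; missing calls
#' are planted independently at `missingRate`.  Deterministic under the
#' config seed.
#'
#' The complete (pre-missingness) causal dosage vector and the group labels
#' are attached as attributes `trueCausalDosage` and `groups` for use by
#' the field simulator and the recovery report.
#'
#' @param cfg a [simConfig()].
#' @return A [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m
  f <- runif(m, cfg$mafRange[1L], cfg$mafRange[2L])
  if (!is.na(cfg$causalSnpIndex)) f[cfg$causalSnpIndex] <- cfg$causalMaf
  groups <- rep(0L, n)
  complete <- matrix(0L, n, m)
  if (!is.null(cfg$populationStructure) && cfg$populationStructure > 0) {
    d <- cfg$populationStructure
    groups <- rep(c(0L, 1L), length.out = n)
    for (gidx in 0:1) {
      fg <- rbeta(m, f * (1 - d) / d, (1 - f) * (1 - d) / d)
      fg <- pmin(pmax(fg, 1e-4), 1 - 1e-4)
      rows <- which(groups == gidx)
      complete[rows, ] <- matrix(rbinom(length(rows) * m, 2L,
                                        rep(fg, each = length(rows))),
                                 length(rows), m)
    }
  } else {
    complete <- matrix(rbinom(n * m, 2L, rep(f, each = n)), n, m)
  }
  dosage <- complete
  if (cfg$missingRate > 0)
    dosage[matrix(runif(n * m) < cfg$missingRate, n, m)] <- NA_integer_
  nChrom <- min(4L, m)
  chrom <- if (m) as.character(1L + (seq_len(m) - 1L) %/%
                                 ceiling(m / nChrom)) else character()
  pos <- integer(m)
  for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 1000L
  snps <- data.frame(chrom = chrom,
                     id = sprintf("rs%06d", seq_len(m)),
                     cm = numeric(m), pos = pos,
                     a1 = rep("A", m), a2 = rep("G", m),
                     stringsAsFactors = FALSE)
  g <- genotypeMatrix(dosage, snps = snps)
  attr(g, "trueCausalDosage") <- if (!is.na(cfg$causalSnpIndex))
    complete[, cfg$causalSnpIndex] else NULL
  attr(g, "groups") <- groups
  attr(g, "alleleFreqs") <- f
  g
}

# row-renormalized truncated Gaussian convolution matrix for one axis
.convMatrix <- function(len, sdVox) {
  if (sdVox <= 0) return(diag(len))
  rad <- max(1L, ceiling(3 * sdVox))
  W <- matrix(0, len, len)
  for (i in seq_len(len)) {
    j <- max(1L, i - rad):min(len, i + rad)
    w <- exp(-((j - i)^2) / (2 * sdVox^2))
    W[i, j] <- w / sum(w)
  }
  W
}

# separable Gaussian smoothing of a (X,Y,Z,3) array
.gaussSmooth <- function(a, fwhmMm, spacing) {
  d <- dim(a)
  sdVox <- (fwhmMm / 2.3548) / spacing
  Ws <- lapply(1:3, function(ax) .convMatrix(d[ax], sdVox[ax]))
  for (comp in 1:3) {
    v <- a[, , , comp]
    v <- array(Ws[[1L]] %*% matrix(v, d[1L]), d[1:3])
    v <- aperm(array(Ws[[2L]] %*% matrix(aperm(v, c(2, 1, 3)), d[2L]),
                     d[c(2, 1, 3)]), c(2, 1, 3))
    v <- aperm(array(Ws[[3L]] %*% matrix(aperm(v, c(3, 1, 2)), d[3L]),
                     d[c(3, 1, 2)]), c(2, 3, 1))
    a[, , , comp] <- v
  }
  a
}

# interior variance-reduction factor of the smoothing (per feature)
.smoothVarFactor <- function(fwhmMm, spacing, dims) {
  sdVox <- (fwhmMm / 2.3548) / spacing
  prod(vapply(1:3, function(ax) {
    if (sdVox[ax] <= 0) return(1)
    rad <- max(1L, ceiling(3 * sdVox[ax]))
    w <- exp(-((-rad:rad)^2) / (2 * sdVox[ax]^2))
    w <- w / sum(w)
    sum(w^2)
  }, 0))
}

#' Simulate a deformation-field cohort with a planted localized effect
#'
#' The "brain" is an ellipsoid inside the grid.  Each subject's field is
#' the sum of (a) shared background modes (compact multi-blob shapes) with
#' standard-normal per-subject coefficients, (b) the effect region's
#' natural variability: a standard-normal coefficient times
#' `effectNaturalAmplitudeMm` on the bump shape (plus, with
#' `effectPartner`, a mirrored distant partner region sharing the same
#' coefficient, so that global components mix the two regions), (c) the
#' genetic effect `beta * dosage * bump`, where the bump is a unit-peak
#' compactly supported radial kernel (raised cosine of radius
#' `effectRadiusMm` at `effectCenter`) displacing along +x, (d) optional
#' age/sex-driven smooth modes, and (e) smooth per-subject noise scaled to
#' `smoothNoiseScaleMm` per feature.  The genetic term uses the complete
#' (pre-missingness) causal dosage.
#'
#' @param cfg a [simConfig()].
#' @param g the [GenotypeMatrix-class] from [simulateGenotypes()] under the
#'   same config.
#' @return list with `fields` (list of [VectorField-class]), `mask`
#'   ([BrainMask-class]), `covariates` (data.frame age, sex), and `truth`
#'   (class `GroundTruth`: causal id, region mask array, beta, per-subject
#'   genetic effect, group labels).
#' @export
simulateFields <- function(cfg, g) {
  stopifnot(inherits(cfg, "SimConfig"), is(g, "GenotypeMatrix"))
  if (nrow(g@dosage) != cfg$n) stop("genotypes do not match cfg$n")
  set.seed(cfg$seed + 1000003L)
  d <- cfg$grid; sp <- cfg$spacing; n <- cfg$n
  centerMm <- (d - 1) / 2 * sp
  ax <- 0.42 * (d - 1) * sp
  # voxel centers
  i0 <- (seq_len(prod(d)) - 1L) %% d[1L]
  j0 <- ((seq_len(prod(d)) - 1L) %/% d[1L]) %% d[2L]
  k0 <- (seq_len(prod(d)) - 1L) %/% (d[1L] * d[2L])
  vc <- cbind(i0 * sp[1L], j0 * sp[2L], k0 * sp[3L])
  inside <- ((vc[, 1L] - centerMm[1L]) / ax[1L])^2 +
            ((vc[, 2L] - centerMm[2L]) / ax[2L])^2 +
            ((vc[, 3L] - centerMm[3L]) / ax[3L])^2 <= 1
  maskArr <- array(inside, dim = d)
  mask <- brainMask(maskArr, spacing = sp)

  # bump center: masked voxel nearest to a point offset along +x
  if (is.null(cfg$effectCenter)) {
    targetMm <- centerMm + c(0.3 * ax[1L], 0, 0)
    dist2 <- rowSums(sweep(vc, 2L, targetMm)^2)
    dist2[!inside] <- Inf
    centerVoxLin <- which.min(dist2)
  } else {
    ec <- as.integer(cfg$effectCenter)
    centerVoxLin <- ((ec[3L] - 1L) * d[2L] + (ec[2L] - 1L)) * d[1L] + ec[1L]
  }
  bumpCenterMm <- vc[centerVoxLin, ]
  raisedCos <- function(center) {
    r <- sqrt(rowSums(sweep(vc, 2L, center)^2))
    ifelse(r <= cfg$effectRadiusMm,
           (1 + cos(pi * r / cfg$effectRadiusMm)) / 2, 0)
  }
  bumpVals <- raisedCos(bumpCenterMm)
  support <- bumpVals > 0.01
  if (any(support & !inside))
    stop("effect region extends outside the brain mask; move effectCenter ",
         "or shrink effectRadiusMm")
  rBump <- sqrt(rowSums(sweep(vc, 2L, bumpCenterMm)^2))
  regionMask <- array(rBump <= cfg$effectRadiusMm & inside, dim = d)
  bump <- array(0, dim = c(d, 3L))
  bump[, , , 1L] <- array(bumpVals, dim = d)      # displacement along +x
  maskFeat <- rep(as.vector(maskArr), 3L)
  # natural variability of the effect region; with effectPartner it
  # co-varies (one shared coefficient) with a diffuse pattern over the
  # *rest* of the brain, the way regional anatomy co-varies with global
  # brain scale -- this makes the corresponding global component spatially
  # mixed, while localized components can separate region from partner
  naturalMode <- bump
  if (cfg$effectPartner) {
    pa <- .gaussSmooth(array(rnorm(prod(d) * 3L), c(d, 3L)),
                       2 * cfg$smoothnessFwhmMm, sp)
    pa[!array(maskFeat, c(d, 3L))] <- 0
    ramp <- pmin(1, pmax(0, (rBump - cfg$effectRadiusMm) / 6))
    pa <- pa * array(rep(ramp^2, 3L), dim = c(d, 3L))
    naturalMode <- naturalMode + pa * sqrt(1.5 * sum(bump^2) / sum(pa^2))
  }

  rmsIn <- function(a) sqrt(mean(a[array(maskFeat, c(d, 3L))]^2))
  # background modes: sums of compact Gaussian blobs with random centers
  # and directions (regionally concentrated, as anatomy varies), so global
  # components mix distant regions while localized ones can separate them
  maskedLin <- which(inside)
  modes <- vector("list", cfg$nBackgroundModes)
  for (jm in seq_len(cfg$nBackgroundModes)) {
    mo <- array(0, dim = c(d, 3L))
    for (b in seq_len(cfg$blobsPerMode)) {
      cenMm <- vc[sample(maskedLin, 1L), ]
      dir <- rnorm(3L); dir <- dir / sqrt(sum(dir^2))
      prof <- exp(-rowSums(sweep(vc, 2L, cenMm)^2) / (2 * cfg$blobSdMm^2))
      for (axn in 1:3)
        mo[, , , axn] <- mo[, , , axn] + array(dir[axn] * prof, dim = d)
    }
    modes[[jm]] <- mo * (cfg$backgroundAmplitudeMm / rmsIn(mo))
  }
  coeff <- matrix(rnorm(n * cfg$nBackgroundModes), n)

  age <- runif(n, 108, 173)
  sex <- rbinom(n, 1L, 0.5)
  covModes <- NULL
  if (!is.null(cfg$covariateEffects)) {
    covModes <- lapply(1:2, function(i) {
      mo <- .gaussSmooth(array(rnorm(prod(d) * 3L), c(d, 3L)),
                         cfg$smoothnessFwhmMm, sp)
      mo / rmsIn(mo)
    })
  }

  dose <- attr(g, "trueCausalDosage")
  if (is.null(dose)) dose <- rep(0L, n)
  effectCoeff <- rnorm(n)
  noiseSd <- if (cfg$smoothNoiseScaleMm > 0)
    cfg$smoothNoiseScaleMm /
      sqrt(.smoothVarFactor(cfg$smoothnessFwhmMm, sp, d)) else 0

  fields <- vector("list", n)
  for (i in seq_len(n)) {
    a <- array(0, dim = c(d, 3L))
    for (jm in seq_len(cfg$nBackgroundModes))
      a <- a + coeff[i, jm] * modes[[jm]]
    a <- a + cfg$effectNaturalAmplitudeMm * effectCoeff[i] * naturalMode +
      cfg$effectBeta * dose[i] * bump
    if (!is.null(covModes)) {
      ce <- cfg$covariateEffects
      if (!is.null(ce$age))
        a <- a + ce$age * (age[i] - 140.5) / 18.8 * covModes[[1L]]
      if (!is.null(ce$sex))
        a <- a + ce$sex * sex[i] * covModes[[2L]]
    }
    if (noiseSd > 0)
      a <- a + .gaussSmooth(array(rnorm(prod(d) * 3L, sd = noiseSd),
                                  c(d, 3L)), cfg$smoothnessFwhmMm, sp)
    a[!array(maskFeat, c(d, 3L))] <- 0
    fields[[i]] <- vectorField(a, spacing = sp)
  }

  covariates <- data.frame(age = age, sex = sex)
  rownames(covariates) <- g@samples$iid
  truth <- structure(
    list(causalId = if (!is.na(cfg$causalSnpIndex))
           g@snps$id[cfg$causalSnpIndex] else NA_character_,
         regionMask = regionMask, beta = cfg$effectBeta,
         perSubjectEffect = cfg$effectBeta * dose,
         groups = attr(g, "groups"),
         effectCenterMm = bumpCenterMm),
    class = "GroundTruth")
  list(fields = fields, mask = mask, covariates = covariates, truth = truth)
}

#' Label atlas derived from the planted truth
#'
#' Label 1 is the planted effect region; the rest of the mask is split into
#' up to 8 octants (labels 2-9) around the mask centroid, giving the region
#' attribution a non-trivial ranking task.
#'
#' @param mask a [BrainMask-class].
#' @param truth the `GroundTruth` from [simulateFields()].
#' @return A [LabelVolume-class].
#' @export
truthLabelVolume <- function(mask, truth) {
  d <- mask@dims
  g <- .maskGeometry(mask)
  lab <- array(0L, dim = d)
  cen <- colMeans(g$loc)
  oct <- 1L + (g$loc[, 1L] > cen[1L]) + 2L * (g$loc[, 2L] > cen[2L]) +
    4L * (g$loc[, 3L] > cen[3L])
  lab[g$idx] <- oct + 1L
  lab[truth$regionMask] <- 1L
  nm <- setNames(c("planted_region", sprintf("octant_%d", 1:8)),
                 as.character(1:9))
  labelVolume(lab, spacing = mask@spacing, names = nm)
}

#' Squared-energy fraction of a component inside a region
#'
#' Fraction of the component vector's squared norm carried by features
#' whose voxel lies in `regionMask` — the spatial-compactness measure used
#' to compare localized against global components.
#'
#' @param model a [LocalizedPCAModel-class].
#' @param componentIndex 1-based component index.
#' @param regionMask logical 3-D array on the model grid.
#' @return scalar in `[0, 1]`.
#' @export
componentEnergyInRegion <- function(model, componentIndex, regionMask) {
  stopifnot(is(model, "LocalizedPCAModel"))
  v <- model@components[, componentIndex]
  inRegion <- regionMask[model@maskIdx][model@featureVoxel]
  sum(v[inRegion]^2) / sum(v^2)
}

#' Recovery metrics for a synthetic run
#'
#' Measures how well the pipeline recovered the planted effect: the rank
#' and p-value of the causal SNP in the scan (ties in p broken by genome
#' order), the components selected for the causal SNP by the loading rule,
#' and, over the selected component set (a compact effect may split across
#' a few kernel-width components), the loading-squared-weighted fraction
#' of component energy inside the true effect region, plus whether region
#' attribution of the weighted component-energy map (peak statistic, since
#' the planted effect has a well-defined peak) ranks the planted region
#' first.
#'
#' @param scan GwasTable from [gwasScan()] (with `loadings` attribute).
#' @param model the fitted [LocalizedPCAModel-class] the traits came from.
#' @param truth the `GroundTruth` from [simulateFields()].
#' @param atlas optional [LabelVolume-class]; defaults to
#'   [truthLabelVolume()] built from the truth.
#' @param mask the [BrainMask-class] (needed when `atlas` is `NULL`).
#' @return list with `causalRank`, `causalP`, `selected`, `topComponent`,
#'   `energyInRegion`, `topRegionLabel`, `topRegionIsPlanted`.
#' @export
recoveryReport <- function(scan, model, truth, mask = NULL, atlas = NULL) {
  idx <- match(truth$causalId, scan$id)
  if (is.na(idx)) stop("causal SNP ", truth$causalId, " not in scan")
  ord <- order(scan$p, .chromRank(scan$chrom), scan$pos, na.last = TRUE)
  causalRank <- which(ord == idx)
  L <- attr(scan, "loadings")
  loadings <- L[idx, ]
  selected <- selectComponents(loadings)
  top <- if (length(selected))
    selected[which.max(abs(loadings[selected]))] else which.max(abs(loadings))
  use <- if (length(selected)) selected else top
  wts <- loadings[use]^2 / sum(loadings[use]^2)
  compE <- vapply(use, function(j)
    componentEnergyInRegion(model, j, truth$regionMask), 0)
  energy <- sum(wts * compE)
  if (is.null(atlas)) {
    if (is.null(mask)) stop("provide mask or atlas")
    atlas <- truthLabelVolume(mask, truth)
  }
  emap <- 0
  for (t in seq_along(use)) {
    fl <- .vectorToGrid(model@components[, use[t]], model@dims,
                        model@maskIdx)
    emap <- emap + wts[t] * (fl[, , , 1L]^2 + fl[, , , 2L]^2 +
                               fl[, , , 3L]^2)
  }
  attribution <- regionAttribution(sqrt(emap), atlas, stat = "max")
  list(causalRank = causalRank, causalP = scan$p[idx], selected = selected,
       topComponent = top, componentEnergies = compE,
       energyInRegion = energy,
       topRegionLabel = attribution$label[1L],
       topRegionIsPlanted = attribution$label[1L] == 1L,
       attribution = attribution)
}
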