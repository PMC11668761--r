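---
title: "Localized morphometric components for multivariate GWAS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized morphometric components for multivariate GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

## From deformation fields to phenotypes

Each subject enters as a 3-D displacement field on a common atlas grid:
one mm-valued 3-vector per voxel, the output of non-linear registration.
Restricted to a brain mask and flattened (voxels in x-fastest grid order,
the three axis components of a voxel contiguous), the cohort is an
`n x p` matrix `X` with `p = 3 * nVoxels`. Every feature has a spatial
location — its voxel center — and that geometry is what the method
exploits.

## Localized PCA by covariance manipulation

Standard PCA diagonalizes the sample covariance `C` of the centered
cohort. Its leading components are optimal for variance but spatially
global: one component routinely mixes distant, anatomically unrelated
regions, which makes a genetic association with that component hard to
interpret. The localized variant multiplies `C` element-wise with a
distance kernel before the eigendecomposition,

\[
  (C \circ K)_{ij} = C_{ij}\,
  \exp\!\left(-\frac{\lVert x_i-x_j\rVert^2}{2\sigma^2}\right),
  \qquad \sigma = f \cdot D ,
\]

where `D` is the diagonal of the axis-aligned bounding box around the
mask (computed voxel-center to voxel-center) and `f` is the *locality
fraction*. Covariance between distant features is shrunk toward zero, so
eigenvectors become spatially compact. Two properties make the
manipulation well behaved:

* the Gaussian kernel matrix is positive semidefinite with unit
  diagonal, so `C o K` is PSD by the Schur product theorem — eigenvalues
  are genuine variances;
* `diag(K) = 1` preserves the trace, so "fraction of total variance
  retained" means the same thing at every kernel width, including the
  `GLOBAL` setting (`f = Inf`, `K = 1`), which reproduces standard PCA
  exactly.

Components are retained until 90% of the trace is covered (the
`varianceTarget`); when the numerical spectrum is exhausted first, the
model carries a `rankLimited` flag instead of silently under-delivering.

## The genetic association model

Scores of all subjects on the training-fit model are the multivariate
phenotype. After residualizing every score column on an intercept, sex,
age and the first 10 genetic principal components, each SNP is tested by
canonical correlation analysis. With a single variant on one side, CCA
collapses to the multiple correlation `r` of the trait block with the
dosage; Wilks' lambda is `1 - r^2` and

\[
  F = \frac{n-k-1}{k}\,\frac{r^2}{1-r^2} \sim F(k,\; n-k-1)
\]

under the null, with `k` the number of components and `n` the complete
cases for that SNP. Per-component *loadings* are structure correlations —
the Pearson correlation of each score column with the fitted canonical
variate — and drive component selection with the absolute threshold 0.2,
falling back to 0.15 when nothing passes (this interpretation, rather
than raw canonical weights, matches how correlation-scaled thresholds are
used in practice; it is a deliberate reading, flagged here). Selected
components are explored generatively: `mean + alpha * sqrt(lambda_j) v_j`
walks `alpha` standard deviations along component `j`, and the magnitude
map of a component is summarized per region of a label atlas.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fractions` | GLOBAL, 3/4, 1/2, 1/8, 1/16, 1/64, 1/128 | kernel widths as fractions of the mask bounding-box diagonal; GLOBAL = standard PCA, 1/128 is near voxel-wise |
| `varianceTarget` | 0.90 | retained trace fraction per model |
| `trainFraction` | 0.80 | subjects used to fit; the rest only report reconstruction error |
| `truncationSigmaMult` | 3 | kernel support cutoff in sigmas (weights < ~0.011 stored as exact zeros) |
| QC `mafMin/genoMax/mindMax/hwePMin` | 0.05 / 0.1 / 0.1 / 0.001 | marker and sample filters, applied in the fixed order snps-only, mind, geno, maf, hwe |
| `loadingPrimary/Fallback` | 0.2 / 0.15 | component-selection thresholds on absolute structure correlations |
| `nGeneticPCs` | 10 | stratification covariates |
| `significanceLine` | 1e-8 | Manhattan reference line |
| `seed` | required, default 0 | controls the train/test split and solver start |

Filter order matters for the bookkeeping: missingness filters run before
frequency filters, and geno/maf/HWE statistics are recomputed on the
post-`mind` sample set, so the per-step removal counts in the QC report
are reproducible.

# Numerical choices

* **Matrix-free eigensolver.** `p` is three times the voxel count, so the
  `p x p` manipulated covariance is never materialized. Its action is
  `(C o K) v = (n-1)^{-1} \sum_r z_r \circ (K (z_r \circ v))` over
  centered training rows. Because the kernel depends only on voxel
  centers, `K` factorizes as a voxel-level sparse kernel times an
  all-ones 3 x 3 block, and each subject term collapses to one sparse
  voxel-kernel product. ARPACK (symmetric Lanczos, via igraph) extracts
  leading eigenpairs, requesting them in doubling blocks until the
  variance target is met — the needed count is data- and width-dependent.
* **GLOBAL fast path.** With `K = 1` the fit is computed exactly in
  sample space from the `n x n` Gram matrix; this *is* standard PCA, and
  the test suite cross-checks it against an independent dense
  feature-space eigendecomposition.
* **Determinism.** Components carry a fixed sign convention (largest
  absolute entry positive, ties to the lowest feature index); eigenvalues
  below `1e-12 * trace` are treated as zero; the split and any solver
  randomness derive from the configured seed.
* **Kernel truncation.** Support is cut at 3 sigma (configurable). The
  discarded weights are below ~0.011, a negligible spectral perturbation
  in exchange for bounded sparsity.
* **Degenerate inputs.** A zero-variance cohort yields `k = 0` with
  retained fraction defined as 1; SNPs with too few complete cases or a
  constant dosage are reported untestable (`NA` p) rather than dropped
  silently; p-values are floored at 1e-300.
* **Warping.** Displacements are stored in mm; image warping is backward
  with trilinear interpolation and zero outside the grid — the convention
  of diffeomorphic registration tooling. Fields are treated as
  displacements on the atlas grid, agnostic to forward/backward
  registration direction.

# The synthetic study design

The generator exists so every stage is testable without access-restricted
imaging or genotype data. Its defaults are the package's study
conditions; they were chosen once, on the following reasoning, and are
not per-experiment dials.

* **Grid and mask.** 16 x 16 x 16 voxels at 2 mm, with an ellipsoidal
  "brain" (~1050 voxels, p ~ 3100). The planted effect region (radius
  6 mm) is then ~11% of the mask — regional, not hemispheric.
* **Background variability** is a small set of shared modes, each a sum
  of two compact Gaussian blobs (SD 2 mm) at random masked locations with
  one standard-normal coefficient per subject per mode (RMS 0.65 mm).
  Anatomical variability is regionally concentrated, and multi-blob modes
  are exactly what makes *global* components mix distant regions. With
  whole-mask smooth noise as the dominant variance instead, the
  manipulated covariance has a near-flat spectrum and the 90% model needs
  more components than there are subjects — a degenerate CCA. That
  observation shaped this design.
* **The effect model.** The causal variant shifts a region that
  *naturally varies*: a raised-cosine bump (unit peak, compact support)
  carries natural variability of SD 1.4 mm whose subject coefficient is
  shared with a diffuse whole-brain partner pattern (1.5 x the bump
  energy, tapered to zero inside the region), the way regional anatomy
  co-varies with global brain scale. The genetic term adds
  `beta * dosage` along the bump only (`beta` = 0.5 mm per allele, twice
  the smooth-noise scale; causal allele frequency 0.3). Two consequences
  are intended: the *global* component associated with the SNP is
  spatially mixed (bump + partner), while localized components isolate
  the bump; and the marginal per-component correlation with dosage is
  realistically weak (~0.2), so detection genuinely relies on the
  multivariate scan conditioning on the co-varying components — the
  argument for multivariate association in the first place.
* **Noise** is per-subject white noise smoothed to 6 mm FWHM and scaled
  to 0.25 mm per feature; genotypes are Binomial(2, f) with f uniform on
  [0.05, 0.5], 1% missing calls, optional two-group Balding-Nichols
  structure; age is uniform on 108-173 months and sex Bernoulli(0.5),
  with optional covariate effects on the fields.

What the generator does **not** emulate: registration error and its
spatial correlation structure, scanner/site effects, realistic MRI
intensities, linkage disequilibrium between markers, and relatedness.
Passing recovery tests therefore demonstrate the pipeline's statistical
behavior under its own assumptions, not performance on real cohorts.

## Recovery metrics

`recoveryReport` measures: the causal SNP's rank and p in the scan (ties
broken by genome order); the loading-selected component set; the
loading-squared-weighted fraction of component energy inside the true
region (a compact effect legitimately splits across a few kernel-width
components, so set-weighted energy is more stable than a single
component's); and region attribution of the weighted component-energy map
using the peak statistic, against a truth-derived atlas whose label 1 is
the planted region and whose remaining labels are mask octants.

Two harness decisions deserve note. First, power of a planted marker is
measured conditional on the marker being tested: when a finite-sample
genotype fluctuation pushes the causal SNP past the HWE filter, the
recovery run re-adds it for the scan and flags `causalRescued` — QC
behavior itself is tested separately. Second, genetic PCs are computed
from the QC-passing markers only: with desk-scale marker counts
(`m < n`) the PCs are near-degenerate noise directions, and a
variance-inflated (HWE-violating) column can rotate a PC onto itself,
absorbing the association during residualization.

# Problem sizes

The shipped tests and the acceptance script run, by design, at desk
scale: oracle comparisons on 20-subject cohorts over a 6^3 grid, where a
dense eigendecomposition is exact and cheap; recovery and calibration
runs at n = 300 subjects, m = 200 SNPs on the 16^3 grid, where a
localized model retains roughly 50-80 components. The methods themselves
have no such limits — the fit is matrix-free and the scan is linear in
markers — but runtime grows with voxel count, component count and
ARPACK's restart behavior.

# Known limitations

* Only Gaussian locality kernels and Euclidean distance; no
  anatomically-informed distances (e.g. respecting hemispheric
  separation).
* The per-SNP test is the single-predictor CCA F approximation; exact
  parity with external multivariate-PLINK implementations is not claimed
  (their missing-data and degrees-of-freedom conventions are not fully
  published).
* The 20% held-out split only reports reconstruction error; model and
  traits come from all subjects projected on the training fit. The
  underlying protocol leaves the held-out role open; this reading is the
  package's choice.
* Registration itself (brain extraction, bias correction, diffeomorphic
  alignment) is upstream: the package consumes deformation fields, it
  does not compute them.
* At small marker counts the genetic PCs absorb a non-negligible share of
  any single SNP's dosage; with array-scale marker counts this vanishes.
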