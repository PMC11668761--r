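# LocMorph

Spatially localized morphometric components as imaging-derived phenotypes
for multivariate GWAS.

## The problem

Deformation-based morphometry encodes each subject's brain shape as a 3-D
displacement field on a common atlas grid, produced by non-linear
registration. Genetic association studies need low-dimensional,
interpretable phenotypes from these fields. Standard PCA supplies
low-dimensional components, but each component mixes distant, anatomically
unrelated regions, so a SNP association with a component says little about
*where* the effect acts. LocMorph implements the alternative: **spatially
localized PCA**, which suppresses covariance between distant voxels before
the eigendecomposition, together with the genetics machinery needed to use
the resulting components as endophenotypes in a per-SNP
canonical-correlation scan.

It is aimed at imaging-genetics researchers who have (a) cohorts of
deformation fields in NIfTI form, (b) genotypes in PLINK 1 binary form,
and (c) basic covariates — or who want to study the method itself on the
package's fully synthetic cohorts.

## The method

Let `X` be the n x p matrix of vectorized masked displacement fields
(p = 3 x voxels) with sample covariance `C`. For feature locations
`x_i, x_j` (mm) the locality kernel is

    K_ij = exp( -||x_i - x_j||^2 / (2 sigma^2) ),    sigma = f * D,

where `D` is the diagonal of the bounding box around the brain mask and
`f` the *locality fraction* (`GLOBAL`, i.e. f = Inf, makes K identically 1
and recovers standard PCA). The analysis diagonalizes the Hadamard
(element-wise) product `C o K` instead of `C`. Because `K` is positive
semidefinite with unit diagonal, `C o K` is PSD (Schur product theorem)
and `trace(C o K) = trace(C)`, so "fraction of variance retained" remains
comparable across kernel widths. Components are extracted iteratively
(matrix-free ARPACK; the p x p matrix is never formed) until 90% of the
variance is retained.

Component scores, adjusted for sex, age and 10 genetic principal
components, enter a per-SNP canonical correlation analysis: with a single
SNP, the canonical correlation `r` is the multiple correlation of the
trait block with the dosage, Wilks' lambda is `1 - r^2`, and

    F = ((n - k - 1) / k) * r^2 / (1 - r^2)  ~  F(k, n - k - 1)

under the null. Components linked to a SNP are selected by structure
correlations (|loading| > 0.2, falling back to 0.15), explored by sampling
along their axes, and attributed to regions of a label atlas.

Genotype QC (minor allele frequency, per-SNP and per-sample missingness,
Hardy-Weinberg exact test, single-character allele codes) and PLINK 1
binary I/O are built in.

## Worked example

The synthetic-data generator plants a compact, genotype-dose-dependent
deformation bump whose natural variability co-varies with a diffuse
whole-brain pattern, inside a cohort with regional background modes and
smooth noise. One call runs the full pipeline — simulate, QC, genetic PCs,
localized PCA, residualization, scan, recovery metrics — at a global and a
1/16 kernel width:

```r
library(LocMorph)
cfg <- defaultConfig()
cfg$seed <- 1L
rep <- cmdRecovery(cfg, fractions = c("global", "1/16"))
```

```
recovery [global]: causal rank 61, energy in region 0.0803
recovery [1-16]: causal rank 1, energy in region 0.634
```

Reading: in the global-PCA scan the causal SNP ranks 61st of 200 and the
component selected for it carries only 8% of its energy in the true effect
region (the effect is diluted across the brain); in the 1/16 localized
scan the causal SNP ranks **first** (p ~ 1e-8) and the selected component
concentrates 63% of its energy in the planted region, whose label also
tops the region attribution. That contrast — same data, same scan, only
the kernel width changed — is the point of the method.

Step-by-step equivalents (`cmdSimulate`, `cmdFit`, `cmdGwas`,
`cmdInterpret`) write NIfTI/PLINK/TSV artifacts, Manhattan plots and
warped-atlas previews to an output directory; a thin command-line wrapper
lives at `inst/scripts/locmorph-cli.R`. All scientific settings travel in
a validated YAML config (see `defaultConfig()`).

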