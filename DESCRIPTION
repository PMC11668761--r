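Package: LocMorph
Title: Localized Morphometric Components as Imaging-Derived Phenotypes for
    Multivariate GWAS
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatially localized principal component analysis of cohorts of
    3-D displacement (deformation) fields via distance-kernel manipulation of
    the sample covariance matrix, producing compact morphometric components
    that serve as multivariate imaging-derived phenotypes in a per-SNP
    canonical-correlation genome-wide association scan.  Includes NIfTI
    vector-field I/O, PLINK binary genotype I/O with quality-control
    filtering (minor allele frequency, missingness, Hardy-Weinberg exact
    test) and genetic principal components, covariate adjustment, Wilks'
    lambda F tests with component-loading selection, Manhattan outputs,
    generative sampling along component axes with region attribution against
    a label atlas, and a synthetic-data generator that plants a spatially
    localized, genotype-dose-dependent deformation effect for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Matrix,
    igraph,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
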