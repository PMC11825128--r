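Package: subtexmap
Title: Data-Driven Microstructural Mapping of Subcortical Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps the internal microstructural organization of a subcortical
    brain structure directly from a volumetric intensity image (histology or
    quantitative MRI) and a binary mask. Builds a multiscale first-order
    texture feature bank (windowed mean, variance, skewness and kurtosis with
    outlier exclusion), projects it to a two-dimensional voxel embedding,
    tests embedding components against anatomical axes with variogram-matched
    spatial autocorrelation null models, validates them against probabilistic
    subregion atlases (top-fraction cores, maximum probability parcellation,
    ANOVA with spatial nulls), derives quantile-based subregions, and
    contrasts their seed-based functional connectivity across subjects with
    max-statistic sign-flip permutation family-wise error control. Includes
    seeded synthetic-data generators (planted intensity gradients, axis-tiled
    probabilistic atlases, coupled seed/cortex time series) so every stage can
    be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    uwot,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
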