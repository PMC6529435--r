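Package: facedec
Title: Linear Latent-Space Decoding of Face Images from fMRI Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains linear brain-decoding models that map multi-voxel fMRI
    activation patterns to a latent face space and back.  A voxel weight matrix
    is estimated by closed-form least squares from HRF-convolved parametric
    regressors (one per latent dimension plus a constant bias term), and novel
    activation patterns are decoded by inverting the linear system.  Includes a
    PCA latent face space, a parametric face-image generator and a forward BOLD
    simulator with region-structured signal for end-to-end validation,
    two-criterion voxel selection with a posterior/rostral-caudal region split,
    rank-based Monte-Carlo and exhaustive identification nulls, binomial and
    Friedman tests, attribute-axis (gender) classification, voxel sensitivity
    maps, structural-similarity scoring and variance partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
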