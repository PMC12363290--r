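Package: hybridGP
Title: Hybrid-Kernel Genomic Prediction with Pedigree and Gaussian Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of relationship kernels for genomic
    prediction in plant breeding: the pedigree-based numerator relationship
    matrix (A), the linear genomic relationship matrix (G = XX'/p), the
    Gaussian kernel (K) with median-heuristic bandwidth, and the hybrid
    symmetric kernels C and P derived from the upper and lower triangular
    parts of the matrix product K x A. Bayesian multi-kernel mixed models for
    single-environment (S1-S5) and multi-environment (M1-M5) prediction are
    fitted by Gibbs sampling, with unstructured environment covariances
    (Kronecker form) for balanced data and Hadamard incidence covariances for
    unbalanced data. Includes repeated k-fold and environment-masking
    cross-validation with Pearson and predictive mean squared error summaries,
    and a synthetic-data generator emulating elite yield trial datasets for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hybridGP-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'markers.R'
    'kernels.R'
    'fit-single.R'
    'fit-multi.R'
    'evaluation.R'
    'simulate.R'
    'io.R'
    'interface.R'
    'utils.R'
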