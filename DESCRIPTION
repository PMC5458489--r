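Package: subtomo
Title: Subtomogram Averaging for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for subtomogram averaging of cryo-electron tomography
    particles: missing-wedge-aware rotational and translational alignment by
    locally normalized cross-correlation, iterative wedge-compensated
    averaging with threshold selection and multireference classification,
    PCA on a blockwise pairwise cross-correlation matrix, membrane-geometry
    particle seeding from tomogram annotations, and a first-come-first-served
    parallel task pool coordinated through file semaphores. Includes MRC and
    EM volume I/O, plain-text particle tables and a synthetic phantom
    generator providing ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
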