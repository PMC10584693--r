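Package: mitoscale
Title: Scaling of Mitochondrial DNA Copy Number with Cell Volume in Budding Yeast
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how mitochondrial DNA (mtDNA) copy number scales with
    cell volume in budding yeast. Provides a 3D confocal image pipeline that
    counts nucleoids and segments the mitochondrial network per cell (Gaussian
    prefiltering, Li auto-thresholding, 3D local-maxima spot detection,
    resolution-spheroid deduplication, and an iterative Welch-test validation
    of candidate foci against the local mitochondrial signal); an absolute
    qPCR copy-number calculus with standard-curve calibration and
    budding-index ploidy correction; scaling statistics (binned means, linear
    fits to replicate means, constant-amount expectation ratios, flow-cytometry
    background subtraction); a minimal limiting-factor steady-state model of
    mtDNA homeostasis with gene-dosage predictions; and seeded synthetic-data
    generators that emit ground-truthed microscopy stacks, qPCR plates, and
    cell populations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
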