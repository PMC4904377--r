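Package: csetr
Title: Compressed Sensing Reconstruction for Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Slice-wise compressed-sensing reconstruction of single-axis
    electron tomography tilt series. Implements a Radon-domain split Bregman
    solver minimizing a least-squares data term with combined total-variation,
    identity and Daubechies-8 wavelet l1 penalties, together with weighted
    backprojection and SIRT baselines, simulated membrane and nanoparticle
    phantoms with Poisson/Gaussian projection noise models, compressibility
    metrics, and harnesses for sparsity-versus-error and random-versus-uniform
    tilt sampling experiments. Reads and writes MRC2014 volumes, TIFF stacks
    and plain-text tilt-angle files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    parallel,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
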