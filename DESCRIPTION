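Package: nltvrecon
Title: Compressed-Sensing MRI Reconstruction with Nonlocal Total Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of magnetic resonance images from undersampled
    k-space data by split Bregman minimization of a nonlocal total variation
    (NLTV) regularizer with a least-squares data-fidelity term. Provides
    synthetic phantoms, variable-density Cartesian undersampling masks, a
    unitary partial-Fourier forward model with Gaussian and Rician noise,
    patch-similarity weight graphs with discrete nonlocal gradient,
    divergence and Laplacian operators, an isotropic-TV split Bregman
    baseline, image-quality metrics (SNR, relative error, SSIM, FSIM with
    log-Gabor phase congruency), and a reduced-scale experiment runner with
    a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    png,
    tiff,
    RNifti
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
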