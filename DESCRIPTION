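Package: klrcs
Title: Kernel Low-Rank Compressed Sensing for Preclinical Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compressed-sensing reconstruction of undersampled multi-coil
    diffusion MRI, centred on a kernel low-rank (KLR) reconstruction that
    handles complex data either through low-resolution-phase (LRP) maps or
    through composite (real/imaginary) kernel PCA, alongside a conventional
    L1-wavelet + total-variation CS baseline. Includes variable-density
    Monte-Carlo and Poisson-disk k-space undersampling mask design with
    acceleration-factor bookkeeping, a synthetic multi-coil diffusion-weighted
    k-space simulator (tensor phantoms, smooth complex coil profiles, object
    phase, noise, frequency-drift shifts), log-linear diffusion tensor fitting
    with FA/MD maps, and evaluation metrics (subpixel rigid registration,
    absolute percent error, 3-D SSIM, peak SNR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
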