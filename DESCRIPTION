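Package: multiecho
Title: Multi-Echo fMRI Denoising, Echo Combination, and Reliability Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for denoising multi-echo functional MRI. Implements
    voxelwise monoexponential T2* decay fitting and T2*-weighted optimal echo
    combination; an early ICA-based denoising stage that decomposes the
    Z-concatenated echoes and classifies components as motion or signal from
    realignment-correlation, high-frequency-content, and edge/CSF spatial
    features; a minimal TE-dependence (kappa/rho) component classifier applied
    to the combined series; quality metrics (DVARS, framewise displacement,
    temporal SNR, carpet matrices, Shannon entropy); and functional-connectome
    reliability metrics (seed-based spatial reliability, Cronbach's alpha,
    sliding-window ICC curves with AUC and minimum-data-percentage). Includes
    a synthetic multi-echo phantom generator with full ground truth and a
    BIDS-flavoured I/O layer, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    MASS,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
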