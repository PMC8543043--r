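Package: InSpect
Title: Integrated Spectral Component Estimation and Mapping for
    Multi-Contrast Quantitative MRI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data-driven spectroscopic analysis of single- and
    multi-contrast quantitative MRI. InSpect jointly estimates a small
    set of canonical spectral components (e.g. T2*-ADC correlation
    spectra) shared across an image together with per-voxel weight maps,
    by alternating non-negative least-squares component updates and
    simplex-constrained weight updates on a Gaussian likelihood. The
    package also provides the standard voxelwise Tikhonov-regularised
    NNLS spectrum inversion with spectral-region-of-interest (sROI)
    integration for comparison, BIC-based selection of the number of
    components, a synthetic diffusion-relaxometry phantom generator with
    Rician noise, and NIfTI/TSV input-output plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
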