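Package: npwmf
Title: Nonprewhitening Matched Filter Model Observers for CT Low-Contrast Detectability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Task-based image quality assessment for computed tomography with the
    nonprewhitening matched filter (NPWMF) model observer, computed three ways:
    in the Fourier domain from the noise power spectrum (NPS) and task transfer
    function (TTF), and in the spatial domain from region-of-interest decision
    variables with or without the assumption of Gaussian observer responses.
    Includes internal-noise calibration, analytic and bootstrap uncertainty
    estimates, percent-correct to AUC conversion for M-alternative forced choice
    experiments, and a synthetic phantom-ensemble simulator with correlated
    noise and a denoiser surrogate so that every estimation path can be tested
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools, jsonlite, yaml, tiff
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
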