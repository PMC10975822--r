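Package: bispeckle
Title: Single-Shot Imaging Through Scattering Media via Truncated Bispectrum Phase Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs objects hidden behind thin scattering media from a
    single speckle frame. The object's Fourier amplitude is recovered from the
    windowed speckle autocorrelation (Wiener-Khinchin route), and its Fourier
    phase from truncated bispectra of Radon-projected sub-speckle tiles using
    recursive phase closure, replacing iterative phase retrieval. Includes a
    Fourier-optics speckle simulator (random phase screen diffuser), a Fienup
    ER/HIO baseline, reconstruction quality metrics, and a truncation-parameter
    sweep with data-reduction accounting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    grDevices,
    graphics,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    tibble,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
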