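Package: ionobeat
Title: Ionoacoustic Range Verification with Photoacoustic Contrast Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and signal analysis for ionoacoustic (protoacoustic)
    range verification in proton therapy, including photoacoustic enhancement by
    optical contrast agents. Provides an analytic proton depth-dose (Bragg curve)
    model, Monte Carlo transport of proton-induced luminescence photons in layered
    phantoms, thermoacoustic initial-pressure conversion via the Grueneisen relation,
    a k-space pseudospectral solver for linear acoustic propagation in heterogeneous
    media (1D/2D), realistic accelerator pulse time structures (square bursts,
    Gaussian synchro-cyclotron pulses, stochastic synchrotron micro-structure), a
    detector-response model, and the frequency-domain analysis chain: Daubechies
    wavelet denoising, spectral amplitude and Hilbert phase extraction, and
    spectrum-beat (cepstral) estimation of the Bragg-peak-to-target-edge distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
SystemRequirements: fftw3
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
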