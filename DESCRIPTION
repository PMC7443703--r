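Package: megdbs
Title: Phantom Simulation and Comparative Evaluation of DBS Artefact
    Rejection for MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how deep brain stimulation (DBS) artefacts
    contaminate magnetoencephalography (MEG) recordings and how well
    sensor-level rejection algorithms recover the underlying signal. The
    package generates synthetic spherical-phantom recordings with a
    calibrated 12 Hz dipole, an under-sampled biphasic DBS pulse train
    (including aliased spectral peaks), and movement-coupled wire
    artefacts; implements four cleaning algorithms (frequency-domain
    Hampel filter, spectral signal space projection, ICA with
    mutual-information component selection, and temporal signal space
    separation); and evaluates them with band-wise log-power RMSE against
    a reference condition, LCMV beamformer source maps with bootstrap
    activation thresholds, and an intersection-over-union overlap
    measure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    pracma,
    signal,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
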