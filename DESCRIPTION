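Package: popcode
Title: Dynamic Population Coding Analysis for Auditory Cortical Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how neural populations encode stimulus
    identity over time. Implements trial-aligned spike-train bookkeeping with
    fixed-length and constant-spike-count read-out windows, per-neuron
    selectivity profiling by Poisson conditional testing, mutual information
    between stimuli and windowed spike counts with Treves-Panzeri
    finite-sampling bias correction and the Ma lower bound, single-neuron and
    population decoders (PCA plus linear discriminant analysis, Euclidean and
    angular template matching) under cross-validation, Poisson spiking
    diagnostics (Fano factor, coefficient of variation, likelihood-ratio
    goodness of fit, discriminability), uniform-adaptation count simulations,
    population response trajectories in principal-component space, and a
    configurable inhomogeneous-Poisson population generator emulating tone
    responses in primary auditory cortex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
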