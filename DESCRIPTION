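Package: itinerancy
Title: Metastable Phase-Cluster Itinerancy in Pulse-Coupled Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mesoscopic excitatory-inhibitory networks of Izhikevich
    neurons (slow pyramidal cells driving fast-spiking interneurons through
    instantaneous pulse coupling) and measures the metastable phase-cluster
    states that emerge in the inhibitory population. Provides burst-phase
    extraction (low-pass Butterworth filtering, standardization, Hilbert
    transform), Kuramoto-Daido order parameters and the redundancy-corrected
    cluster-stability metric Gn, Gaussian-mixture phase clustering, Rand and
    adjusted Rand indices, and a perturbation-based collective-response metric,
    together with experiment drivers for frequency sweeps, connectivity grids
    and collective-response curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
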