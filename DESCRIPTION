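Package: tcsleep
Title: Thalamocortical Network Simulation of Sleep-Dependent Memory Consolidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of a four-population thalamocortical
    network (cortical pyramidal and inhibitory neurons, thalamic relay and
    reticular neurons) whose awake, N2 and N3 sleep stages are switched by
    neuromodulator scaling of potassium leak, AMPA and GABA-A conductances.
    Cortical excitatory synapses are plastic under a symmetric spike-timing
    dependent plasticity rule, which allows sequence memories trained in the
    awake stage to be replayed and consolidated during sleep spindles (N2)
    and slow oscillations (N3). Includes the full measurement toolkit for
    such experiments: string-match sequence scoring, recall-sequence
    detection, replay counting in spike rasters, spatial cross-correlation,
    spatiotemporal cluster analysis, synaptic-weight trajectory statistics,
    experiment presets, and a synthetic raster generator for testing the
    analysis chain without running the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
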