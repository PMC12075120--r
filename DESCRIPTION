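Package: colrhythm
Title: Spiking Cortical Column Model of Mouse V1 with Plasticity-Driven Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a data-constrained spiking network model
    of a mouse primary visual cortex column. The column comprises 17 cell groups
    (pyramidal, PV, SST and VIP interneurons across layers 1 to 6) of leaky
    integrate-and-fire neurons coupled through conductance-based AMPA, NMDA and
    GABA-A synapses, driven by per-group Poisson background input. Long-term
    plasticity is available as pair-based exponential STDP on
    excitatory-to-excitatory synapses and a symmetric "sunken Mexican hat" rule
    on PV-to-pyramidal synapses. The package bundles the published membrane and
    background-rate parameter tables, a synthetic generator for
    inhibition-dominated connectivity, the experiment protocols (spontaneous,
    evoked, STDP conditioning, inactivations, layer-4 isolation, weight-shuffle
    and uniform-increase controls, input sweeps) and a measurement layer
    (population rates, ISI irregularity, membrane-potential synchrony, Welch
    power spectra, activation latencies, rate cross-correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
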