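Package: striderSwarm
Title: Individual-Based Swarm Model of Water Strider Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a size-heterogeneous group of water striders (Gerris)
    on a bounded two-dimensional water surface. Individuals interact through
    short-range Gaussian repulsion and weak long-range Gaussian attraction
    whose amplitudes and radii scale with body mass, are confined by soft
    exponential boundary walls, chase randomly deposited food portions, grow
    by mass-proportional food assimilation, lose stored mass at a constant
    rate, are recruited at a small starting mass and removed on reaching
    critical minimal or maximal mass. A transient long-range "wave of fear"
    forcing from one shore can be scheduled periodically. The package provides
    a seeded, reproducible simulation engine (compiled inner loop), the
    observables used to characterise such populations (nearest-neighbour
    distance and mass/volume histograms, velocity-mass curves, time-volume
    maps, size-class time series, one-dimensional density profiles), a
    perspective camera-to-ground-plane reduction for field video detections
    with a synthetic scene generator, a two-sample Kolmogorov-Smirnov
    comparison helper, canned scenario configurations and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
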