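Package: eicrit
Title: Criticality and Synchronous Transitions in Excitation-Inhibition
    Balanced Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of excitation-inhibition (E-I) balanced
    networks of leaky integrate-and-fire neurons with bi-exponential synaptic
    kinetics. Provides a fast compiled network simulator, a semi-analytical
    mean-field reduction (six-dimensional field equations) with fixed-point,
    Jacobian and Hopf-bifurcation analysis of the synchronous transition,
    spike-train statistics (coefficient of variation of inter-spike
    intervals, Fano factors, pairwise correlations, voltage coherence, Welch
    power spectra), a neuronal-avalanche criticality pipeline (doubly
    truncated discrete power-law maximum likelihood with Kolmogorov-Smirnov
    surrogate testing, size-duration scaling, the crackling-noise exponent
    relation), a demographic-noise Langevin model of avalanche first-passage
    times, up-state detection with inter-spike-interval shuffling surrogates,
    and seeded synthetic raster generators for testing every statistic
    without a network run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
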