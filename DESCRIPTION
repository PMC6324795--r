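Package: ivlsim
Title: In-Vivo-Like Synaptic Input Regimes in a Reduced Hippocampal Interneuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced multi-compartment conductance-based model of a
    hippocampal interneuron-specific type 3 (IS3) cell under parameterized
    excitatory and inhibitory synaptic bombardment, and classifies the resulting
    regimes with an "in-vivo-like" (IVL) metric built from subthreshold membrane
    potential statistics, spike irregularity, and spike amplitude. Provides a
    deterministic synthetic morphology and synapse bank, double-exponential
    synapse kinetics with distance-dependent weight rules, uniform-sampled and
    theta-timed (8 Hz) presynaptic spike train generators with common-input
    grouping, a backward-Euler branched cable integrator with somatic Gaussian
    noise (compiled), passive and noise calibration to measured input resistance
    and voltage fluctuation targets, excitation-inhibition balance metrics,
    4-D input-grid sweeps with pool division and clutter-based dimensional
    reordering (CBDR) images, somatic voltage-clamp conductance isolation, and
    theta-cycle analyses of spike-train power spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
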