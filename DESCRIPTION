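Package: sigprop
Title: Signal-Propagation Atlases from Stimulation-Response Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build statistical functional-connectivity atlases from
    single-neuron stimulation experiments with whole-brain calcium imaging.
    Implements calcium-trace pre-processing (missing-value interpolation,
    double-exponential photobleach correction, outlier removal, causal
    Savitzky-Golay smoothing, windowed dF/F0), autoresponse-based inclusion
    criteria, empirical-null Kolmogorov-Smirnov testing with Fisher combination
    and Storey-Tibshirani false-discovery-rate q-values, TOST equivalence
    testing for functionally non-connected pairs, symbolic fitting of
    signal-propagation kernels as sums of convolved decaying exponentials,
    kernel-based network simulation of activity correlations, and a
    connectome-constrained leaky-integrator biophysical model with hop-distance
    and agreement statistics. A synthetic-data module generates ground-truth
    networks, recordings and matched connectomes so the whole pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
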