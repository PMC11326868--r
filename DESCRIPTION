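Package: mocsyn
Title: Excitatory-Inhibitory Synaptic Integration in Medial Olivocochlear Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how converging excitatory and inhibitory
    synaptic inputs shape the activity of medial olivocochlear (MOC)
    efferent neurons. Provides a compartmental conductance-based MOC
    neuron model with double-exponential conductance synapses and
    excitation-inhibition latency-sweep protocols; detection, kinetic
    characterisation, gap-statistic/k-means clustering and random-forest
    classification of postsynaptic currents; relative-fluorescence
    (dF/F) quantification of calcium-imaging regions of interest; and
    synthetic-data generators that emulate each recording modality with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
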