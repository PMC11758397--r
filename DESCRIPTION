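Package: l6ephys
Title: Quantification of Layer 6 Corticothalamic and Corticocortical Neuron
    Physiology and Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the electrophysiology and morphology of
    excitatory neurons in neocortical layer 6, where FOXP2-expressing
    corticothalamic pyramidal cells and FOXP2-negative corticocortical
    neurons form two sharply distinct populations. The package extracts
    passive, single action-potential and repetitive-firing features from
    current-clamp step protocols; measures unitary EPSP amplitudes and
    paired-pulse ratios from paired recordings; quantifies neuromodulator
    (acetylcholine, dopamine) induced membrane-potential changes; computes
    morphometric parameters and voxelized axonal/dendritic length-density
    maps from SWC reconstructions; and provides exact rank-based two-sample
    statistics. A fully ground-truthed synthetic-data generator (adaptive
    exponential integrate-and-fire spiking, Tsodyks-Markram short-term
    plasticity, drug-application traces, morphology archetypes) supports
    end-to-end validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
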