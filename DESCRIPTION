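Package: wormcircuit
Title: Connectome-Constrained Simulation and In Silico Dissection of C. elegans Sensorimotor Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates membrane-voltage dynamics of the Caenorhabditis elegans
    nervous system as a network of single-compartment leaky units coupled by
    ohmic gap junctions and graded chemical synapses. Supports per-neuron
    current injection protocols and structural in silico ablation, and turns
    the resulting motor-neuron voltage traces into oscillation readouts
    (amplitude, period, in-phase/anti-phase relations, per-class verdicts)
    used to screen candidate interneurons for membership in sensorimotor
    circuits such as the olfactory-driven reflexive-aversion pathway.
    Includes generators for small four-layer toy connectomes and surrogate
    oscillatory trace sets with known ground truth, and the response/occupancy
    behavioral indices used to report aversion assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pracma,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
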