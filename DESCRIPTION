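Package: neuroassembly
Title: Simulation and Mean-Field Analysis of Binary Threshold Neural Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating synchronous binary threshold neural
    assemblies whose synapses are unitized to -1, 0 or 1, and for the
    statistical laws such assemblies obey: attractor (cycle) detection,
    the logistic relation between a neuron's mean input accumulation and
    its spike probability, the nonlinear fixed-point system whose solution
    the spike probabilities meet, Shannon/Boltzmann entropy and its
    polarization under stimulation, a binomial/normal theory of activity
    stability as a function of the excitatory fraction, reduction of
    weighted, thresholded, delayed networks to an equivalent unit matrix,
    and a phase-coupling short-term-memory framework built from coupled
    assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
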