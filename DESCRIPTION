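Package: cisnn
Title: Cerebellum-Inspired Spiking Neural Networks for Classification and
    Trajectory Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and supervised training of a cerebellum-inspired
    spiking neural network. Provides adaptive exponential integrate-and-fire
    (AdEx) neuron models parameterised for granule, Golgi and Purkinje cells,
    Gaussian receptive-field encoding of tabular features into mossy-fiber
    drive currents, construction and simulation of the mossy-fiber to granule
    to Purkinje microcircuit with Golgi inhibition, a rate-coded sigmoid
    decoder, error-modulated multiplicative plasticity, population sparseness
    and perceptron storage-capacity analytics, and a dual-error
    trajectory-prediction mode for a virtual six degree-of-freedom arm with a
    geometric forward-kinematics model. Includes seeded synthetic dataset
    generators so all analyses run offline, and a command-line interface for
    end-to-end training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    foreign,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
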