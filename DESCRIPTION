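Package: distractnorm
Title: Contextual Normalization of Perceptual Choices by Distracters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for two-alternative
    orientation-discrimination experiments in which a task-irrelevant
    distracter shapes choices about a target grating. Renders noisy Gabor
    stimuli and trial designs for three experiment layouts, simulates
    parametric and energy-template observers (including an accelerated
    stochastic approximation staircase), computes Gabor filter-bank energy
    profiles with a cosine phase model, estimates psychophysical decision
    kernels and their singular value decomposition, fits the logistic
    choice-regression family with consistency interactions and stepwise
    predictor selection, and fits a three-parameter contextual
    normalization transducer compared across variants by cross-validated
    likelihood and random-effects Bayesian model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
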