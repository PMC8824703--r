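Package: svsdt
Title: Sine-Vocoded Speech Stimuli, Experiment Designs and
    Signal-Detection Simulation for Degraded-Speech Listening Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing degraded-speech listening
    experiments of the kind used to study expectation effects and
    hallucination-proneness. Implements a cochlear (Greenwood) map
    filterbank with Butterworth band definitions, a sine vocoder with
    spectral inversion and noise-carrier variants, SNR mixing and
    stimulus-condition grids, seedable trial-schedule generators for
    one-shot, cyclic and naive-listening paradigms, equal-variance
    signal-detection measures (d-prime, criterion C, beta) with the
    extreme-rate correction, a latent-trait generative model of listener
    cohorts (discrimination, spontaneous recognition,
    remember/know/new memory responses, questionnaire scores), and the
    statistical pipeline the paradigms call for: paired change tests,
    bivariate/partial/Bayesian correlations, mixed and repeated-measures
    ANOVA with sphericity correction, and logistic regression of
    recognition group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    car,
    withr
Config/testthat/edition: 3
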