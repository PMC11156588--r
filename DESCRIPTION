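Package: groomloop
Title: Closed-Loop Detection of Grooming Onset from Orbitofrontal LFP
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Real-time detection of compulsive grooming onsets from
    low-frequency orbitofrontal local field potentials (LFP), and simulation
    of closed-loop optogenetic intervention. Implements the full pipeline:
    a synthetic multi-electrode LFP and behavior generator with a 1-4 Hz
    pre-onset power ramp; offline spectral biomarker characterization
    (Butterworth preprocessing, Hann periodogram, generalized Morse wavelet
    spectrograms, band-power ramp rising-point detection); an online feature
    reduction stage (triangular filterbank warped around a principal
    frequency, log energies, decorrelating cosine transform, M x P feature
    matrices); per-electrode two-hidden-layer feedforward classifiers with a
    strict-majority electrode voting trigger; a streaming closed-loop engine
    with 200-ms decision cadence, 4-s stimulation lockout and
    OFF/closed-loop/randomized trial schedules; and an event-anchored
    evaluation layer (early-detection periods, bin-level confusion counts,
    pseudorandom baseline, behavioral endpoint formulas).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    arrow
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classifier.R'
    'closedloop.R'
    'evaluation.R'
    'features.R'
    'signal-io.R'
    'spectral.R'
    'synthetic.R'
    'utils.R'
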