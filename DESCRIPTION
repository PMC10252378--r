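Package: drivestress
Title: Driver Stress Recognition from Multimodal Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising driver stress levels from multichannel
    physiological recordings (ECG, heart rate, skin conductance, EMG,
    respiration and wearable-device channels). Provides per-channel cleaning
    recipes (notch, Butterworth and FIR filtering, Gaussian smoothing,
    min-max normalisation), sliding-window segmentation with phase-derived
    stress labels, compact 1D convolutional and hybrid convolutional-LSTM
    sequence classifiers with causal padding, per-class one-vs-rest
    classification metrics, and an eight-step EDAS (Evaluation based on
    Distance from Average Solution) procedure that ranks competing models
    across several metrics. A synthetic driving-protocol signal generator
    makes the full pipeline reproducible without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
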