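---
title: "Recognising driver stress from multimodal physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising driver stress from multimodal physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivestress)
```

## The problem

Acute mental stress degrades driving performance, and sympathetic arousal
leaves measurable traces in physiological signals: heart rate rises, skin
conductance climbs and fires phasic responses, trapezius muscle tone
increases, breathing changes. Real-drive protocols exploit this by
bracketing a fixed city/highway/city route with two 15-minute parking-lot
rests; the rest, highway and city phases are treated as proxies for low,
medium and high stress (or, collapsed to two levels, relaxed versus
stressed). `drivestress` implements the full analysis chain for such
recordings: per-modality signal cleaning, sliding-window segmentation with
phase-derived labels, compact 1D convolutional and hybrid
convolutional-LSTM classifiers, one-vs-rest classification metrics, and a
distance-from-average multi-criteria procedure that ranks competing models
across five metrics at once. A synthetic drive generator makes every stage
reproducible without access to any instrumented-vehicle dataset.

## Signal cleaning

Each modality has its own cleaning recipe, applied by `clean_channel()`:

* **ECG / heart rate** — a 59–61 Hz notch (order-2 Butterworth band-stop)
  removes mains interference, a 1.5–150 Hz FIR band-pass removes baseline
  wander and high-frequency muscle noise while preserving ECG morphology,
  and min–max normalisation maps the result to [0, 1]. The classic
  5–15 Hz QRS-emphasis band is available separately as `ecg_qrs_band()`;
  it is a beat-detection band, not a cleaning band, so it is not part of
  the default chain.
* **Skin conductance (GSR/EDA)** — 4 Hz Butterworth low-pass, Gaussian
  smoothing (σ = 0.5 s by default), then scaling to the maximum value, so
  a constant level maps to 1.
* **EMG** — 0.5–500 Hz Butterworth band-pass, 60 Hz notch, min–max. At
  realistic EMG sampling rates the 500 Hz edge exceeds what the rate can
  represent; any edge above `0.45 * fs` is clipped to `0.45 * fs` with a
  warning. A stage whose entire band falls away this way (for instance a
  60 Hz notch on a 15.5 Hz heart-rate stream) raises an error naming the
  stage; `clean_recording()` degrades such channels to plain min–max
  normalisation instead.
* **Respiration** — 0.05 Hz high-pass then 0.70 Hz low-pass, isolating
  the breathing band.

All filters are applied forward–backward (zero phase) by default, with
odd-reflection padding to suppress start/end transients. Filter orders
default to Butterworth 4 and notch 2 and are configurable. One numerical
choice deserves a note: a Hamming-window FIR needs roughly `3.3 * fs / f`
taps before its transition band is narrow enough to act at frequency `f`,
so a fixed 101-tap design cannot realise a 1.5 Hz edge at ECG rates
(496 Hz) — it would pass baseline wander untouched. `clean_channel()`
therefore grows the FIR length with the sampling rate
(`max(101, ~3.3 * fs / 1.5)` taps); `apply_filter()` itself always honours
exactly the order it is given.

Min–max normalisation maps a zero-range (constant) input to all zeros
rather than dividing by zero.

## Segmentation and labelling

`segment_record()` linearly resamples all channels to a single common rate
(default 8 Hz — fast enough for the tonic stress structure the classifiers
exploit, slow enough that a window is a small matrix), stacks them, and
cuts sliding windows of `window_s` seconds (default 10) with fractional
`overlap` (default 0.5). The window count obeys
`floor((N - W) / S) + 1` for `N` samples, window `W` and stride `S`.
Windows take the stress label of the phase covering the majority of their
samples; windows straddling a boundary go to the majority side, ties to
the lower stress level, and windows outside the annotation are dropped.
The two-level scheme maps rest to `relaxed` and both driving phases to
`stressed`; the three-level scheme maps rest/highway/city to
`low`/`medium`/`high`. Window length and overlap are not dictated by the
protocol, so both are plain arguments; the defaults were chosen once as
typical values for slow autonomic signals and are not tuned anywhere.

## Classifiers

`build_cnn()` declares the convolutional architecture for a device
profile: Conv1D blocks (kernel 3, causal padding, each followed by ReLU
and layer normalisation), an optional trailing conv, global average
pooling, a fully connected layer of width `n_classes`, softmax, and a
cross-entropy head. The wearable profiles (`srad`, `e4l`, `e4r`, `e4lr`,
`bh_e4lr`) use four blocks of 8/32/64/128 filters plus a trailing
8-filter conv; the chest-strap profile (`bh`) uses three blocks of
128/64/32 filters. Causal padding keeps every conv output the same length
as its input and uses only past samples. `build_cnn_lstm()` keeps the same
convolutional front end and replaces pooling with an LSTM (hidden size 250
for `srad`, 300 for `e4l`, 200 otherwise) whose final hidden state passes
through dropout (0.4 for `srad`, 0.5 otherwise) into the same
classification head.

Fusion profiles use *early fusion*: the channels of the constituent
devices are resampled to the common rate and stacked as input channels of
a single stack (the deeper of the constituents). A parallel-branch
architecture would be the main alternative; early fusion was chosen
because it is the simplest design consistent with "summing the layers" of
the constituent networks, and because it lets one `segment_record()` call
serve every profile.

Training (`train()`) performs a stratified split (default 0.8 training
fraction; 0.85 appears in some published summaries of this design — the
split is a plain argument), initialises weights Glorot-uniform from the
seed, and minimises cross-entropy with Adam (learning rate 0.001 — the
standard Adam default, as no rate is dictated by the design — β₁ = 0.9,
β₂ = 0.999). Validation loss and accuracy are recorded every
`validation_frequency = 10` iterations. Epoch/mini-batch defaults come
from the profile (20/30 for `srad`, 30/20 otherwise). Everything is
deterministic given the seed; rerunning reproduces the history bitwise.

Two open representational choices are worth recording. Layer
normalisation here normalises over channel features at each time step
(per-row), the interpretation that matches per-time-step feature scaling;
normalising over time would be the alternative. The fully connected layer
has width `n_classes` exactly — no additional hidden width — because the
classification head is described as FC → softmax → classification with no
intermediate size given.

The whole engine is plain R matrix code (the batch is packed as one
`(B·T) × C` matrix so causal convolution becomes K shifted BLAS products).
At the window sizes this package targets (tens of samples, a few channels,
a few hundred windows) that is entirely adequate, and it keeps the
training loop dependency-free and bit-reproducible.

## Metrics

`class_metrics()` computes one-vs-rest accuracy, recall, precision,
F-score and specificity per class; "accuracy" here is the one-vs-rest
accuracy `(TP + TN) / N`, which for two classes is identical for both
classes. Ratios with zero denominators are reported as `NA` rather than
silently as 0, because a silent zero would corrupt a downstream decision
matrix; `decision_matrix_from_metrics()` refuses rows containing `NA` for
the same reason. Micro-averaged recall equals overall accuracy
(`overall_accuracy()`), and for two classes each class's recall is the
other's specificity — both identities are enforced in the test suite.

## Ranking competing models

`run_edas()` implements an eight-step EDAS (Evaluation based on Distance
from Average Solution) procedure over an alternatives × criteria decision
matrix with positive weights (despite the "fuzzy EDAS" name this family
of analyses sometimes carries, the procedure is crisp — there is no
fuzzification step):

1. ψ: per-criterion column means;
2. PI: for a beneficial criterion, the relative shortfall below the
   average, `max(0, ψ − x) / ψ`;
3. NI: the relative surplus above the average, `max(0, x − ψ) / ψ`
   (a non-beneficial criterion swaps the two);
4–5. SPI/SNI: weighted row sums of PI and NI;
6. NSPI = SPI / max SPI and NSNI = 1 − SNI / max SNI, with a zero maximum
   making the ratio 0 (so an all-zero SNI column yields NSNI = 1
   everywhere);
7. λ = (NSPI + NSNI) / 2 ∈ [0, 1];
8. dense ranks ascending in λ — the *lowest* appraisal score wins, and
   scores within `5e-5` (half a fourth-decimal rounding step) share a
   rank.

Note the orientation: this variant penalises shortfall below the average
(PI) rather than rewarding surplus, which is the mirror image of the more
common EDAS formulation; combined with lowest-λ-wins ranking the final
order is the conventional one. The orientation and the λ formula were
fixed against the fully worked step-by-step tables this procedure is
validated on (the published λ formula is degenerate as printed — its two
terms are identical — and the mean of the two normalised sums is the
unique correction consistent with the worked rows). The default criterion
weights `(0.4176, 0.2850, 0.1453, 0.0844, 0.0676)` for
(ACC, RCL, PRC, F1, SPC) are used exactly as published (sum 0.9999); a
`renormalize` flag rescales them to 1 if desired. Their derivation is not
documented in the source analysis; they are treated as given constants.

The procedure is scale-invariant per criterion (multiplying a column by
c > 0 changes nothing), PI·NI = 0 holds cell-wise, λ is bounded in
[0, 1], and a weakly dominating alternative has SPI = 0 and rank 1 — all
asserted as properties in the test suite. The worked-example golden tests
assert only table cells that are internally consistent with the stated
formulas; a handful of published cells (one accuracy NI cell, one
precision NI cell and one F-score PI cell, plus two aggregate rows) are
transcription-inconsistent with their own weighted aggregates and are
checked at the formula-faithful values instead.

## The synthetic drive generator

No generative model of in-car physiology accompanies the analysis chain
(real instrumented-vehicle recordings were the original substrate), so
`generate_drive()` synthesises stand-ins with three explicit contracts:
realistic sampling rates per device (ECG at 496 Hz, skin conductance at
31 or 4 Hz, chest-strap scalars at 1 Hz); the classic noise taxonomy the
cleaning recipes target (white noise, slow baseline wander, 60 Hz mains
interference) so the filters have something real to remove; and
controllable class separation. Each channel is baseline + per-stress-level
offset + oscillation + event transients + noise. Stress-sensitive channels
default to a five-sigma separation between adjacent stress levels
(e.g. heart rate: +10 bpm per level at σ = 2 bpm), phasic
skin-conductance events fire at 0.01/0.05/0.1 events per second at
low/medium/high stress, and the ECG stand-in is a periodic pulse train at
the stress-dependent heart rate with no morphological realism claimed.
`default_channel_models()` exposes `noise_scale` (an SNR dial) and
`sep_scale` (an effect-size dial).

The default protocol is rest–city–highway–city–rest with 900 s rests and
600/900/600 s driving segments; `scale = 0.1` (the desk scale used
throughout the tests) shrinks a drive to 390 s so a full cohort generates
in well under a second. Cohorts derive per-drive seeds deterministically
from a master seed and add mild per-drive baseline jitter. Samples are
stored rounded to 1e-6 so recordings are platform-independent.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline is correct end to end — cleaning removes exactly the
injected artefacts, labels follow the protocol, a five-sigma-separated
cohort is learned to high validation accuracy, and ranking tracks
configured signal quality. They do not demonstrate performance on real
driving data, whose class structure is far less separable and whose
artefacts (motion, electrode drift, traffic variability) are richer than
this model.

## Problem sizes and numerical choices

The test suite and the reproduction script run entirely at desk scale:
cohorts of two to five drives at protocol scale 0.1, a three-channel
montage (heart rate, skin conductance, respiration) where a full montage
would only add runtime, common rate 8 Hz, 10 s windows at 50 % overlap
(roughly 70 windows per drive), and profile-default training options.
These sizes were fixed once when the tests were written, as the smallest
configurations that exercise every code path with comfortable statistical
margins.

Other numerical conventions: layer-norm ε is 1e-5; the LSTM forget-gate
bias starts at 1 (standard practice, keeps early gradients flowing);
softmax is computed with per-row max subtraction; predicted-class ties
break to the first class; the dense-ranking tie tolerance is 5e-5;
`minmax_normalize()` of a constant returns zeros; and an empty segment set
predicts an empty label vector.

## Known limitations

* The classifiers are small-scale by design; there is no GPU path, no
  hyperparameter search and no pretrained weights.
* The generator's channels are statistical stand-ins, not physiologically
  validated waveforms; heart-rate variability, skin-conductance recovery
  shapes and motion artefacts are all simplified.
* Published headline accuracies from real instrumented-vehicle datasets
  are not reproduction targets here: those datasets are external, and
  stochastic training on them is outside this package's scope. The
  package reproduces the *procedures* — the metric arithmetic and the
  complete ranking chain — exactly.
* Heart-rate derivation from ECG, inter-beat-interval processing and
  artifact rejection beyond the stated filters are out of scope.
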