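# drivestress

Driver stress recognition from multimodal physiological signals.

Real-drive stress protocols bracket a city/highway/city route with two
15-minute rests and treat the rest, highway and city phases as proxies for
low, medium and high stress. `drivestress` implements the complete
analysis chain for such recordings, for researchers working with
physiological time series who need a tested, reproducible pipeline:

* **Signal cleaning** per modality: ECG/HR (59–61 Hz notch, 1.5–150 Hz
  zero-phase FIR band-pass, min–max normalisation), skin conductance
  (4 Hz low-pass, Gaussian smoothing, scale to maximum), EMG
  (0.5–500 Hz band-pass with Nyquist-aware edge clipping, 60 Hz notch),
  respiration (0.05 Hz high-pass, 0.70 Hz low-pass).
* **Segmentation**: sliding windows over channels resampled to a common
  rate, labelled by the majority phase (`rest → relaxed/low`,
  `highway → medium`, `city → high`).
* **Classifiers**: 1D CNNs (Conv1D blocks with causal padding, ReLU and
  layer normalisation, global average pooling, softmax head) and hybrid
  CNN–LSTM variants, trained with Adam under a fixed seed — training is
  bit-reproducible.
* **Metrics**: confusion matrices and per-class one-vs-rest ACC/RCL/PRC/
  F1/SPC, with zero-denominator metrics reported as undefined rather
  than zero.
* **Model ranking**: an eight-step EDAS (Evaluation based on Distance
  from Average Solution) procedure. With decision matrix X
  (alternatives × criteria) and weights y, it computes the column
  averages ψ, the relative shortfall below average
  PI = max(0, ψ − X)/ψ and surplus NI = max(0, X − ψ)/ψ per cell,
  weighted sums SPI = PI·y and SNI = NI·y, normalised sums
  NSPI = SPI/max SPI and NSNI = 1 − SNI/max SNI, and the appraisal score
  λ = (NSPI + NSNI)/2; the lowest λ ranks first (dense ranks, ties
  within 5e-5 shared).
* **Synthetic drives**: a generator producing phase-annotated multichannel
  recordings with stress-dependent structure (offsets, phasic
  skin-conductance events) and removable artefacts (baseline wander,
  60 Hz mains interference, white noise), so the whole pipeline runs and
  tests without any external dataset.

## Worked example: ranking six stress classifiers

The package bundles the published per-class metrics of six convolutional
stress classifiers built on different device subsets (an in-car montage
`SRAD`, a chest strap `BH`, two wrist devices `E4-L`/`E4-R`, and their
fusions) for the two-class task. Ranking the relaxed-state rows:

```r
library(drivestress)
dm <- read_decision_matrix(example_decision_matrix("cnn_two_class_relaxed"))
run_edas(dm)
#> <edas_result>
#>                SPI    SNI   NSPI   NSNI lambda rank
#> SRAD        0.0088 0.0158 0.1663 0.7271 0.4467    3
#> BH          0.0233 0.0071 0.4405 0.8768 0.6586    4
#> E4-L        0.0528 0.0100 1.0000 0.8267 0.9133    6
#> E4-R        0.0316 0.0000 0.5987 1.0000 0.7993    5
#> E4-(L+R)    0.0066 0.0321 0.1249 0.4452 0.2850    2
#> BH+E4-(L+R) 0.0000 0.0579 0.0000 0.0000 0.0000    1
```

`SPI` is each model's weighted shortfall below the per-criterion average
(zero for a model at or above average on every metric) and `SNI` its
weighted surplus above it; the fused chest+wrist model dominates every
criterion, so its appraisal score λ is 0 and it ranks first — the
multimodal-fusion-wins conclusion in one table. Per-class metrics from
confusion counts work the same way:

```r
cm <- as_confusion_matrix(rbind(c(214, 5), c(18, 291)),
                          c("relaxed", "stressed"))
round(metrics_table(cm)[, -1], 4)
#>      acc    rcl    prc    f1    spc
#> 1 0.9564 0.9772 0.9224 0.949 0.9417
#> 2 0.9564 0.9417 0.9831 0.962 0.9772
overall_accuracy(cm)
#> [1] 0.9564394
```

An end-to-end synthetic run — generate a cohort, clean, segment, train a
CNN, evaluate on a held-out drive and rank — is one call:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1, n_drives = 3))
```

A command-line front end with `synth`, `preprocess`, `train`, `evaluate`,
`rank` and `pipeline` subcommands is installed at
`system.file("scripts", "drivestress", package = "drivestress")`.

See the vignette (`vignettes/drivestress-methods.Rmd`) for the models,
their assumptions, all tunable parameters and the generator's contracts.

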