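# fetalica

Noninvasive fetal ECG extraction from multichannel maternal abdominal
recordings, built around a deflationary fixed-point ICA (FastICA) with a
cubic negentropy contrast — in its conventional form and with an
**overrelaxation factor** incorporated into the approximated Newton
iteration, which relaxes the algorithm's sensitivity to the random initial
weight vector.

The package is for biomedical-signal researchers who need a complete,
reproducible abdominal-ECG pipeline: baseline-wander removal, whitening and
source separation, maternal R-peak detection, SVD template cancellation of
maternal beats, fetal channel selection, and the standard evaluation
metrics — plus a seeded synthetic abdominal simulator with analytic ground
truth, so every stage is testable without clinical data.

## The method in brief

Abdominal channels are modelled as an instantaneous mixture `X = A S` of
independent sources. After centering and PCA whitening, FastICA finds
unit-norm directions `w` maximizing the non-Gaussianity of `y = wᵀx` via
the fixed-point update derived from the Kuhn–Tucker residual

```
F(w) = E{x g(wᵀx)} − β w,   β = E{wᵀx g(wᵀx)},   g(y) = y³
```

whose approximated Newton step (white data) is
`w ← E{x g(wᵀx)} − E{g'(wᵀx)} w`, renormalized each iteration. The improved
variant multiplies the Newton step by an overrelaxation factor
`α ∈ (1, 2)` chosen by grid search over `1 + k/N` (N = 100): among
candidates that strictly decrease `‖F‖²`, the one minimizing
`‖F(w − αΔw)‖` wins, falling back to `α = 1` when none does. The selected
factor drives a two-stage update (overrelaxed step, then a correction step
re-evaluating `E{g'}` at the intermediate direction).

Downstream, maternal beats found on the maternal ICA component are
cancelled per channel by a robustly fitted rank-2 SVD template over
beat-aligned windows, and fetal R-peaks are detected on the cleanest
residual channel with a fetal-parameterized Pan–Tompkins detector.
`snr_eig` / `snr_rms` (eigenvalue- and cross-correlation-based SNRs of
beat-aligned segments) and `detection_stats` (Sens / PPA / F1) quantify the
result; `amari_index` scores separation against a known mixing.

## Worked example

```r
library(fetalica)

# a 30 s, 4-channel synthetic abdominal record with known ground truth
rec <- synth_abdominal(synth_config(duration_s = 30, seed = 42))
rec
#> Synthetic abdominal record
#> Multichannel recording: 4 channel(s) x 30000 samples @ 1000 Hz (30.0 s)
#> Channels: abd1, abd2, abd3, abd4
#> Maternal: 40 beats (~79 bpm); fetal: 70 beats (~140 bpm)

fit <- extract_fecg(rec$recording, seed = 42)
fit
#> Fetal ECG extraction
#>   separation: improved FastICA, total iterations 16
#>   maternal component: IC1, 40 beats (~79 bpm)
#>   fetal channel: 1, 70 beats (~140 bpm), SNR_Eig 3.67

summary(fit)
#> Fetal ECG extraction (improved FastICA)
#>   total iterations: 16
#>   maternal rate: 79.3 bpm; fetal rate: 139.5 bpm (70 beats)
#>   fetal segment SNR_Eig: 3.670, SNR_RMS: 2.809

# score the detected fetal beats against the simulator's ground truth
counts <- match_beats(fit$fetal_beats, rec$fetal_beats, tol_ms = 50)
counts
#> Beat matching: TP=69 FP=1 FN=1
detection_stats(counts)
#>  Sens   PPA    F1
#> 98.57 98.57 98.57
```

The numbers read as follows: the improved FastICA separated four components
in 16 total iterations; the component beating at ~79 bpm was claimed as
maternal and cancelled from every channel; the residual channel with the
most self-consistent fast rhythm carried 70 fetal beats at ~140 bpm, of
which 69 match the ground-truth fetal R-peaks within ±50 ms (sensitivity
and positive predictive accuracy 98.6%). The segment SNRs (3.67 eigenvalue
/ 2.81 cross-correlation) summarize how mutually consistent the extracted
fetal beats are.

`plot(fit)` draws the extracted fetal trace with detected beats;
`run_benchmark(rec, n_repeats = 10)` tabulates iteration counts, SNRs and
detection statistics per method over repeated random initializations.

## Command line

A thin CLI over the same functions lives in `inst/cli/fetalica.R`
(installed under `system.file("cli", "fetalica.R", package = "fetalica")`):

```sh
Rscript inst/cli/fetalica.R simulate  --seed 3 --out rec.csv --truth truth.json
Rscript inst/cli/fetalica.R extract   --input rec.csv --out-dir out/
Rscript inst/cli/fetalica.R evaluate  --fetal out/fetal_beats.csv --reference ref.csv --tol-ms 50
Rscript inst/cli/fetalica.R benchmark --input rec.csv --repeats 10
```

`read_recording()` accepts CSV (header of channel labels, optional `time_s`
first column), continuous EDF, and WFDB `.hea`/format-16 `.dat` records;
for abdominal databases with a direct fetal scalp lead, channels labelled
`direct`/`scalp` are split off as a reference attribute. To benchmark on a
clinical record (e.g. a PhysioNet abdominal/direct fetal ECG record
downloaded locally), point `benchmark --input` at the `.hea` file.

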