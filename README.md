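# bowelsound

Detection of bowel-sound activity in abdominal auscultation audio and
prediction of imminent defecation from it.

Bowel sounds — brief acoustic transients of intestinal peristalsis — are the
standard non-invasive indicator of gut motility. For patients with fecal
incontinence, peristaltic activity rises in the minutes before defecation,
so a classifier over bowel-sound features of an auscultation recording
(mono, nominally 60 s at 4000 Hz) can provide an early warning without any
invasive sensor. This package implements that full signal chain, plus a
seeded synthetic generator with ground-truth burst annotations so every
stage is testable without clinical recordings (no public labelled corpus
exists).

## The method

A recording `x` is modelled additively as bursts plus background,
`x = BS + BGS`.

1. **Iterative kurtosis detector** (`run_mikd`). In non-overlapping 0.05 s
   windows (1200 per nominal record) the excess kurtosis
   `K_j = sum((x - m)^4) / ((M - 1) s^4) - 3` is near zero for the
   near-Gaussian background (< 100 Hz) and positive for windows containing
   a transient burst (200–1000 Hz). Windows are flagged against an adaptive
   threshold — twice the upper edge of the histogram bin where the
   cumulative count of `K` passes 90% — moved verbatim to the burst
   channel, and the procedure iterates on the remainder. `bs + bgs`
   reconstructs the input exactly.
2. **Kalman denoising** (`denoise_record`). The burst channel is smoothed
   by a constant-acceleration filter with state `(p, v, a)`, transition
   `A = [[1, h, h²/2], [0, 1, h], [0, 0, 1]]`, observation `H = [1, 0, 0]`,
   `h = 1/fs`.
3. **Features** (`build_feature_vector`). TF1–TF8 time-domain statistics
   (mean, population variance, extremes, square-root amplitude, absolute
   mean, raw third/fourth moments), TF9–TF11 frequency-domain statistics
   (DC, mean in-band DFT magnitude, total spectral power = `sum(x^2)` by
   Parseval), and the subband energies of a depth-6 Haar decomposition
   (pairwise averaging/differencing with 1/2 scaling) — 18 numbers per
   record.
4. **BP classifier** (`bp_fit`). A from-scratch one-hidden-layer
   backpropagation network (200 logistic units, single logistic output,
   squared-error loss, mini-batches of 10, learning rate 0.01, momentum
   0.9, up to 50,000 updates, convergence when the epoch loss moves by
   < 0.01), with z-scoring by training-set statistics.
5. **Protocol** (`run_rounds`, `run_pipeline`). 20 rounds of stratified
   7:3 train/test splits; per-round held-out accuracy, pooled confusion
   matrix, accuracy/sensitivity/specificity.

See `vignettes/bowelsound-methods.Rmd` for assumptions, parameter
rationale and limitations.

## Worked example

```r
library(bowelsound)

params <- synth_params(duration = 10)          # 10 s records, default classes
rec <- make_record(params, label = 1, seed = 42)
rec
#> Labelled synthetic record: 40000 samples @ 4000 Hz, class 1, 15 burst event(s)

det <- run_mikd(rec)
det
#> mIKD result: 7 iteration(s), 29/200 window(s) flagged as bowel sound
detection_performance(det, rec$events)[c("recall", "false_flag_rate")]
#> window recall 1.00, background false-flag rate 0.034

round(extract_features(rec)[c("tf2", "tf8", "tf11", "wA6")], 6)
#>      tf2      tf8     tf11      wA6
#> 0.000426 0.000002 17.041403 0.000259

cfg <- default_config(); cfg$n_rounds <- 5L
report <- run_pipeline(params = params, n_records = 40, config = cfg, seed = 1)
report
#> Evaluation over 5 round(s): mean accuracy 0.9167 (min 0.8333, max 1.0000)
#>   pooled: accuracy 0.9167, sensitivity 0.8667, specificity 0.9667
```

Every one of the 15 injected bursts was recovered at the window level
(recall 1.00) while 3.4% of pure-background windows were flagged; the
5-round evaluation on 40 synthetic records separates the classes at 92%
held-out accuracy. `tf11` is the record's total energy; `tf8`, the raw
fourth moment, is the feature most sensitive to burst activity.

A command-line front end wrapping the same functions is installed at
`system.file("cli", "bowelsound", package = "bowelsound")` with
`detect`, `denoise`, `featurize` and `run-all` subcommands.

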