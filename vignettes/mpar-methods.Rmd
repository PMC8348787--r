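---
title: "Recognising maternal physical activities from wrist-worn sensors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising maternal physical activities from wrist-worn sensors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpar)
```

## The problem

During pregnancy, the intensity and kind of physical activity matter
clinically: some activities are protective, others are discouraged at
particular stages, and keeping a manual diary of what was done and for how
long is impractical. `mpar` implements a complete recognition-and-monitoring
pipeline for this setting: a wrist-worn module samples a 3-axis
accelerometer and 3-axis gyroscope at 50 Hz and a skin-temperature sensor at
1 Hz; the stream is cut into short windows; each window is summarised by a
43-dimension statistical/spectral feature vector; a supervised classifier
assigns one of ten activity classes (`MPA1`–`MPA10`: stairs up/down,
cooking, eating, hands exercise, laundry, laying, walking, front bending,
side bending, standing); and a rule layer raises an alert when a proscribed
activity is sustained too long.

Clinical recordings of this kind are not freely redistributable, so the
package ships a seeded synthetic signal generator that emulates the cohort
design (subjects performing ~6 of the 10 activities in 2–5 minute bouts).
Everything downstream of the generator — segmentation, features, the
evaluation harness, monitoring — is the same code a real deployment would
run on real CSV streams.

## Data model

A recording is one subject-activity bout: a tick table at 50 Hz with columns
`t, acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z, temp`. Accelerometer values
are in g, gyroscope in degrees/second — the file header declares both, since
wearable hardware varies and the arithmetic downstream is unit-agnostic.
Temperature is sampled at 1 Hz and forward-filled onto the 50 Hz grid so one
flat file carries all channels; validation enforces that it is constant
within each second. Timestamps are seconds from bout start: nothing in the
pipeline needs wall-clock time. The sensors quantize at 16 bits; that is
recorded as channel metadata (`channel_specs()`) but samples are stored as
decimals — the feature arithmetic operates on real values and
re-quantization would only discard information.

## Windowing

`segment()` slides a fixed window over the IMU channels: 1 s (N = 50
samples) or 2 s (N = 100), either abutting (stride N) or 50% overlapped
(stride N/2, i.e. 0.5 s or 1 s of shared signal). Trailing samples that do
not fill a complete window are dropped rather than padded: every feature
formula below assumes exactly N samples, and padding would bias the
statistics. Windows never span bout boundaries, because labels are per bout.
The closed form `window_count(T, cfg) = floor((T − N)/stride) + 1` is tested
against an explicit enumeration.

## The 43 features

Each window yields 43 features in a fixed order (see `feature_names()`),
grouped in thirteen families. With \(S_i\) the i-th sample of a channel,
\(N\) the window length, \(\mu\) the window mean and
\(\sigma = \sqrt{\tfrac1N \sum_i (S_i - \mu)^2}\) the population standard
deviation:

| family (count) | definition | channels |
|---|---|---|
| mean (4) | \(\tfrac1N \sum S_i\) | acc x/y/z, temp |
| std (3) | population \(\sigma\) | acc |
| cosine similarity (3) | \(\frac{a \cdot b}{\lVert a\rVert \lVert b\rVert}\) | acc pairs (x,y),(x,z),(y,z) |
| RMS (3) | \(\sqrt{\tfrac1N \sum G_i^2}\) | gyro |
| skewness (3) | \(\tfrac1N \sum \left(\frac{S_i-\mu}{\sigma}\right)^3\) | acc |
| kurtosis (3) | \(\frac{\sum (S_i-\mu)^4}{N\sigma^4}\) | acc |
| max, min (3+3) | extrema | acc |
| zero crossings (3) | strict sign changes of adjacent samples | acc |
| spectral (6) | see below | acc magnitude |
| entropy (3) | \(-\sum p_i \log_2 p_i\), 16-bin histogram | acc |
| first quartile (3) | grouped \(Q_1 = l + \tfrac{h}{f}(\tfrac N4 - C)\), 10 classes | acc |
| peak time difference (3) | \(\lvert t_{\max} - t_{\min}\rvert\) | acc |

Several definitional choices deserve a word, because the conventional forms
in the literature vary:

* **Spectral features.** The six frequency-domain features (`peakf`,
  `lowf1..lowf3`, `medf`, `highf`) are computed from the DFT of the
  *mean-removed acceleration magnitude* \(m_i = \sqrt{a_x^2+a_y^2+a_z^2}\).
  Magnitude is orientation-invariant and yields exactly six features rather
  than eighteen per-axis ones. Mean removal zeroes the DC bin, so a window
  of pure gravity scores 0 across the family. On the one-sided spectrum
  (bins \(k = 1..N/2\), bin k at \(k \cdot f_s / N\) Hz): `peakf` is the
  largest magnitude, `lowf1..lowf3` the first three non-DC bins, and
  `medf`/`highf` the mean magnitude over the (5, 15] Hz and (15, 25] Hz
  bands — three even slices of the 0–25 Hz range at 50 Hz sampling. Both
  bands and a frequency-of-peak variant of `peakf` are configurable through
  `feature_spec()`.
* **Skewness and entropy normalisation.** Skewness uses the standard
  \(1/N\) third-moment normalisation; entropy is plain Shannon entropy (in
  bits, base 2) over a 16-bin equal-width histogram. Both families also
  offer a *literal* mode (`feature_spec(literal_skewness=, literal_entropy=)`)
  — skewness as a bare sum, entropy with an extra \(1/N\) — matching the
  less common summed/scaled conventions so either can be reproduced
  exactly. The defaults were chosen for internal consistency: the summed
  skewness grows with window length, and an entropy scaled by \(1/N\) makes
  the static/dynamic contrast it is meant to capture depend on N.
* **Grouped quartile.** The \(Q_1\) formula presumes binned data; 10
  equal-width classes over the window range are used, a stable choice for
  N ∈ {50, 100}. It is an estimate of the 25th percentile accurate to one
  class width.
* **Degenerate windows** are legal — laying still produces near-constant
  signal. Conventions: \(\sigma = 0 \Rightarrow\) skewness = kurtosis = 0;
  zero-norm vectors ⇒ cosine similarity 0; constant window ⇒ entropy 0 and
  \(Q_1\) = the constant; extremum ties resolve to the first occurrence;
  samples exactly at zero produce no zero crossing (the sign-change
  predicate is strict).

Every family is verified in the test suite against an independent
brute-force evaluation of its formula (elementwise loops, and a naive
O(N²) DFT for the spectral family) on 1000 random windows at 1e-9
tolerance, exactly for the integer-valued features.

## Classifiers and evaluation protocol

`train_and_evaluate()` reproduces a window-level repeated random split
protocol: pool all windows, split 90–10 / 80–20 / 70–30, train, score the
disjoint test set, repeat (default 10 times) and average. Five classifier
configurations are supported, mirroring their original WEKA-style setups:

| kind | configuration | engine |
|---|---|---|
| `knn` | K = 1, Manhattan distance | in-package exact search |
| `j48` | decision tree, max depth 50 | rpart (depth capped at its engine limit of 30) |
| `rf`  | random forest, 100 trees | ranger |
| `ir`  | induction rules, grow/prune ratio 0.95 | in-package grow/prune pruned tree |
| `gbt` | gradient boosted trees, 100 trees, depth 50 | xgboost |

Manhattan 1-NN is implemented in the package because no installed library
offers that metric; the rule inducer follows the classic grow/prune recipe —
grow an unpruned tree on 95% of the training rows, then keep the pruning
level that minimises error on the held-out 5%, each root-to-leaf path acting
as a rule. Splits are stratified by class by default (ten imbalanced classes
make small unstratified test sets noisy); the unstratified variant is one
flag away. All randomness — splits, forest bootstraps, boosting, tie-breaks —
derives from the plan's master seed, so any result reruns bit-identically.

Two caveats documented rather than hidden: window-level pooled splitting
puts windows of the same bout on both sides of the split, so accuracies are
optimistic relative to a leave-subject-out protocol (the harness exposes the
split machinery to build one, but the pooled protocol is the reference
design being reproduced); and `run_grid()` evaluates the full windowing ×
classifier × split product so those comparisons stay honest — each cell
equals the standalone call at the same seed.

## Monitoring

`monitor_stream()` watches the time-ordered prediction stream. An *episode*
is a maximal run of one label; an alert fires the first moment a proscribed
label has been predicted continuously for `sustain_seconds`, and again
within the same continuing episode only after `cooldown_seconds`. A new
episode of the same activity alerts independently — the cooldown throttles
repetition within one episode, it does not suppress detection of a fresh
one. Which activities are proscribed is a clinical judgement that varies by
trimester and patient; the default policy proscribes nothing and the sets,
thresholds and recipients live in configuration. `smooth_predictions()`
(centred majority vote, ties keep the centre label) is available to damp
single-window flicker before the rule sees the stream. Message delivery is a
pluggable sink (`sink_log()`, `sink_file()`), standing in for whatever
transport a deployment uses.

## The synthetic generator

Each activity profile is a sum of (a) a per-axis gravity projection, (b) a
fundamental sinusoid plus a second harmonic per axis, and (c) Gaussian
noise, with per-bout random phase and a few percent of amplitude/frequency
jitter; gyroscope channels are zero-baseline sinusoids plus noise, and
temperature drifts slowly at 1 Hz. This is deliberately the simplest family
that gives the thirteen feature families something to discriminate — the
classes differ in fundamental frequency (0.25–1.9 Hz), amplitude, noise
scale and orientation.

The profiles engineer a confusion structure analogous to what wrist-worn
sensing shows clinically: stair walking (`MPA1`, 1.6 Hz) is deliberately
close to walking (`MPA7`, 1.9 Hz) — a pregnant subject takes stairs slowly
and carefully, so the wrist signal resembles an ordinary walk; side bending
(`MPA9`) and standing (`MPA10`) sit near hands exercise (`MPA4`) in
wrist-motion energy; laying (`MPA6`) is almost static and far from
everything. Separability is tunable: `scale_profile_noise()` multiplies all
noise terms, and inflating them degrades accuracy toward chance.

What the generator does **not** emulate: biomechanics (gait asymmetry,
posture transitions, tremor), sensor artefacts (drift, clipping,
dropped packets), inter-subject variability beyond bout-level jitter, and
any trimester effect on the signal (metadata is carried, not modelled).
Passing the benchmark therefore demonstrates that the pipeline — windowing,
features, harness — is correct and discriminative on signals of realistic
structure; it does not certify clinical accuracy on real patients.

Bout durations default to the emulated design's 2–5 minutes. The default
benchmark cohort is 10 subjects × 6 activities — about 12,600 one-second
windows — which keeps a full generate–segment–extract–evaluate run (three
classifiers, 10 repeats) interactive on a single workstation; the emulated
study's 61 subjects is `cohort_spec(n_subjects = 61)` away. On the default
cohort with 80–20 stratified splits, the tree ensembles sit above 0.99 mean
accuracy, 1-NN slightly below them, and permuting labels collapses accuracy
to the 0.10 chance level of ten balanced classes — the qualitative ordering
(boosted trees ≥ random forest > nearest neighbour) that motivates choosing
a forest for on-device deployment.

## Numerical and engineering choices

* Population (divisor-N) variance everywhere, matching the printed feature
  definitions, not the sample estimator.
* Cosine similarity is clamped to [−1, 1] against floating round-off.
* Histogram binning uses `findInterval` with the rightmost edge closed, so
  the window maximum falls in the last bin.
* Largest-remainder allocation reconciles per-class stratification with an
  exact overall training-set size; every class keeps at least one train and
  one test row.
* Per-repeat and per-fit seeds are derived from the master seed by a fixed
  integer recurrence kept inside 32-bit range.
* The `j48` depth cap of 30 is an rpart engine limit; at these data sizes
  trees never reach it.

## Known limitations

Window-level splits leak bout context (discussed above). The synthetic
benchmark bounds software correctness, not clinical performance. The
monitoring layer assumes a contiguous prediction stream from one subject;
multi-subject streams should be monitored per subject. The grouped-quartile
and entropy features depend mildly on their bin counts; both are exposed in
`feature_spec()` and fixed by default for comparability.
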