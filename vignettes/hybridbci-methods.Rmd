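---
title: "Methods: models, parameters and the leakage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and the leakage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`hybridbci`: what each stage assumes, which parameters matter and why their
defaults were chosen, what the synthetic generator does and does not emulate,
and the analysis of why the package's central transformation — cluster-center
attribute weighting applied before the cross-validation split — inflates
accuracy through label leakage.

## 1. The synthetic recording model

The generator (`sim_config()`, `generate_dataset()`,
`simulate_feature_tables()`) emulates the *geometry* of a 29-subject hybrid
motor-imagery / mental-arithmetic protocol: 3 sessions per subject, 20 trials
per session (29 × 3 × 20 = 1740 observations), 36 fNIRS source–detector
pairs sampled at 12.5 Hz, 32 EEG channels at 1000 Hz, a 2-s instruction
period, a 10-s task, and 15–17 s of rest drawn uniformly per trial, after an
initial 60-s rest.  One deliberate deviation from the published montage: the
EEG channel count is fixed at 32 rather than the 30 electrodes of the
documented cap, because the downstream feature arithmetic of the reference
analysis (32 × 7 = 224 EEG features) assumes 32; the feature-count contracts
depend on it.

Class structure enters through two mechanisms, each confined to a designated
channel subset so that informative and uninformative channels coexist:

* **Hemodynamics.** Every trial adds a double-gamma response (peak at 6 s,
  small undershoot at 16 s, 20 s support) to each channel's HbO ground
  truth, with per-trial, per-channel amplitudes drawn uniformly in ±20%
  around `hbo_peak` = 0.005 mM — a typical single-trial cortical ΔHbO
  excursion for a 3-cm channel.  HbR is a scaled mirror,
  `hbr_ratio` = −0.35, reflecting the usual smaller, negative deoxy
  response.  On the first third of channels ("active"), class-2 amplitudes
  are multiplied by `hemo_effect_size` (default 1.5, a moderate
  contralateral-activation contrast).  Ground truth is converted to
  two-wavelength optical density with the forward Beer–Lambert map and
  stored alongside, enabling exact inversion round-trip tests.
* **EEG oscillation.** A 10-Hz (alpha/mu) oscillation with random phase and
  a 0.5-s Hann on/off ramp is present during each task window; on the first
  quarter of channels its amplitude (base `alpha_amp` = 4 µV) is multiplied
  by `erd_effect_size` for class 2 (default 0.5, i.e. a 50% event-related
  desynchronization — strong but within the range reported for motor
  imagery).

Setting either dial to 1 makes the classes statistically identical in that
modality, which the tests use as the chance-level control.

**Noise.** Both modalities carry 1/f ("pink") noise plus white Gaussian
noise: 0.02 + 0.005 OD units for fNIRS and 10 + 2 µV for EEG, all scaled by
the single `noise_sd` dial (0 = noise-free).  The model deliberately omits
cardiac pulsation, Mayer waves, respiration, ocular and motion artifacts,
electrode drift and inter-subject variability in HRF shape.  Consequently,
passing tests demonstrate that the *pipeline machinery* is correct and that
its statistical behavior (chance level without effect, monotone response to
effect size, leakage under faithful weighting) is as claimed — they say
nothing about classification performance on real recordings, where artifact
structure dominates.

**Determinism.** Every recording is a pure function of the configuration:
per-(subject, session) seeds are derived arithmetically from `cfg$seed`, and
the trial layout stream is separated from the per-modality noise streams, so
the EEG and fNIRS arms can be generated independently and still align trial
for trial.  All seed-taking functions restore the caller's RNG state.

## 2. Beer–Lambert conversion

`mbll_inverse()` applies the 2 × 2 linear inverse samplewise.  The default
parameters (λ = 760/850 nm; ε in mM⁻¹cm⁻¹ of 0.5958/1.6745 at 760 nm and
1.0507/0.7861 at 850 nm for HbO/HbR; DPF = 6 at both wavelengths; ρ = 3 cm)
are ordinary continuous-wave fNIRS values from standard extinction
tabulations.  They are configuration, not measurements: every test is a
forward/inverse round-trip property (identity to ≤ 1e−12 relative error),
never an assertion about absolute concentrations.  The constructor rejects
near-singular ε·DPF systems outright.

## 3. Filtering and resampling

**Band-pass.** Hemoglobin series are filtered 0.01–0.09 Hz with a 3rd-order
Butterworth.  Filtering is zero-phase (forward–backward) by default because
epoch timing relative to stimulus onset must not be phase-shifted; this
doubles the effective magnitude order, and a causal single pass is available
(`zero_phase = FALSE`).  Two numerical choices matter at this band, whose
lower edge sits at 0.0016 of Nyquist when designed at 12.5 Hz:

* The filter is realized as *cascaded biquads designed analytically*
  (analog Butterworth prototype poles → low-pass-to-band-pass transform →
  bilinear map, gain fixed to 1 at the band center).  Expanding the
  transfer function into a single direct form at this normalized band loses
  about six significant digits (measured linearity error ~3.6e−6 against
  ~1e−12 for the cascade), and factoring the expanded polynomial back into
  sections is equally ill-conditioned because the roots cluster near z = 1.
* Edges are handled with odd-symmetric padding of three filter orders plus
  *DC-matched initial conditions* (each section starts from the steady
  state of a constant input equal to its first sample).  Initial-condition
  matching is what makes a constant input map to numerically zero
  everywhere; with zero initial conditions the step transient of this
  narrow band decays over hundreds of samples, far beyond any reasonable
  padding.

**Resampling** (12.5 → 10 Hz fNIRS, ratio 4/5; 1000 → 200 Hz EEG, ratio 1/5)
is a polyphase FIR implementation written for this package: upsample by `p`,
apply a Hamming-windowed sinc of length `2·10·max(p, q) + 1`, decimate by
`q`, with two corrections — every polyphase branch is renormalized to unit
sum (so constants are preserved exactly rather than to the window's ~1e−3
ripple), and the odd filter delay is compensated so output sample `m` sits
exactly at time `(m − 1)/fs_out`.  The bundled `signal::resample` was
measured to leave its group delay uncompensated (≈0.14 amplitude error on an
in-band sinusoid) and was therefore not used.  Marker onsets are rescaled as
`round(t_onset · fs_out) + 1`.

**Order of operations.** The fNIRS chain is MBLL → band-pass (at the native
12.5 Hz) → downsample.  Filtering at the native rate keeps the design away
from any interaction with the new Nyquist; the stages are exported
separately, so any other order can be composed.

## 4. Epoching and baseline correction

Trials are cut with half-open sample windows
`[round(onset + a·fs), round(onset + b·fs))`, which makes a 10-s window at
10 Hz exactly 100 samples and at 200 Hz exactly 2000 — the boundary
convention is chosen so the per-rate sample counts come out exact.
`segment()` retains the −2–0 s instruction context; `baseline_correct()`
subtracts the per-trial, per-channel mean over that window and then trims to
the task window.  A second correction on trimmed epochs is a contract
violation and raises an error (the baseline context is gone).  Markers whose
context window would leave the recording are reported by index.  No trial
rejection is performed.

## 5. Features

Seven statistics per channel per trial: mean, maximum, least-squares slope
(amplitude/s over the whole epoch), variance with the N−1 denominator,
skewness and kurtosis as third and fourth standardized moments with the
*population* standard deviation in the denominator (kurtosis non-excess: a
Gaussian gives 3), and the median (mean of the two middle order statistics
for even N).  Two conventions worth noting:

* *Slope.*  "Average slope in a time window" admits several readings; the
  default is the single regression slope over the full 10-s epoch, and a
  windowed variant (mean of per-window regression slopes,
  `slope_window` seconds each) is available.  For a pure linear trend the
  two agree.
* *Constant epochs.*  The standardized moments are undefined at zero
  variance; they are returned as 0 with a warning rather than an error, so
  a degenerate all-zero channel does not abort a 1740-trial run.

Tables are laid out channel-major (all seven features of channel 1, then
channel 2, …), giving 252 fNIRS and 224 EEG feature columns at the
reference montage; serialized CSVs append a final `label` column (253 / 225
total).  `combine_tables()` refuses mismatched label vectors — a mismatch
means trial ordering diverged upstream, which must fail loudly rather than
silently misalign modalities.

## 6. Cluster-center attribute weighting

The weighting core is Lloyd's k = 2 algorithm (`kmeans2()`): centers
initialized from two distinct sampled points, equidistant assignment ties to
cluster 1, empty clusters reseeded with the point farthest from the other
center, 10 restarts by default with the best within-cluster sum of squares
kept.  On small instances the restarts recover the global optimum, which the
tests verify against an exhaustive minimum-SSE bipartition oracle.

The weighting schemes need a *single* center per class while 2-means returns
two; `class_center()` resolves this as the componentwise mean of the two
within-class centers — the reading that keeps the step order (split by
class → cluster → one `z_i` per class) coherent.  For symmetric within-class
structure it coincides with the class mean.  The choice is isolated in one
function so alternatives (e.g. the center nearer the class mean) can be
swapped in; a `per_feature` flag clusters each feature independently in 1-D
instead of once on the full class matrix.  Near-zero centers
(|z| ≤ 1e−12) would make the ratio weights explode; they receive the
method's identity value (1 for KMCC, 0 for KMCCD) with a warning, preserving
each method's semantics.  Both maps are scale-equivariant — rescaling a
feature rescales `μ` and `z` alike — so the weights are unit-free.

### The leakage analysis

The pseudo-code's final step multiplies each observation's features by the
weight vector *of that observation's own class* — including observations
that will later be held out.  `apply_weights(mode = "faithful")` reproduces
exactly this.  The consequence: rows of class 1 and class 2 are transformed
by two *different* linear maps, so the transformation itself encodes the
label.  On features with no class information at all (i.i.d. Gaussian
noise, 400 × 20), 1-NN after faithful KMCCD weighting exceeds 90% mean
10-fold CV accuracy over 10 seeds, while `mode = "global"` — the label-free
averaged weight vector, fitted on training folds only — stays at 50 ± 10%.
The package runs this demonstration in its test suite and acceptance
script.  Faithful mode is retained as the default for *replication* of the
original protocol, with the leak documented here and in the function
documentation; any claim about real discriminative power must use the
global mode (or any other transformation fitted strictly within training
folds).

## 7. Classification and metrics

* **LDA** is a two-class pooled-covariance discriminant using a
  pseudo-inverse, because weighted high-dimensional tables are routinely
  rank-deficient (e.g. 504 features from 240 trials) where a plain solve or
  `MASS::lda` fails; on well-conditioned data it agrees with `MASS::lda`
  (verified in the tests).  Priors come from training proportions.
* **SVM** is `e1071::svm` with a linear kernel and C = 1, no internal
  rescaling (the weighting is the transformation under study; silently
  standardizing features would partially undo it).  Kernel and cost are
  configurable.
* **1-NN** is computed from exact Euclidean distances with ties broken by
  the lower training-row index — a determinism requirement that off-the-shelf
  implementations with randomized tie-breaking do not meet.

Stratified 10-fold CV deals each class's shuffled members round-robin with
the starting fold rotated between classes, keeping global fold sizes within
⌊n/k⌋–⌈n/k⌉ (1740 observations → ten folds of exactly 174, 87 per class).
Each fold's held-out predictions are pooled into a single confusion matrix
per cell; per-fold accuracies are retained in the report but the headline
metrics are pooled, matching the single-value-per-cell reporting convention
of the protocol being replicated.  Metrics use the standard forms — accuracy
(TP+TN)/total, FPR = FP/(FP+TN), p₂ = (TP+FP)/total in the kappa chance
term — with the occasionally printed variants (accuracy numerator TP+FP,
FPR denominator TP+TN) available behind `printed_formulas = TRUE` for
compatibility; only the standard forms satisfy the identities the tests
assert (ACC/100 + error = 1, κ = 1 exactly for a perfect classifier).  The
error CI is `z·√(error(1−error)/n)` with z = 1.96 at 95% and `n` the number
of observations used to develop the model (1740 at full protocol scale).
Zero-denominator metrics are reported as `NA`, never as 0.

## 8. Problem sizes

Full-scale synthesis of the EEG arm (87 sessions × 32 channels × ~600 s at
1000 Hz) is dominated by raw sample generation and decimation, so the
package chooses its evaluation sizes by arm: the fNIRS arm runs at the full
default geometry (all 29 subjects, true 1740-row tables) in the acceptance
script, while the EEG/hybrid arm and the 54-cell classification grid run on
a 4-subject subset (240 observations) — enough for every structural count
to be computed from real objects and for the weighting phenomenology to be
unambiguous.  The test suite uses smaller geometries still (2 subjects × 1
session × 20 trials, 4-channel montages) with the EEG rate set to its
post-downsampling value, plus the pure-noise benchmark (n = 400,
d = 20, 10 seeds) for the leakage demonstration and 10-seed averages for
the chance-level and effect-size-monotonicity properties.

## 9. Known limitations

* The generator's class mechanisms (HRF amplitude scaling, alpha
  attenuation) are linear and channel-stationary; real ERD is
  time-frequency structured and subject-specific.
* No artifact model, no short-separation channels, no motion correction —
  the preprocessing module is deliberately minimal (band-pass + resample).
* The LDA uses a pseudo-inverse rather than shrinkage regularization; for
  p ≫ n problems a shrinkage discriminant would be preferable.
* Binary classes only; k > 2 weighting is out of scope.
* Faithful-mode results must never be read as generalization estimates; see
  Section 6.
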