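---
title: "Methods: epoch-based sleep-stage scoring for mouse EEG/EMG"
author: "sleepscoreR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epoch-based sleep-stage scoring for mouse EEG/EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scoring problem

Rodent sleep is scored in three vigilance states — Wake, NREM and REM —
from skull-surface EEG and nuchal EMG. The discriminative physiology is
well established: NREM shows high-amplitude, delta-dominant (1–4 Hz) EEG;
REM shows theta-dominant (4–8 Hz) EEG with muscle atonia (minimal EMG);
Wake shows low-amplitude mixed-frequency EEG with high, variable EMG tone.
Mouse sleep is fragmented — NREM and REM come in episodes of seconds to
minutes interspersed with waking — so scoring is done on fixed 10-s epochs,
each receiving one label, coded `1` Wake, `2` NREM, `3` REM in all label
files this package reads and writes.

`sleepscoreR` scores each epoch independently from a fixed feature vector;
no neighbouring-epoch context and no temporal smoothing are used. This
keeps the classifier honest about per-epoch evidence and makes predictions
invariant to epoch order, at the cost of ignoring stage-transition priors.

## Pipeline

1. **EDF input** (`readEDF`). Channels are mapped to the roles
   `EEG1` (parietal), `EEG2` (frontal) and `EMG` by case-insensitive
   regular expressions (`defaultChannelMap()`), since EDF labels vary
   between acquisition systems. Amplitudes are converted to microvolts
   from the declared physical dimension (`uV`/`mV`/`V`; an unknown unit is
   assumed to be microvolts, with a warning). Rates below 100 Hz are
   rejected: the feature set needs the 30–40 Hz band comfortably below
   Nyquist.
2. **Optional resampling** (`resampleRecording`). Implemented in the
   Fourier domain: the spectrum is truncated at the target Nyquist
   frequency and inverse-transformed at the new length. This is
   anti-aliased by construction — content above the new Nyquist is removed
   exactly rather than attenuated by a finite filter — which matters
   because band powers up to 40 Hz are features and a leaked 55–60 Hz
   component would alias into them. Only downsampling (to ≥ 100 Hz) is
   supported.
3. **Quality control** (`checkQuality`). Two recording-level exclusion
   criteria: any EEG channel whose absolute amplitude stays below 1 µV for
   at least 50% of samples, or an EMG channel below the EMG floor for at
   least 50%. The comparison is inclusive (`>= 50%`), "amplitude" is the
   absolute instantaneous sample value on the raw (unfiltered) signal, and
   the decision is therefore invariant to sign flips and sample order. The
   default EMG floor is 1 pV (`1e-6` µV) — at 16-bit quantization this only
   catches dead channels; `emgFloor = 1` (µV) is the recommended setting
   when the EMG criterion should mirror the EEG one. QC is advisory in
   library use (a report) and gating in the CLI `score` command unless
   `--no-qc`.
4. **Epoching**. Epochs tile the recording contiguously from time zero;
   a trailing partial epoch is discarded (floor rule). Recordings shorter
   than one epoch are an error.
5. **Feature extraction** (`extractFeatures`), below.
6. **Classification** (`fitGBM` / `fitLogreg` / `fitRandomForest`,
   `predictStages`), below.

## The canonical feature schema

All channels are first bandpass filtered 1–40 Hz (zero phase), which also
removes 50/60 Hz line interference. Per EEG channel the extractor computes
46 raw quantities per epoch:

* 5 broadband time statistics: mean, median, maximum and population
  standard deviation of |x|, and RMS (µV);
* 6 band powers (delta 1–4, theta 4–8, alpha 8–12, sigma 12–15, beta
  15–30, low gamma 30–40 Hz) from a single-segment FFT of the 10-s epoch,
  scaled `(2/n²)·Σ|X_k|²` over the half-open bin range `[low, high)` so the
  value is the band's contribution to the signal's mean square and is
  comparable across sampling rates;
* 5 band/delta power ratios (theta-, alpha-, sigma-, beta-, low
  gamma-to-delta);
* 30 FIR band-filtered time statistics (the 5 time statistics after
  zero-phase bandpass to each of the 6 bands).

Each raw quantity is accompanied by two per-recording normalized versions
— divided by the per-recording mean and by the per-recording median of
that quantity — giving 138 features per EEG channel. The EMG contributes
the 15 broadband time statistics only (rodent EMG carries little useful
spectral structure below 40 Hz). Totals: 291 features for the two-EEG
variant, 153 for the single-EEG variant (whose EEG block is named
channel-agnostically, so one model serves either physical EEG channel);
45 features are temporal, 123 per EEG channel are frequency-domain.

The per-recording normalization is the mechanism that absorbs
inter-recording amplitude differences (electrode impedance, amplifier
gain): scaling a whole recording leaves every normalized feature
unchanged, which the tests assert bit-for-bit.

### Numerical choices

* FIR filters are linear-phase Hamming-window designs with order
  `ceiling(3.3·rate/1 Hz)` (≈1 Hz transition bandwidth at any rate) and are
  applied forward–backward (zero phase) in the frequency domain, which is
  algebraically the squared-magnitude response of the kernel without the
  O(n·taps) time cost.
* Inside `extractFeatures` the band-filtered statistics are computed by
  filtering the whole channel once per band and then segmenting, avoiding
  per-epoch edge transients; the exported `bandFilteredStats` operates on
  a single epoch for oracle-style testing.
* Denominators (per-recording mean/median, delta power in ratios) are
  floored at `1e-12`, so degenerate all-zero signals produce finite
  features rather than NaN.
* The standard deviation divides by `n` (population form) for exact
  determinism and simple closed-form tests.
* Band intervals are half-open `[low, high)` so adjacent bands never
  double-count an FFT bin.
* Power spectra use the plain single-segment FFT of the epoch, not Welch
  averaging: the epoch is already the analysis unit, and the classifier
  consumes relative band structure rather than low-variance density
  estimates.

## Classifiers

All models consume the same feature matrix and fixed class order
(Wake, NREM, REM). Random seeds are explicit arguments everywhere
(default 0).

* **Gradient-boosted trees** (the primary scorer): leaf-wise growth with
  100 leaves per tree, learning rate 0.01, up to 100,000 boosting rounds,
  multiclass softmax objective. The training set is split 80/20 at the
  epoch level (plain random split); the 80% fits trees and the 20%
  validates early stopping, which halts after 500 rounds without
  improvement of the multiclass log-loss — log-loss being the conventional
  default early-stopping metric for boosted trees. The round actually
  reached is recorded on the model. The implementation is xgboost's
  histogram method in leaf-wise (`lossguide`) mode, which grows trees
  leaf-wise exactly as LightGBM-style boosting does.
* **Multinomial logistic regression** baseline: ridge (L2) penalty with
  inverse regularization strength 1, intercept, tolerance `1e-4`, up to
  10,000 iterations, unstandardized features (via glmnet).
* **Random forest** baseline: 100 trees, Gini impurity, unlimited depth,
  minimum node size 1, bootstrap resampling.
* No class weighting: stages are learned at their natural imbalance.

Trained models carry a fingerprint (FNV-1a hash) of the ordered feature
names; prediction reorders name-keyed columns automatically and refuses
genuinely different schemas, naming both fingerprints.

**Evaluation** is subject-grouped: `splitBySubject` partitions animals,
never epochs or recordings, so no subject contributes to both sides —
recordings from one animal share individual patterns that would otherwise
leak. Metrics are per-stage recall, precision and f1, the agreement rate
(accuracy), and Cohen's kappa `(accuracy − p_e)/(1 − p_e)` with
`p_e = Σ_s row_s·col_s/total²`. A stage absent from a rater yields NaN for
the undefined quantity rather than a silent 0. In the degenerate case
`p_e = 1`, kappa is defined as 1 if agreement is perfect and 0 otherwise.
Swapping which rater is ground truth swaps recall and precision and leaves
f1 unchanged, which makes f1 the right symmetric statistic for
expert-vs-expert comparisons; the tests assert the identity exactly.

**SHAP attributions** (`computeShap`) are exact tree-path-dependent SHAP
values from the boosted model, per epoch and class, satisfying local
accuracy (base value plus contributions equals the class margin, up to the
engine's single-precision output). Global summaries are mean absolute
contributions per feature and class. Attribution is available for the
boosted kinds only.

## The synthetic benchmark generator

The generator exists so the whole pipeline can be exercised and graded
without any recorded data. It emulates exactly the structure the features
exploit, and nothing more:

* **Hypnogram**: a continuous-time semi-Markov chain — exponential dwell
  with per-stage means, embedded transitions with REM entered
  predominantly from NREM (Wake→NREM only; NREM→Wake 0.6/→REM 0.4;
  REM→Wake 0.7/→NREM 0.3) — discretized to 10-s epochs by majority
  occupancy. Light-cycle dwell means are Wake 120 s, NREM 160 s, REM 55 s,
  giving roughly 37/55/8% Wake/NREM/REM; the dark cycle lengthens Wake
  dwell to 420 s, shifting proportions toward Wake as in mouse actigraphy.
  These values were chosen once as typical of fragmented C57BL/6 sleep
  architecture at this granularity.
* **Signals**: each EEG channel is a sum over the six canonical bands of
  unit-RMS band-limited noise (white noise passed through the same FIR
  bandpass filters the extractor uses, so spectra are continuous and leak
  across band edges), weighted per epoch by the stage's band profile and
  amplitude scale (Wake 40, NREM 80, REM 50 µV RMS; NREM delta-weighted
  0.55, REM theta-weighted 0.55), plus a 2 µV white noise floor and a
  60 Hz line tone (5 µV default). EMG is broadband noise at stage scales
  40/10/3 µV (Wake/NREM/REM). A per-subject gain factor (uniform 0.5–2)
  multiplies everything, exercising the per-recording normalization.
* **Benchmark** (`makeBenchmark`): 12 subjects × 2 recordings (one light,
  one dark) × 1 h at 256 Hz — 8,640 epochs — written as EDF plus label
  files plus a manifest, all seeds derived from one master seed. One hour
  per recording and 256 Hz are desk-scale choices: they preserve every
  pipeline property being tested (epoching, band structure, per-recording
  normalization, grouped splitting, early stopping) at a few minutes of
  total compute. A `separability` knob shrinks all stage signatures toward
  their mean, monotonically degrading achievable kappa; the tests use it
  to confirm the benchmark's difficulty is controllable.

**What passing the benchmark does and does not show.** Epochs within a
stage are statistically exchangeable here, stage signatures are stationary
within a recording, and mixed-stage epochs arise only at episode
boundaries (the honest cost of majority-vote discretization). Real
recordings add artifacts, drift, inter-individual spectral idiosyncrasy
and ambiguous transitional epochs, none of which the generator emulates.
A near-perfect benchmark kappa therefore validates the pipeline's
plumbing, feature semantics, split hygiene and training mechanics — it is
not a claim about accuracy on recorded mice, which in practice lands near
human inter-rater agreement rather than at 1.

## Design choices where the design was open

* The per-channel feature itemization is reconstructed from the printed
  totals (138 = 15 + 18 + 15 + 90 per EEG channel); it is the only
  decomposition consistent with all of 291/246/153/138/123/45/15 under the
  stated mean/median normalization rule.
* Truncation of non-multiple-of-10-s recordings uses the floor rule;
  labels in practice align to whole epochs.
* The low-amplitude QC fraction is computed on the raw signal, before any
  filtering — filtering would smear exactly the flat segments the
  criterion looks for.
* No extra 60 Hz notch beyond the 1–40 Hz bandpass: the stopband already
  attenuates 60 Hz by orders of magnitude.
* The inner early-stopping split is a plain random epoch split (not
  stratified, not grouped): it only tunes the stopping round, and the
  outer evaluation remains subject-grouped.
* Resampling is Fourier-domain rather than polyphase decimation; see step
  2 above for why exact band-limitation was preferred.
* Model archives store the booster as a portable raw dump plus schema
  fingerprint and metadata in a single RDS file; no pretrained weights
  ship with the package — the generator makes a demo model in seconds.

## Known limitations

* Per-epoch independence means no hypnogram smoothing; isolated
  single-epoch stage flips that a human would overrule are kept.
* REM is the hardest stage in practice (shortest episodes, most mixed
  epochs); per-recording reports break out per-stage f1 so this is
  visible.
* The EDF writer emits plain 16-bit EDF with 1-s records; EDF+
  annotations are ignored on read, and per-channel heterogeneous rates
  among the mapped channels are rejected rather than resampled.
* SHAP export is restricted to the boosted models; there is no exact
  TreeSHAP for the random-forest baseline here.
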