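---
title: "Methods: building and auditing a PPG-to-blood-pressure benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and auditing a PPG-to-blood-pressure benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpbench)
```

## The problem

Cuffless blood-pressure estimation maps a photoplethysmogram (PPG) — a
unit-free optical waveform of blood-volume variation — to systolic and
diastolic pressure (SBP/DBP, mmHg), whose gold-standard reference is the
invasive arterial pressure waveform (ABP). Published models are hard to
compare: preprocessing differs, validation splits often leak subject
information, and absolute errors are incomparable across datasets with
different blood-pressure ranges. `bpbench` packages the three ingredients a
fair comparison needs — a shared cleaning pipeline with an audit trail, a
subject-grouped multi-label stratified split, and a scale-free headline
metric (MASE) — together with a synthetic paired PPG/ABP generator so the
whole machinery is testable end to end without any external waveform
download.

## The synthetic generator

No public generative model exists for paired PPG/ABP records, so the
waveform family here is the package's own construction, chosen for
analysability rather than physiological mechanism:

* Each cardiac cycle is the sum of two smooth asymmetric Gaussian lobes — a
  systolic lobe and a smaller dicrotic lobe. The shape is infinitely
  differentiable, so the velocity (VPG) and acceleration (APG) landmarks
  (w, y, z and a–e) exist and have analytically predictable positions. The
  width asymmetry is blended over 0.8 lobe widths; narrower transitions
  introduce spurious curvature extrema that corrupt APG landmark detection.
* `notch_delay` positions the *dicrotic notch* (the APG `e` wave — the
  curvature maximum on the leading flank of the dicrotic lobe, placed
  `sqrt(3)` lobe-widths before the crest), not the crest itself. This makes
  `T_s_e` recover `notch_delay` to within one or two samples.
* ABP spans exactly `[dbp, sbp]` in the noiseless case; PPG is the same
  cycle structure, unit-normalized to `[0, 1]`, delayed by `ppg_delay`
  (a transit-time delay), with optional additive Gaussian noise and
  sinusoidal baseline wander. Noise applies to the PPG channel only: the
  catheter-derived reference is treated as clean, and label variation is
  controlled separately (below).
* A cohort draws per-subject latent (SBP, DBP) levels from shifted
  log-normal distributions parameterized by interpretable (mean, sd, skew)
  moments — the presets carry the published summary statistics of four open
  datasets (e.g. 134.36/65.37 ± 21.78/10.51 mmHg for the MIMIC-derived
  multi-subject preset). Pairs with SBP ≤ DBP are rejection-resampled and
  the rejection rate reported. Segments within a subject vary by
  `within_subject_sd` (default 3 mmHg), making samples of one subject
  correlated — the property the leakage experiments need. Each subject also
  draws a stable heart rate and a stable waveform morphology (notch depth
  and relative delay), so subjects have feature-space fingerprints, as real
  subjects do.
* `artifact_fraction` of records receive a tagged injected artifact from
  the six *filter-violating* kinds (flatline, amplitude spikes, pressure
  above 220 mmHg, pulse pressure below 10 mmHg, tachy- and bradycardia).
  Baseline drift (`bw_drift`) is available too but is deliberately not in
  that set: it is a *correctable* artifact — the spline step removes the
  drift, not the segment — so it carries no removal ground truth.

What the generator does **not** emulate: sensor-specific noise spectra,
motion artifacts with physiological structure, pulse-wave reflection
changes with pressure, or any causal PPG–BP coupling (the optional
`hr_sbp_link` makes SBP an affine function of heart rate purely as a
*learnability* probe). Passing tests on this generator therefore
demonstrates that the machinery is correct, not that any model will
estimate blood pressure well on real data.

## The cleaning pipeline

`run_pipeline()` applies, in order: (0) cross-correlation alignment of each
PPG/ABP pair (shift capped at ±1 s; positive shift means the PPG lags and
is advanced) and segmentation into non-overlapping 5 s chunks (2.1 s for
short-record data); (1) ABP screening — samples outside 30–220 mmHg, median
per-cycle pulse pressure not strictly above 10 mmHg, heart rate outside
35–140 BPM (closed bounds pass), or no identifiable cycle — with SBP/DBP
labels extracted from passing segments as the median of the cycle-peak
values and the median of the pooled onset/offset values; (2) PPG cycle
identification with the same heart-rate limits; (3) removal of distorted
waveforms by thresholding four standard deviations (peak-to-peak and
valley-to-valley intervals, peak and valley amplitudes); (4) baseline-wander
removal by a natural cubic spline through the valleys (constant-extrapolated
beyond the terminal knots) followed by a re-check of the cycle and
distortion criteria; (5) removal of segments on which feature extraction
fails; (6) removal of segments with negative skewness (the signal-quality
index). Every step logs deleted/kept counts per criterion, and the audit
table satisfies `kept(k) = kept(k−1) − deleted(k)` exactly.

Numerical choices worth knowing:

* **Peak detector.** Local extrema filtered by topographic prominence ≥ 40%
  of the segment's amplitude range, minimum spacing 0.3 s. The range (not
  the interquartile range) is the reference because a pulsatile signal
  spends most of its time near baseline, which collapses the IQR; and the
  spacing floor is deliberately *above* the physiological maximum (200 vs
  140 BPM) so tachycardic rhythms are detected and then rejected by the
  BPM filter rather than silently thinned at detection time.
* **Distortion thresholds.** The default derives each threshold as the
  97.5th percentile of the statistic over the candidate population, the way
  thresholds are read off cumulative-percentage plots. Note the union over
  four statistics removes ≈ `1 − 0.975^4` ≈ 10% of even a perfectly clean
  population; for synthetic presets the package ships explicit frozen
  thresholds (`preset_distortion_thresholds()`), obtained by inspecting
  clean-cohort distributions once, under which clean cohorts pass intact.
* **Idempotence.** `run_pipeline()` returns `config_used` with the resolved
  thresholds and alignment disabled (kept segments are already aligned and
  cut); re-running the kept segments under `config_used` removes nothing.
  Re-running under percentile mode would instead re-trim the new top tail
  forever — an intrinsic property of percentile thresholds.
* **Boundary rules.** All filter intervals are closed; pulse pressure must
  be strictly greater than 10 mmHg; skewness exactly 0 is kept (strict
  `< 0` removal); even-count medians are the mean of the central pair.

## The feature catalog

Features are computed per cycle and aggregated across a segment's cycles by
the **median** (robust to one residual odd cycle), except the spectral
features, computed once per segment:

* **Landmarks.** `o`, `s`, `f` from cycle detection; `w`/`y`/`z` as the VPG
  maximum in (o,s), minimum in (s,f), and maximum in (y,f); `a` as the APG
  maximum in (o,s) and `b` the first APG minimum after it. The notch `e` is
  the largest interior APG maximum in (s,f), *certified* by the presence of
  a second maximum there: a dicrotic lobe contributes a notch shoulder plus
  a trailing flank, while a notch-free falling limb carries exactly one
  curvature maximum — so single-lobe pulses fail with the missing-point
  name `e`, which routes the segment to the feature-failure removal step.
  `c`/`d` are the first APG max/min pair between `b` and `e`. A strict
  alternating-extrema chain was rejected because for mid-range notch delays
  the systolic falling-limb curvature maximum merges into the notch rise
  and the chain mislabels `e`.
* **Pre-smoothing.** Second derivatives amplify white noise by the square
  of the sampling rate, so `extract_features()` smooths the PPG with a
  short cubic Savitzky–Golay filter (11 samples ≈ 88 ms at 125 Hz,
  zero-phase) before differentiating. `derivatives()` itself is plain
  central differences with one-sided ends, in per-second units.
* **Elapsed times** `T_x_y` for all pairs among {o, w, s, e, z, f}, as
  absolute time differences — `e` (APG notch) and `z` (VPG diastolic rise)
  have no fixed mutual order on sampled signals, and the catalog's
  invariant is that elapsed times are non-negative.
* **Areas** by trapezoidal integration of the (per-cycle minimum
  subtracted) PPG over phases split at w, s, e: `A1`–`A4`, with
  `A_sys = A1 + A2`, `A_dia = A3 + A4` (additivity is exact).
* **Widths** `SW_p`/`DW_p` at 25/50/75% of the onset-referenced peak
  amplitude, by linear interpolation of the crossings, plus their sums and
  `DW/SW` ratios.
* **Spectral**: dominant frequency in 0.5–8 Hz, its magnitude, and the mean
  magnitude within ±0.5 Hz of it excluding the peak bin.
* **Histograms**: 5 systolic + 10 diastolic equal-width bins per signal
  (PPG/VPG/APG), ranges per-phase min–max (the PPG is unscaled, so global
  ranges would be meaningless), densities summing to 1.
* **Slope deviation** (SDC): mean absolute deviation of each phase from its
  straight chord, normalized by the peak-minus-onset amplitude (a convex
  quadratic upstroke against its chord gives exactly 1/6).
* **Quality and indices**: moment skewness and excess kurtosis of the cycle
  samples; the aging index `AI = (b − c − d − e)/a`; `I_bd = b/d`;
  `I_bcda = (b − c − d)/a`; and `I_sdoo = (t_d − t_s)/(t_f − t_o)`. The
  first three follow the conventional APG literature; the `I_sdoo` formula
  is an adopted convention (the name's letters read: systolic peak to d,
  over onset-to-onset) and is isolated in one documented function so it can
  be swapped if a different convention is preferred.

The extractor emits an identical ordered schema (127 features) for every
kept segment; any sub-extractor failure marks the whole segment
feature-failed.

## Validation splitting

SBP and DBP are each encoded into four classes (cut points 100/140/160 and
60/80/100 mmHg, half-open `[lo, hi)` so 140 falls in the third SBP class),
giving 16 joint classes. Each subject is summarized by its count row over
the 16 classes, and subjects are assigned to folds by greedy iterative
multi-label stratification: repeatedly take the rarest remaining class,
within it the subject holding most of it, and place that subject in the
fold with the largest remaining desideratum for the class (ties by
remaining fold capacity, then seeded randomness). All segments of a subject
share a fold, so subject leakage is exactly zero. The same engine with
unequal weights produces stratified train/validation/test holdout splits;
when subject identifiers are missing, records act as pseudo-subjects and
this is flagged loudly as a leakage caveat. `leaked_split()` provides the
deliberately wrong baseline — uniform segment-level assignment — and
`audit_split()` reports per-fold class histograms, total-variation distance
to the global distribution, and the measured leakage fraction.

## Evaluation

`Diff_i = P_PRED_i − P_REF_i`; ME is its mean, SD its sample standard
deviation (n−1), MAE the mean absolute value. The naive predictor emits the
training-set mean; MASE is `100 · MAE / MAE_naive` (percent), computed on
pooled predictions: metrics are always computed once on the concatenation
of all folds' predictions, never as an average of per-fold metrics. The
naive denominator pools each fold's own training mean — the naive model
must not see its test fold either — which preserves the exact identity
*naive pooled MASE = 100* for every cohort and split mode. Waveform-output
models are scored by running the same cycle detection and label extraction
used on reference ABP over their predicted waveform, with undetectable
cycles counted as missing rather than erroring. Model pairs are compared by
a paired bootstrap (segments resampled with replacement, 2000 replicates by
default) of the MASE difference, with percentile intervals at
Bonferroni-corrected levels `1 − α/m` for α ∈ {0.05, 0.01, 0.001}.

## Feature selection and tuning

`rank_features()` fits two fully grown 500-tree ensembles — a bagged forest
and an extremely-randomized variant — and averages their impurity-decrease
importances, normalized to sum to 1. For regression trees the impurity is
the node variance; this is the regression analogue of what classification
literature calls Gini importance. `select_features()` keeps the top
`ceil(rate · n)` names. `tune_and_fit()` grid-searches hyperparameters
jointly with the selection rate by mean inner-validation MAE over
subject-stratified inner folds built from the training subjects only (ties
break toward fewer features, then grid order), then re-ranks and refits on
the full training partition. The shipped model zoo (naive, k-NN, random
forest, SVR, gradient-boosted trees, boosted stumps, single-hidden-layer
feed-forward net) stands behind one `fit_bp_model()`/`predict_bp_model()`
contract; the published-style search spaces are in `feat2lab_grid()` and
`selection_rate_grid()`, while the per-model defaults are single sensible
points so that untuned runs stay fast. The feed-forward family is
implemented with a single hidden layer; deeper stacks from the published
search space are not reproduced, and the net standardizes inputs and target
internally (choices the grids cannot express are documented here rather
than inferred).

## Experiment scales

The shipped tests and the acceptance script run, per experiment, cohorts of
8–50 subjects with 3–8 five-second segments each at 125 Hz — large enough
that fold-level MASE estimates stabilize, small enough to run on one CPU in
well under an hour in total. The learnability probe uses 50 subjects × 5
segments with SBP = 30 + 1.4·HR + ε, ε ~ N(0, 2 mmHg), and segment-level
label jitter of 1 mmHg; the leakage probe uses 20 subjects × 8 segments
with 1 mmHg within-subject label variation and 0.3 BPM heart-rate jitter,
so that segments of one subject are near-replicas — the regime in which
segment-level splitting is most misleading.

## Known limitations

* The waveform family is two-lobed; pulses with prominent reflected waves
  (three lobes) or pathological morphologies are out of its range, so the
  landmark detector's behaviour on such shapes is untested here.
* The `e`-certificate (two APG maxima in the diastolic window) is tuned to
  this family's geometry; on heavily smoothed real signals a shallow notch
  can fall below detectability and will be routed to feature-failure
  removal — the correct conservative behaviour, but it costs yield.
* Deep-learning waveform models are supported only through the model
  contract (`Sig2Sig` outputs are scored via
  `labels_from_predicted_abp()`); no network training is included.
* The UCI-style pseudo-subject holdout cannot rule out subject leakage and
  says so; its leakage fraction is reported as unknown rather than zero.
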