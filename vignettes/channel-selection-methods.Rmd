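---
title: "Wavelet features and multi-objective EEG channel selection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet features and multi-objective EEG channel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegselect)
```

`eegselect` classifies mild cognitive impairment (MCI) against healthy
controls (HC) from 19-channel resting-state EEG and searches for small
electrode subsets that preserve — or improve — that classification.
This vignette explains the model at each stage, the tunable parameters
and their defaults, the numerical decisions taken where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Signal model and preprocessing

A recording is a `ch × samples` matrix of scalp potentials (µV) at a
sampling rate `fs` (256 Hz throughout the defaults). Preprocessing is
deliberately minimal:

* **Band-pass 0.5–32 Hz, Butterworth order 5** (`bandpass_filter()`).
  The high-pass edge removes baseline drift; the low-pass edge excludes
  AC line noise entirely, so no notch filter is needed. The filter is
  applied forward and backward (`signal::filtfilt`), i.e. zero-phase.
  A causal application would have been equally defensible; zero-phase
  was chosen because the entropy measures downstream operate on the
  time course of sub-band waveforms, and phase distortion would shift
  threshold crossings. The effective attenuation order doubles as a
  side effect.
* **Segmentation into 10 s non-overlapping windows**
  (`segment_recording()`), starting at sample one, remainder
  discarded. Segments never straddle subjects. At 256 Hz a 10-minute
  recording yields 60 segments of 2560 samples.

## Wavelet sub-band features

Each channel's segment is decomposed with a level-4 discrete wavelet
transform (db4 by default; `haar` is also wired in). Rather than using
the coefficients directly, each coefficient set is re-expanded into a
full-length time-domain signal by zeroing all other coefficients and
inverting the transform, producing five "WP signals": `cA4` and
`cD4 … cD1`. By linearity these sum back to the input exactly
(`dwt_subband_signals()`; the tests enforce agreement within 1e-6
relative, and the implementation achieves ~1e-12).

Two caveats are worth stating explicitly:

* At `fs` = 256 Hz the dyadic bands are cA4 ≈ 0–8, cD4 ≈ 8–16,
  cD3 ≈ 16–32, cD2 ≈ 32–64, cD1 ≈ 64–128 Hz. These are close to, but
  not identical with, the named EEG rhythms (delta/theta/alpha/beta/
  gamma); the package names bands by coefficient identity, never by
  rhythm.
* Boundary handling is symmetric (mirrored) extension, so coefficient
  counts per level are `floor((n + L - 1)/2)` for the `L = 8`-tap db4
  filter. The filter-bank kernels are compiled (Rcpp) because each
  full-scale cohort run performs ~70,000 decompositions.

One scalar measure then summarises each of the five sub-band signals
plus the original segment, giving six features per channel — 114 for
the 19-channel montage (`extract_segment_features()`,
`build_feature_matrix()`). The seven measures (`compute_measure()`)
are energy, log band power, and five entropy-family measures
(threshold, norm, SURE, log-energy, transformation-Shannon).

### Interpretation of the measure formulas

The entropy measures here are the sample-based variants popular in
wavelet toolboxes, not probability-distribution entropies: `xᵢ` is the
raw i-th sample and `k = N`, which is the only reading under which the
default thresholds (α = 0.2 µV-scale amplitude, SURE threshold £ = 3)
are meaningful. Specific decisions, all configurable through
`measure_params()`:

* Threshold comparisons use `|xᵢ|`. Band-passed signals are zero-mean,
  so a signed comparison would silently ignore the negative half of
  every oscillation.
* Logarithms are natural logs.
* `LogEn` and `TShEn` are undefined at zero samples; a guard
  `ε = 1e-12` is added inside every log term. `BP` of an all-zero
  signal returns `log(ε)` instead of `-Inf`.
* `TShEn = (1/N) Σ xᵢ² log xᵢ²` is implemented exactly in this form,
  without a leading minus sign — it is the negative of the conventional
  Shannon expression up to scale, and is kept as-is so that feature
  values match the formula users will expect from the wavelet-toolbox
  tradition.
* Defaults: α = 0.2, p = 1.1 (norm entropy exponent), £ = 3, with the
  admissible ranges 0 < α < 1, p ≥ 1, £ > 2 enforced.

## Classification and validation

Four classifier families share one integer hyperparameter, matching
the single parameter gene used by the optimisers
(`classifier_spec()`): KNN (K ∈ 1–10), SVM (kernel 1 = linear,
2 = polynomial degree 3, 3 = RBF), discriminant analysis (1 = LDA,
2 = QDA) and random forest (depth 1–35, 100 trees).

`crossval_evaluate()` implements stratified 10-fold cross-validation:

* Folds are drawn once per evaluation from `cv_config()$seed`;
  within-class round-robin assignment keeps fold sizes within one row
  of each other and both classes in every fold.
* Features are z-scored with means/sds fitted **on the training part
  of each fold only**; zero-variance columns are dropped. KNN and SVM
  are scale-sensitive and the seven measures live on wildly different
  scales, so some normalisation is unavoidable; train-only fitting
  avoids information leakage.
* MCI is the positive class. Metrics with zero denominators are
  reported as `NA` (undefined), never coerced to 0.
* Cross-validation is **segment-level** by default: segments of one
  subject may appear in both training and validation folds. This
  mirrors the protocol of the MCI-EEG literature this package engages
  with, but it is an optimistic protocol whenever subjects have
  idiosyncratic signatures; `cv_config(grouped = TRUE)` provides
  subject-grouped folds for the conservative alternative.
* KNN is implemented in-package with a deterministic tie-break (tied
  votes resolved by the single nearest neighbour), so repeated
  evaluations are bit-identical; the RBF bandwidth uses the
  median-distance heuristic on the training fold; random-forest fold
  seeds derive from the CV seed.

## Greedy channel selection

`backward_eliminate()` starts from all C channels (one evaluation),
then repeatedly removes the channel whose removal maximises CA;
`forward_add()` mirrors it upward. Both record C iterations and cost
exactly `C(C+1)/2` evaluations — 190 for C = 19 — which the tests
verify with a counting mock evaluator. `single_channel_ranking()` plus
`incremental_subsets()` give the naive baseline of adding channels in
order of individual merit. Two fixed conventions: ties on CA keep the
candidate earliest in montage order, and the CV fold seed is shared
across every evaluation inside one search so that subset comparisons
are paired rather than re-randomized.

## Multi-objective optimisation

The optimisers solve: maximize CA, minimize `no_ch`, subject to
`no_ch ≥ 1`, over 19 binary channel genes plus the parameter gene.
Dominance, fronts (`fast_nondominated_sort()`), crowding distance
(`crowding_distance()`), Das–Dennis reference points
(`reference_points()`) and the external archive are all first-class,
tested primitives.

Choices where the standard algorithms leave freedom (all exposed via
`moo_config()`):

* **Variation (NSGA-II/III)**: uniform crossover (per-gene 0.5,
  per-pair probability 0.9), bit-flip mutation at rate `1/(C+1)`, and
  parameter-gene redraw at the same rate — standard binary-GA
  defaults.
* **Constraint handling**: an all-zero channel mask is repaired by
  activating one uniformly random channel; with only one constraint,
  repair is simpler and less distorting than penalties.
* **Survival**: NSGA-II uses (µ+λ) rank-then-crowding; NSGA-III
  replaces the last-front tie-break by reference-point niching with
  min-max normalized objectives (CA negated) and perpendicular-distance
  association. The default division count makes the reference set the
  size of the population.
* **MOPSO**: particles move in `[0,1]^C × [param range]`; channel
  genes are obtained by thresholding positions at 0.5 and the
  parameter dimension by rounding. Leaders are drawn from the archive
  by crowding-biased binary tournament; personal bests are replaced
  when dominated (mutual non-dominance resolved by coin flip); a
  per-dimension turbulence redraw at rate `1/(C+1)` prevents premature
  collapse — without it the swarm misses planted optima on a
  noticeable fraction of seeds. The archive is capped (default 100) by
  discarding the most crowded member.
* **Caching**: objective values are cached by genotype
  `(genes, param)`; at population 100 × 50 generations, revisits are
  the rule rather than the exception.
* **Returned front**: the run returns the external archive of all
  non-dominated solutions encountered (the final population's first
  front is a subset). This makes the per-channel-count best accuracy
  non-decreasing over generations, which the tests assert.
* Defaults `population_size = 100`, `max_iter = 50` match the scale of
  the wrapper-selection studies this implements; the recovery tests run
  at population 40 × 30 generations, which is ample for the 19-bit
  search space.

All randomness in a run derives from one seed; runs are bit-for-bit
reproducible, and every stochastic entry point restores the caller's
RNG state.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the *shape* of the
kind of two-class resting-state study the pipeline targets: 32 HC + 29
MCI subjects, 600 s per subject at 256 Hz, 19 channels in a fixed
10–20 montage order (Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4, T4,
T5, P3, Pz, P4, T6, O1, O2 — front-to-back, chosen once for
reproducibility since montage diagrams do not prescribe an order).

Each channel is stationary Gaussian noise with power concentrated in
the five canonical rhythm bands (delta 0.5–4 Hz at amplitude 20 µV,
theta 4–8 at 10, alpha 8–13 at 15, beta 13–30 at 5, gamma 30–32 at 2 —
a 1/f-like profile with the eyes-closed alpha peak) plus 2 µV of flat
sensor noise. The class effect is *EEG slowing*: on the planted
channels only, MCI subjects have theta variance multiplied by
`1 + effect_size` and alpha variance divided by it, so `effect_size = 0`
makes the classes identically distributed (the chance-level control
the tests rely on).

Implementation note: the band components are synthesized in the
frequency domain — one white series per channel shaped by the square
root of the summed band-power envelope, where each band's envelope is
the squared magnitude response of a 4th-order Butterworth band-pass
normalized to unit average power. For stationary Gaussian noise this
is equivalent in distribution to summing independently band-pass
filtered white-noise streams, and it is roughly twenty times faster,
which keeps full-scale cohort generation to seconds per subject. Each
subject's stream is derived from `(seed, subject index)` by a fixed
integer hash, so cohorts are order-independent and bit-reproducible.

**What the generator does not emulate** — and hence what passing tests
do and do not show: no eye-blink/EMG/movement artifacts, no
non-stationarity or state drift, no subject-level random effects (two
subjects differ only by realization noise), and — importantly — no
inter-channel correlation from volume conduction: generated channels
are independent, whereas real scalp EEG is strongly spatially
correlated. Consequently, planted-channel recovery on synthetic
cohorts validates the *search machinery* (that wrappers find where
class information lives), not clinical effect sizes; accuracies
obtained here do not transfer to real recordings, and segment-level CV
results on real data should additionally be checked with
`grouped = TRUE`.

## Problem sizes used by the tests and the acceptance script

The test-suite sizes were fixed once, as study conditions: the
structural accounting runs the full 61-subject, 600 s cohort (3660
segments, 3660 × 114 features); planted-channel recovery and
chance-level controls use 10 + 10 subjects × 60 s (120 segments) with
`effect_size = 2` and 0 respectively; planted-optimum recovery of the
optimisers uses a 4-of-19-channel Hamming objective at population 40,
30 generations, five seeds. `scripts/acceptance.R` recomputes all of
these from one root seed.

## Known limitations

* EDF support targets the common 16-bit single-rate layout (one data
  record per second); amplitudes round-trip to the format's
  quantisation step, not to machine precision.
* QDA requires enough rows per class to invert per-class covariances;
  on very small or collinear feature sets `MASS::qda` can fail, and
  LDA may warn about collinearity (the 114 wavelet features are highly
  correlated by construction).
* The measures follow the wavelet-toolbox sample-based convention
  (see above); they are not information-theoretic entropies, and
  `TShEn` carries the sign of the formula it implements.
* Channel selection inherits whatever bias the chosen CV protocol has;
  segment-level CV is the reference behaviour by design, not an
  endorsement.
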