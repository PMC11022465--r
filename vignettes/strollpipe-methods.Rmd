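---
title: "strollpipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strollpipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strollpipe)
```

This vignette is the package's own account of its science: the models
behind each stage, the assumptions they make, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate,
and the numerical and design choices taken where the analysis design left
them open.

## 1. The question and the two measurement settings

In rehabilitation research, walking *capacity* is typically measured in
clinic — for example gait speed over a two-minute walk test (2MWT) on a
short path, here instrumented with three IMUs (both feet and low back,
104 samples/s) — while walking *performance* (walking ability in daily
life) is measured by wearing a single sensor for days: steps per day, and
the average and maximum daily gait speed from an acceleration-only calf
IMU at 52 samples/s. The pipeline estimates the association between the
two with linear mixed models and asks whether IMU gait features beyond
gait speed (compressed into principal components) act as confounders or
effect modifiers of that association.

## 2. The 2MWT chain

**Preprocessing** (`preprocess()`): every stream is linearly interpolated
onto a uniform 100 Hz grid, and the per-axis gyroscope offset is removed.
The offset is the median angular rate over detected stationary samples
(acceleration norm within 0.3 m/s² of gravity for ≥ 0.2 s); when less
than 0.5 s of stationary data exists, the whole-recording median is used
— during continuous walking the foot sensors provide stance samples and
the trunk sensor falls back to the global median, which is the offset
when the true rates are symmetric about zero.

**Gait events** (`detect_gait_events()`): mid-swing is the maximum of the
sagittal (y-axis) foot angular rate, found by topographic-prominence peak
picking (default prominence 0.5 rad/s, minimum separation 0.4 s; both
configurable, since such thresholds are conventionally tuned per sensor
setup). Initial contact (IC) is the first zero crossing after mid-swing;
final contact (toe-off, FC) the last zero crossing before it. Peaks must
also reach the prominence value in height: without that floor, noise
ripples sitting between the negative toe-off/heel-strike dips acquire
large *topographic* prominence and masquerade as swings.

**Features**: the registry (`feature_registry()`) carries 41 features in
the four standard families; it is deliberately a representative,
extensible catalog rather than an exhaustive battery — adding a feature
is a registry row plus an emitter, with no API change.

* *Spatiotemporal*: stride/step time statistics, stance and swing
  fractions, cadence, gait speed = distance/time (the walked distance is
  supplied directly when known; otherwise path length × inferred
  traversals), stride length = speed × stride time. Strides longer than
  1.5× the median stride are flagged as turns and excluded from stride
  statistics: on a 14 m path, turning strides otherwise inflate
  variability. The factor is a parameter; the analysis design itself is
  silent on turn handling.
* *Frequency*: per trunk axis, the dominant frequency in 0.3–5 Hz from a
  Welch periodogram (Hamming windows, 50% overlap), refined within one
  bin by maximizing the projected amplitude — the raw Welch grid
  (≈ 0.05 Hz) is too coarse for amplitude readout; the index of
  harmonicity (power at the dominant frequency over its first six
  harmonics); and the harmonic ratio over the first 20 harmonics of
  stride frequency (even/odd for AP and vertical, odd/even for
  mediolateral, following the convention that trunk AP/vertical motion is
  step-periodic and mediolateral motion stride-periodic).
* *Complexity*: sample entropy (m = 2, r = 0.2 × SD, computed in C++ —
  the O(n²) template count over a 100 Hz 2-minute series is too slow in
  pure R), and step/stride regularity as the first and second dominant
  peaks of the unbiased autocorrelation normalized to lag zero, plus
  their ratio.
* *Asymmetry*: symmetry index SI = |L − R| / (0.5(L + R)) × 100% and the
  ordered max/min ratio for step, stance and swing time.

## 3. The daily-life chain

Recordings are split into consecutive non-overlapping **10 s epochs**
(trailing remainder dropped). The study design used a trained neural
network to identify gait; network weights are not reproducible from a
paper, so the package defines a *classifier contract* (any function
epoch → label) with a rule-based default: off-body when the
acceleration-norm SD stays below 0.02 m/s² (non-wear looks like pure
gravity), gait when the 0.5–3 Hz step-band power fraction of the norm
exceeds 0.5 and the SD exceeds 0.3 m/s², else non-gait.

**Steps** are peaks of the band-passed (0.5–3 Hz) acceleration norm with
minimum prominence 1.5 m/s² and minimum separation 0.25 s. Contiguous
gait epochs are filtered as one segment so steps straddling an epoch
boundary are counted once, and each peak is attributed to its epoch.

**Speed** follows the ZUPT scheme: gravity is removed (per-epoch 0.25 Hz
low-pass in the acceleration-only configuration; a complementary attitude
filter with gain 0.02 when a gyroscope is present — both paths share the
integrator, because the wear configuration records acceleration only
while the described fusion consumes gyro data, and neither can be singled
out as "the" study path); the anterior-posterior (AP) axis is the first
principal component of the horizontal residual, which makes the estimate
invariant to sensor yaw on the calf. Stance is detected as intervals
where the smoothed magnitude of the deviation from gravity stays below
1.0 m/s² for ≥ 0.08 s; the deviation uses a per-axis *median* gravity
vector because a 0.25 Hz low-pass is mostly edge transient on a 10 s
slice. The acceleration *norm minus g* was rejected as the statistic: for
horizontal accelerations it is quadratically suppressed
(‖a‖ ≈ g + a²ₕ/2g), which makes slow-gait swings invisible. Swing is the
complement, so stance and swing tile the epoch. Per swing, AP
acceleration is integrated to velocity (zero at the stance anchor), the
linear velocity trend forced to zero at both anchors is removed
(standard ZUPT drift correction), and a second integration gives the
displacement; epoch distance is the sum of absolute per-swing
displacements and speed is distance / 10 s. Runs of consecutive gait
epochs are segmented and integrated as one stretch, each swing's
displacement attributed to the epoch containing its midpoint — per-epoch
integration loses the partial swings cut at both boundaries, a bias of
order one stride per epoch (≈ 10% at 1.3 s strides).

**Daily summary**: wear time = 10 s × non-off-body epochs, valid iff
≥ 8 h; gait epochs with speed ≤ 0.05 m/s are excluded (below that speed
gait characteristics cannot be determined reliably); average speed is the
mean of the remaining epoch speeds; "maximum" speed defaults to the 95th
percentile rather than the literal maximum, because a single-epoch max is
dominated by integration noise (the percentile is a parameter, 1 gives
the literal max). Day boundaries fall at local midnight via the
recording's start-time metadata.

## 4. Feature selection, PCA, reliability

**Pruning**: while any feature pair has |r| above 0.95, the member of a
violating pair with the largest summed absolute correlation to all
current features is dropped and correlations are recomputed — iterative
single drops, because a batch rule is order-ambiguous; ties break by
registry order. Absolute correlation is used (sign-flipped duplicates are
equally redundant); the report records this convention.

**KMO**: anti-image partial correlations from the inverse correlation
matrix; KMOⱼ = Σr² / (Σr² + Σp²) over pairs involving j, the overall
measure over all pairs; overall < 0.7 or per-feature < 0.5 is flagged. A
numerically singular matrix gets a 1e-8 ridge (recorded); a vanishing
denominator (e.g. two independent features) yields a degeneracy flag
rather than a silent number. The implementation is from the standard
formulas; tests check it against a brute-force oracle that computes every
partial correlation by double regression.

**Standardization**: z-scores with the n−1 sample SD (the convention must
be fixed for exact tests); the fitted means and SDs are stored, and
held-out data are always transformed with the *stored* parameters — the
alternative (re-scoring external data with its own moments) exists as
`standardize()` on the new table, but fixed-loading projection is the
default because scores are otherwise not comparable across datasets.

**PCA** (`fit_pca()`): eigendecomposition of the feature correlation
matrix (identical to the covariance of z-scores — stated to remove
ambiguity); components with eigenvalue > 1 retained (Kaiser); sign
convention: each loading column is oriented so its largest-magnitude
entry is positive; eigenvalues in [0.95, 1.05] are flagged near-threshold
because retention is unstable there. Components are labelled by the
feature with the highest |r| to the component scores, ties broken by
registry order and recorded. The model serializes to YAML (means, SDs,
loadings, eigenvalues, labels, conventions) so projections are
reproducible bit-for-bit.

**Reliability** (`reliability()`): ICC(2,1) — two-way random effects,
absolute agreement, single measure — from the two-way ANOVA mean squares,
with the F-based (McGraw–Wong) 95% confidence interval: deterministic,
unlike a bootstrap. SEM = pooled SD × √(1 − ICC), MDC = 1.96·√2·SEM,
RMSE of the test-retest differences, and the conventional bands
(0.5/0.75/0.9).

## 5. Mixed models and forward selection

Per walking-ability outcome: `outcome ~ gait speed + (1 | subject)`,
REML. Wald-based SEs, 95% CIs and p-values; AIC/BIC always from
maximum-likelihood refits because REML likelihoods are not comparable
across fixed-effect structures; nRMSE = RMS conditional residual divided
by the observed outcome range (the normalizer is a parameter — "mean" is
available — since the design does not define one). A singular fit (zero
subject variance) is reported with a boundary flag, not an error; an
exactly deterministic outcome falls back to the fixed-effects model with
the subject variance pinned at zero.

Candidates (components surviving the |r| ≥ 0.9 collinearity screen
against gait speed and earlier components) are visited in descending
explained-variance order — the design says "forward selection" without an
order, so the order is a parameter. Each candidate is evaluated **against
the gait-speed-only base model**: refit with the candidate as a main
effect, confounder iff the gait-speed coefficient changes by ≥ 10%
relative to the base coefficient; refit with the speed × candidate
interaction (ML, Wald p), modifier iff p < 0.05. Judging against the
accumulating model instead (exposed as `reference = "sequential"`) makes
every candidate after a genuine confounder inherit its coefficient shift
and be spuriously flagged, so the base reference is the default. Flagged
candidates accumulate into the definitive model, which always contains
gait speed. Diagnostics report skewness, excess kurtosis, Shapiro–Wilk
normality and an |residual|-vs-fitted heteroscedasticity screen.

## 6. What the generators emulate — and what they do not

`generate_2mwt_signals()` renders foot sagittal angular rate as a stance
plateau plus a half-sine swing lobe whose magnitude scales with stride
length, with small negative dips at toe-off and initial contact placed
clear of the lobe (so zero crossings stay at the true event times), and
trunk acceleration as step- and stride-frequency sinusoids plus gravity;
white Gaussian noise throughout. Right-foot contacts sit at a fixed
fraction (the left step time, r/(1+r) of the stride for asymmetry ratio
r) between consecutive left contacts, so both feet share one cycle
timing and the per-foot stride-time CV is the requested one.

`generate_daily_recording()` renders gait bouts with an AP full-sine
swing lobe whose double integral over the swing is exactly the stride
length (amplitude 2πL/Ts², which at a default stance fraction of 0.45
and stride time 1.3 s yields the ~10–25 m/s² transients a shank sensor
sees), gravity plus a small step-frequency vertical sinusoid, and
postural-sway or pure-gravity quiet bouts; the per-bout truth (steps =
⌊duration/step time⌋, speeds, wear) is emitted alongside. Defaults
(stride time 1.3 s, stride length 0.9 m, hence ≈ 0.69 m/s) reflect a
sub-acute stroke cohort.

`generate_cohort()` plants a three-factor structure (a dominant latent
walking-capacity factor carried by the spatiotemporal/frequency features,
minor asymmetry and variability factors), 2MWT speed = 0.7 + 0.25 ×
capacity + noise, and outcomes driven by speed with a subject random
intercept, a confounder path (a covariate loading 0.7 on capacity that
also shifts the outcome) and a speed × covariate interaction. The default
path strengths (0.06 for the confounder, 0.2 for the interaction) are
sized analytically so the planted effects are unambiguous at the default
cohort size — the confounder shifts the speed coefficient by roughly
45%, far past the 10% rule, and the interaction Wald statistic sits near
z ≈ 5 — i.e. they represent moderate-to-strong effects, not borderline
ones. Calibration of the *null* (a zero-strength candidate) is assessed
on cohorts generated with both strengths at zero, since planted effects
left in the residual would otherwise contaminate the false-positive rate.

What the generators do **not** emulate: biomechanically realistic
musculoskeletal dynamics, pathological gait phenotypes (hemiparetic
circumduction, spasticity patterns), sensor orientation drift,
magnetometer data, double support timing, or non-walking rhythmic
activities (cycling) that challenge real classifiers. Passing tests
therefore demonstrate that the *pipeline recovers what its own waveform
model encodes* — correctness of the computation chain, not field validity
of any single threshold.

## 7. Determinism and seeds

One top-level seed fans out to per-stream child seeds by a stable 31-bit
string hash of the stream name (`child_seed()`), so adding a sensor or a
bout never perturbs existing streams; identical seed + spec gives
bit-identical output everywhere, and all RNG use is wrapped so the
caller's RNG state is untouched.

## 8. Problem sizes used by tests and the acceptance script

Monte-Carlo checks run at sizes chosen to keep the whole suite fast while
leaving clear margins: selection calibration and power at 100 cohorts of
20 × 3 measurements; oracle equivalence on 50 random 5–8-feature tables;
classifier accuracy over 8 half-hour days; speed recovery on half-hour
recordings per speed. The zero-strength-confounder stability property is
asymptotic in cohort size (the candidate is correlated with speed, so
the adjustment noise shrinks as 1/√n) and is checked at 240 subjects.
`scripts/acceptance.R` recomputes the headline quantities at the same
sizes from a single `--seed`.

## 9. Known limitations

* Gait speed from the 2MWT requires either the walked distance or
  turn-based traversal counting; the synthetic path has no turns, so the
  examples supply the distance via metadata.
* The acceleration-only ZUPT path assumes a roughly constant sensor
  orientation within an epoch; strong orientation drift would need the
  gyro path.
* Wald inference in the mixed models is asymptotic; at very small cohort
  sizes interaction p-values are mildly anti-conservative, which is
  visible in the null calibration when planted effects are present.
* The ICC confidence interval assumes the two-way ANOVA normality
  conditions; heavy-tailed scores would call for a resampling interval.
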