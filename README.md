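# strollpipe

From raw inertial-sensor signals to walking ability in daily life.

`strollpipe` implements, as a tested and reusable R pipeline, the analysis
chain used to ask a recurring question in (stroke) rehabilitation research:
**does IMU-derived gait information beyond gait speed improve the
estimation of walking ability in daily life?** It covers both measurement
settings of that study design —

1. an **instrumented two-minute walk test (2MWT)**: three IMUs
   (left foot, right foot, low back) sampled at 104 Hz, resampled to
   100 Hz, from which gait events and a four-family feature catalog
   (spatiotemporal, frequency, complexity, asymmetry) are extracted;
2. **multi-day daily-life wear**: a single acceleration-only calf sensor
   at 52 Hz, split into 10 s epochs, classified (gait / non-gait /
   off-body), step-counted, and turned into per-epoch gait speed by
   zero-velocity-update (ZUPT) double integration of the
   anterior-posterior linear acceleration over swing phases —

and the statistical stages that connect them: correlation pruning
(|r| > 0.95), Kaiser-Meyer-Olkin sampling adequacy, z-scoring, PCA with
Kaiser retention (eigenvalue > 1) and fixed-loading projection, a
test-retest reliability panel (ICC(2,1) with F-based 95% CI,
SEM, MDC = 1.96·√2·SEM, RMSE), and linear mixed models
`outcome ~ gait speed + (1 | subject)` with forward selection of principal
components as **confounders** (≥ 10% change of the gait-speed coefficient)
or **effect modifiers** (speed × component interaction, p < 0.05),
compared via nRMSE / AIC / BIC.

Because raw cohort data of this kind are rarely shareable, the package
ships a first-class **synthetic-data module** with exact ground truth:
periodic bipedal gait signals with controllable stride time, stride
length, speed, asymmetry and variability; daily-life activity timelines
mixing gait, sedentary, standing and off-body bouts; and longitudinal
cohorts with a dominant latent walking-capacity factor plus planted
confounding and effect-modification paths. Every processing stage is
validated by parameter recovery against that truth, and the core numerics
(KMO, PCA, ICC) are tested against independent brute-force oracles.

## Worked example

Simulate half an hour of daily-life wear at a true gait speed of 1.0 m/s
and recover the walking-ability measures:

```r
library(strollpipe)
tl  <- default_timeline(hours = 0.5, gait_truth = gait_truth(gait_speed = 1.0))
day <- generate_daily_recording(tl, noise_sd = 0.3, seed = 1)
process_daily_recording(day$recording)$summary
#>   day avg_speed_mps max_speed_mps steps wear_h valid
#> 1   0         0.988          1.03   690    0.5 FALSE
```

The estimated daily average speed (0.988 m/s) recovers the true 1.0 m/s
within 1.2%; the step count of 690 matches the 690 steps the timeline
truly contains (45 gait epochs at stride time 1.3 s); the day is marked
invalid because half an hour of wear is far below the 8-hour validity
threshold.

Run the full statistical chain on a synthetic longitudinal cohort
(20 subjects × 3 sessions):

```r
coh <- generate_cohort(cohort_spec(n_subjects = 20,
                                   sessions_per_subject = 3, seed = 1))
res <- run_pipeline(coh$features, coh$outcomes)
res
#> <pipeline_result>
#>   pruned 0 feature(s); overall KMO 0.91
#>   PCA: 3 component(s), 86.7% variance
#>   avg_speed: definitive model keeps {}
#>   max_speed: definitive model keeps {}
#>   steps: definitive model keeps {}

res$models$avg_speed$comparison
#>             model  nrmse     aic    bic
#> 1 gait_speed_only 0.1047 -120.87 -112.5
#> 2      definitive 0.1047 -120.87 -112.5
#> 3         pc_only 0.1281  -98.87  -88.4
```

Three components pass the Kaiser criterion (the three planted latent
factors), the first being the gait-speed-like capacity factor. The
dominant component is excluded from candidacy by the |r| ≥ 0.9
collinearity screen against 2MWT gait speed, the remaining components are
neither confounders nor effect modifiers here, and the components-only
model performs comparably to (slightly worse than) the gait-speed-only
model — the qualitative pattern this analysis design probes for. Planted
confounders and modifiers in `cohort_spec()` are recovered at
documented rates (see the selection-calibration quantities below).

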