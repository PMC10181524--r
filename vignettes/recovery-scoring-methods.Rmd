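---
title: "Modelling continuous postoperative recovery from wearable streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous postoperative recovery from wearable streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postoprecovery)
```

## The problem

After major abdominal surgery, patients recover along very different
trajectories, yet recovery itself is never measured directly: wards rely on
sparse spot checks and subjective judgement, and most models predict single
events (discharge, complication, mortality) rather than the day-by-day state
of the patient. This package models *continuous* recovery: one score per
patient per post-operative day, learned from two wearable devices — a chest
patch recording heart rate (HR, 8-s storage), respiration rate (RR, 1-s),
activity level and posture for 14 days, and a wrist band recording HR,
inter-beat intervals, steps, walking speed, activity counts, active/sedentary
classification and energy expenditure for 21 days, in hospital and at home.

Because no per-day ground truth of "how recovered" a patient is exists, the
training target is *engineered* from the two events that are reliably
recorded — discharge and complications — and the model then learns to
reproduce that target from sensor-derived daily features. Since the clinical
recordings behind such studies are restricted, the package ships a synthetic
cohort and stream generator whose statistical structure is driven by a
latent daily recovery state, so every stage is testable end to end.

## The reference recovery profile

The engineered target assumes recovery improves fastest in the first days
and then converges to a plateau, i.e. an exponential trend anchored at three
clinically interpretable points: 1.0 on the day of surgery (start of
recovery), 1.8 on the day of discharge (discharged but not fully recovered),
and 2.0 as the asymptote (fully recovered). The minimal curve through these
anchors is

$$R(t) \;=\; 2 - e^{-kt}, \qquad k = \frac{\log 5}{\mathrm{LOS}},$$

since $R(0)=1$ and $R(\mathrm{LOS}) = 2 - e^{-\log 5} = 1.8$. Only the
anchors are contractual — any monotone exponential through them would encode
the same clinical statement — and the profile continues past discharge
toward the plateau, because recovery continues at home.

Complications pull the profile down by an amount tied to their Clavien–Dindo
(CD) severity grade: 0.02 for CD 1–2, 0.04 for CD 3, 0.06 for CD 4. The
decrease *anticipates* the recorded event day — by two days for CD 4 and one
day otherwise — reflecting that severe complications are expected to be
physiologically detectable before they are diagnosed. Design choices where
the anchors alone do not decide the shape:

* **Ramp shape.** The deficit grows linearly across the anticipation window
  and reaches its full magnitude exactly on the event day. The profile is
  already strictly below baseline on the first day of the window
  (`event − lead`), which is what "decreasing two days before" means
  operationally.
* **After the event.** The deficit decays at the profile's own rate $k$, so
  the score resumes exponential convergence to the plateau from the dropped
  value; late complications still end near 2.0.
* **Multiple events** add their deficits — the simplest composable rule.
* **CD 5** (death) has no meaningful drop magnitude; the profile is
  truncated at the event day.
* Early severe complications may push the score below 1.0; that is
  intentional, not clamped.

```{r anchors}
p <- base_profile(los = 10)
round(p$score[p$day %in% c(0, 5, 10, 21)], 4)  # 1.0 ... 1.8 ... toward 2.0
pd <- apply_drops(p, list(list(day = 8, cd_grade = 4)))
round((p$score - pd$score)[p$day %in% 5:10], 4)  # ramp to 0.06, then decay
```

## The synthetic cohort and streams

`generate_cohort()` samples demographics, LOS, complications and
readmissions with marginals emulating a 125-patient major abdominal cancer
surgery cohort: ~46% female, six surgery strata, about one third of patients
with 1–3 complications, log-normal LOS with median 8 days (the median that
later defines the fast/slow group threshold) and mean near 11.

`generate_streams()` turns a patient's reference profile into raw channels.
The latent daily score $s$ drives every recovery-linked signal linearly,
with additive Gaussian noise per channel:

| signal | mapping (per unit of $s-1$) | default |
|---|---|---|
| daily steps | `effect$steps` | 2500 steps |
| upright hours | `effect$upright` | 8 h |
| hours walking | `effect$walk_hours` | 0.5 h |
| circadian day–night HR amplitude | `circ_base + circ` | 2 + 8 bpm |
| resting HR | `hr_rest_base − hr_rest` | 80 − 10 bpm |
| post-exercise HR decay rate | `hrr_rate_base + hrr_rate` | 0.001 + 0.006 s⁻¹ |

Within a day the patient is upright from 09:00 for a recovery-dependent
number of hours, walks during the first part of that block, and — once
$s$ exceeds `activity_onset` (1.25) — performs two exercise bouts whose HR
ramps to 80% of the age-predicted maximum ($220-\mathrm{age}$) over four
minutes and then decays exponentially at the recovery-dependent rate, which
is what makes 1- and 2-minute heart-rate recovery (HRR-1/HRR-2) computable
and monotone in recovery. Early post-operative days therefore have *no*
bouts, and HRR features are legitimately missing ("inactive") exactly as in
real feature frames. Respiration is stationary noise around 16 breaths/min
and deliberately carries **no** recovery signal: the RR channels are the
generator's designed uninformative fillers, used to check that the learner
ranks them last. Inter-beat intervals are synthesized as $60000/\mathrm{HR}$
plus short-term jitter so HRV summaries are nontrivial. Wrist channels lose
one contiguous 30–90-minute block per day (charging), chest channels none.

With all noise levels zero, each recovery-linked daily summary is a
*strictly increasing* function of the latent score — the property the
parameter-recovery tests exploit. An anticipatory physiological dip before
complications needs no extra machinery: the latent driver is the reference
profile itself, which already decreases ahead of events.

What the generator does **not** emulate: raw PPG/accelerometer waveforms,
sensor artefacts and beat-detection errors, between-patient heterogeneity in
the latent-to-signal gains, or activity rhythms unrelated to recovery
(visits, physiotherapy schedules). Passing tests therefore demonstrate that
the pipeline recovers a latent state *when the features genuinely encode
it*, not that these effect sizes are clinically attained.

## Daily features

`extract_features()` computes 36 daily features per patient-day — HR and RR
mean/variance, resting HR (mean of the lowest decile of HR during inactive
periods), circadian day–night difference and hourly peak–nadir amplitude,
time-domain HRV (SDNN, RMSSD, pNN50), Welch-based band powers (VLF/LF/HF and
LF/HF), exercise-bout detection at 70% of $220-\mathrm{age}$ with HRR-1,
HRR-2 and HRR-time, HR by context (walking/upright/sedentary,
active/inactive, activity-count split at 2000, activity-level split at 3),
and activity totals — plus a `delta_` column per feature (today minus
yesterday; missing on each patient's first day and whenever either operand
is missing). RR comes from the chest (more reliable at the ribcage),
HR-derived features from the wrist (longer coverage).

Numerical conventions, fixed once and tested:

* **Variance/SDNN** use the population convention (divide by $n$).
* **Day/night windows**: 08:00–22:00 and 00:00–06:00 local clock.
* **HRV bands**: VLF 0.0033–0.04 Hz, LF 0.04–0.15 Hz, HF 0.15–0.4 Hz (the
  standard task-force bands); IBI series cubic-spline-resampled to an even
  grid (4 Hz default) and fed to Welch's averaged periodogram (Hann window,
  5-min segments, 50% overlap). The PSD routine is written in the package
  because the installed signal-processing stack lacks one; it is verified
  against direct periodograms of pure sinusoidal modulations.
* **Missingness**: a daily feature is missing when under 30% of the day's
  expected samples exist, when its context never occurs (e.g. no walking),
  or when no qualifying bout occurred (HRR). Missing values propagate to
  deltas but never to neighbouring days.
* **Bouts**: contiguous runs above threshold, merged across gaps < 5 min,
  runs < 30 s discarded; the bout peak is the maximum sample; HRR-1/2 by
  linear interpolation at peak + 60/120 s; HRR-time is the first sample
  at least 10 bpm below the peak within 10 min.
* The Nemenyi post hoc (below) is likewise implemented in the package from
  the mean-rank/studentized-range formulas, as no post-hoc package is
  available, and is tested against brute-force computation.

## Split, model, and feature elimination

`balanced_split()` reproduces a covariate-balanced random search: draw
10,000 partitions at fraction 2/3 (train size `floor(2n/3)`, so 83/42 at
$n=125$), score each with uncorrected chi-square p-values (gender,
complication count, surgery type) and two-sample Kolmogorov–Smirnov p-values
(age, LOS), and keep the partition with the largest product of p-values.
Degenerate tables (a category absent overall, or an undefined statistic)
score a neutral $p=1$ rather than crashing a candidate.

The regressor is a gradient-boosted tree ensemble (`xgboost`), with features
standardized to zero mean and unit variance on training data only
(zero-variance features pass through unscaled), native missing-value routing
at splits, and early stopping on a held-out 10% of training *patients*.
Every patient-day is an independent sample; the model never sees patient
identity or the day index. Hyperparameters (learning rate, maximum depth)
are tuned by 5-fold cross-validation on the training set; assessment uses
10-fold CV. Folds are grouped by patient — all of a patient's days stay in
one fold — which is the stricter choice when the target is a smooth
per-patient curve; an ungrouped mode exists for comparison. Ties in the
grid search keep the first point in declared order.

`backward_eliminate()` removes the lowest-total-gain feature one at a time;
after each removal the reduced model's per-fold MSE and SRCC are compared to
the all-features model with a Friedman test followed by a Nemenyi post hoc
at $\alpha = 0.05$. Elimination stops when *either* metric first differs
significantly, returning the last non-different set (never empty). The
pipeline driver eliminates from the top-16 features by absolute Pearson
correlation with the reference score — a runtime choice; the elimination
operation itself is agnostic to how many features it starts from.

Evaluation reports MSE, Spearman rank correlation (SRCC) over all
patient-days, and the discharge error: the mean absolute difference between
predicted and reference score on each patient's discharge day.

## Clinical comparison layer

`group_profiles()` averages predicted scores per day within the short-LOS
(≤ 8 days, the training-cohort median) and long-LOS (> 8 days) groups,
with 10th/90th percentile bands (linear interpolation between order
statistics). A patient's predicted profile is classified per day as *fast*
(inside/above the short-LOS band and above the long-LOS 90th percentile),
*slow* (inside/below the long-LOS band and below the short-LOS 10th
percentile), or *indeterminate* in the overlap — an explicit
operationalization of what is a visual comparison in practice.
`discharge_readiness()` reports the first day the predicted score reaches
1.8 and flags patients below 1.8 on their actual discharge day;
`decline_flags()` marks days ending a strictly decreasing run (ties break
runs) of configurable length, the pattern that can precede complications.
`feature_frame_report()` renders the selected features per day with bout-free
days shown as "inactive" and HRR-1 below 12 bpm flagged as abnormal.

## Problem sizes and reproducibility

The cohort-scale runs (the acceptance script and `analysis/` drivers) use
125 patients with cadences thinned to one chest sample per minute, one
wrist/IBI sample per 15 s, and 1-Hz Welch resampling; daily summaries are
insensitive to this thinning because every feature is a within-day mean,
total, decile or band integral, and the unit tests exercise the
device-native 8-s/1-s cadences on short windows. A single global seed fans
out to per-stage and per-patient seeds, so cohorts, streams, splits, folds
and boosters are all individually reproducible; repeated runs are
byte-identical.

On this synthetic cohort the pipeline recovers the latent score nearly
perfectly (held-out SRCC above 0.99 at default noise; the tests require
≥ 0.95 noise-free and ≥ 0.7 at default noise). That headroom is expected:
the generator's latent-to-signal mapping is exactly the kind of structure
boosted trees represent, and real wearable data are far harder. The numbers
demonstrate correctness of the machinery, not clinical performance.

## Known limitations

* The engineered target inherits its assumptions: discharge timing also
  reflects non-physiological factors, real recovery is not smooth, and the
  drop magnitudes are design constants, not measurements.
* The generator's linear latent-to-signal mapping with shared gains across
  patients makes recovery easier to learn than in reality.
* Readmission is recorded in the cohort but has no profile mechanic.
* Alarm thresholds with confidence levels are out of scope; `decline_flags`
  is a building block, not an alarm policy.
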