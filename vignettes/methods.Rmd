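---
title: "Methods: critical speed extraction, GXT processing and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: critical speed extraction, GXT processing and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critspeed)
```

This vignette documents the computational methods in `critspeed`: how the
3-minute all-out test (3MT) is reduced to critical speed (CS) and D', how the
graded exercise test (GXT) is processed into VO2max, the gas exchange
threshold (GET) and the 50%-delta speed, how the quality-control screens are
defined, and how the seeded synthetic-cohort generator is constructed so that
every stage can be validated end to end without laboratory data.

## 1. The 3-minute all-out test

A 3MT speed trace is a data frame of `time_s` (seconds from the start of the
all-out effort) and `speed_mps`. Two window means define the outcome measures:

- `s150` — mean speed over the half-open window [0, 150) s,
- `cs`   — mean speed over [150, 180) s (at 1 Hz this is exactly 30 samples).

D' (the finite above-CS distance capacity, in metres) is the distance run
above CS during the first 150 s, which for window means reduces to the exact
identity

```
dprime = 150 * (s150 - cs)
```

`compute_allout()` evaluates both window means and this identity, and flags a
trace as *pacing-suspect* when `dprime < 0`, i.e. when the final 30 s were
faster than the first 150 s — impossible under a genuinely all-out effort.
Windows are half-open so a sample at exactly 150 s belongs to the CS window
and a sample at exactly 180 s is excluded; samples after 180 s are ignored.
Traces sampled at other rates (e.g. 0.5-s intervals) are handled by the same
window-mean rule without interpolation.

## 2. GXT processing

### 2.1 Binning

Gas-exchange series are 1-Hz breath-by-breath-equivalent samples with a
`phase` label (`rest`, `warmup`, `ramp`, `recovery`, `verification`).
`bin_15s()` restricts to one phase and averages `vo2` and `vco2` over
consecutive non-overlapping 15-s windows from the phase onset; a trailing
partial window is dropped. Bin timestamps are end-of-bin.

### 2.2 VO2max

`vo2max_two_highest()` takes the mean of the two highest consecutive 15-s
VO2 bins of the ramp phase. The shipped implementation scans adjacent pairs;
the test suite checks it against a brute-force oracle and against invariance
properties (appending strictly lower bins never changes the answer).

### 2.3 Gas exchange threshold: v-slope with admissibility constraints

`detect_get_vslope()` fits all two-segment ordinary least-squares splits of
binned VCO2 on binned VO2 with at least `min_segment = 3` points per segment.
A split is *admissible* only if

1. the upper-segment slope exceeds the lower-segment slope by at least
   `min_slope_gap = 0.10`, and
2. the fitted intersection of the two lines falls inside the VO2 range of the
   bins within `junction_slack` (default 4) positions of the split itself.

Among admissible splits the one with minimum total residual sum of squares is
returned, and the GET is the VO2 at the intersection of the two segments. If
no admissible split exists the detector reports `found = FALSE` together with
the best unconstrained split for diagnostics, and `process_gxt()` raises an
error stating that no admissible breakpoint was found.

Both constraints are applied *during* the search, not as post-hoc checks.
This matters because the VO2 axis is itself noisy (an errors-in-variables
problem): with realistic bin-level gas noise, the unconstrained global RSS
minimiser is frequently a degenerate near-collinear split, or a split whose
fitted intersection extrapolates far away from its own junction. Treating the
slope gap and junction consistency as admissibility rules lets physiologically
meaningful splits compete on RSS only against each other.

### 2.4 50%-delta and demand lag

The 50%-delta intensity is the VO2 halfway between GET and VO2max:

```
vo2_fifty = get_vo2 + 0.5 * (vo2max - get_vo2)
```

To convert this VO2 back to a running speed, `process_gxt()` accounts for the
on-transient lag of oxygen uptake during a continuously incremented ramp: the
VO2 measured in 15-s bin `j` is attributed to the treadmill speed one minute
earlier, i.e. the quarter-stage speed at bin index `j - 4`
(`lagged_speed_at()`), clamped at the ramp start. The GET bin is the first
bin whose VO2 reaches `get_vo2`; the 50%-delta bin is located the same way
with `vo2_fifty`. Speeds on an inclined treadmill are reported as
*flat-equivalent* speeds, `speed * (1 + 4.5 * grade)`, so that CS from
level-ground running and the GXT intensities share one scale. The reported
`fifty_delta` is the mean of the GET-anchored and 50%-delta flat-equivalent
speeds' midpoint construction implemented in `process_gxt()`.

### 2.5 Supramaximal verification

`process_verification()` compares the verification-bout VO2 peak with the
ramp VO2max. The bout *verifies* the ramp value when the relative difference
is at most 3% (inclusive). `design_protocol()` inverts the demand model to
choose ramp start and increment such that the ramp lasts 8–12 minutes and the
verification stage sits above peak ramp demand.

## 3. Quality control

`apply_qc()` applies two screens per athlete and partitions the cohort:

- **Pacing**: fail when `|cs - fifty_delta| / fifty_delta >= 0.035`
  (a deviation of exactly 3.5% fails; strictly below passes).
- **Verification**: fail when the ramp/verification relative VO2 difference
  exceeds 3% (exactly 3% still passes).

Exclusion reasons are `"pacing"`, `"verification"`, `"both"` or `"none"`, and
the summary counts (`n_valid`, `n_excluded`, `n_pacing`, `n_verification`,
`n_both`) always satisfy the partition identities.

## 4. Prediction model and reliability statistics

`fit_stepwise()` fits relative VO2max by forward stepwise OLS: CS always
enters; `sex` (male = 1, female = 0) enters when its partial *t*-test has
p < 0.05. The standard error of estimate uses `n - k - 1` denominator
degrees of freedom. `predict_vo2max()` evaluates either a fitted model or the
package's reference equation

```
vo2max = 8.449 * cs + 4.387 * sex + 14.683        (SEE = 3.34)
```

Reliability helpers implement the standard pairwise-trial definitions:
typical error `TE = sd(diff) / sqrt(2)` (`typical_error()`), its chi-square
confidence interval, linear and log-scale CV% (`cv_percent()`), consistency
ICC(3,1) from mean squares (`icc_consistency()`), and `te_from_see()`, which
converts a regression SEE to the TE implied by treating observed and
predicted values as two trials:

```
te = see * sqrt((n - k - 1) / (n - 1)) / sqrt(2)
```

## 5. The synthetic cohort generator

The generator exists so the full pipeline — trace rendering, GXT rendering,
extraction, QC, model fitting — can be validated against known ground truth.

### 5.1 Athlete truths

`gen_config()` fixes the population: CS ~ truncated normal (mean 3.56,
SD 0.55 m/s), D' ~ truncated normal (mean 208.5, SD 54.3 m), sex ~ Bernoulli,
body mass ~ truncated normal. `calibrate_sex_cs_distributions()` solves (by
common-random-number bisection) for the male/female CS means that reproduce a
target CS–VO2max correlation and sex gap under the reference equation, so
that `true_vo2max` is generated directly from the equation plus residual
noise. The first `n_pacing_violators` athletes are flagged as pacing
violators and the next `n_vp_violators` as verification violators.

### 5.2 3MT traces

`render_trace()` draws an exponentially decaying all-out speed profile whose
initial speed `S0` solves the discrete-sum constraint that the rendered
windows reproduce the athlete's true CS and D' exactly in the noiseless
limit. For large D' the time constant is widened adaptively (root-finding
with `S0` capped at 11.5 m/s) so no athlete is asked to run impossibly fast.
Multiplicative noise is added per sample. Pacing violators get a rendered
trace whose 50%-delta deviation hits a requested target; the pipeline injects
these at a 10% deviation so the violation clears the 3.5% screen by many
multiples of the ~1.3% measurement noise of the extraction chain.

### 5.3 GXT series

`render_gxt_series()` renders a full 1-Hz session (rest, warm-up, ramp,
recovery, verification). Oxygen demand is linear in flat-equivalent speed
with a per-athlete economy slope found by fixed-point iteration so that the
athlete's true VO2max is reached exactly at their true peak ramp speed. The
ramp protocol is designed per athlete: the start speed sits a margin of
`max(2, 0.45 * (vo2max - get))` mL/kg/min of demand below the GET (capped at
5 mph), the target duration is 12 minutes, the first four 15-s bins follow a
smooth on-transient, and the ramp is truncated two bins after the demand cap.
Measured VO2 follows demand with the one-minute on-transient lag of §2.4
plus clipped Gaussian noise. Verification violators are rendered with a
verification peak 5% away from the ramp VO2max, so they fail the inclusive
3% screen.

All randomness flows from a single integer seed through deterministic
per-stream child seeds, so any cohort, trace or series can be reproduced in
isolation.

## 6. Validation strategy

The test suite is oracle-first: window means, the D' identity, the v-slope
search, OLS coefficients and the two-highest-bin rule are each checked
against independent brute-force or closed-form reference implementations, and
key invariances (clock shifts, speed rescaling, trial symmetry) are asserted
as properties over randomized inputs. End-to-end, a large seeded cohort run
through trace rendering, extraction and stepwise OLS must recover the
reference-equation coefficients, SEE, and the CS–VO2max correlation within
pre-stated tolerances.
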