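# critspeed

Critical speed field testing and VO2max prediction in R.

`critspeed` implements a complete analysis pipeline for running-based
critical speed (CS) field testing:

- **3-minute all-out test (3MT)**: extracts CS (mean speed of the final
  30 s), S150s (mean speed of the first 150 s) and the finite above-CS
  distance capacity D' = 150·(S150s − CS) from a speed trace, flagging
  pacing-suspect efforts (negative D').
- **Graded exercise test (GXT) processing**: 15-s gas-exchange binning,
  VO2max as the mean of the two highest consecutive bins, gas exchange
  threshold (GET) by an admissibility-constrained v-slope breakpoint search,
  and the 50%-delta running speed (halfway between GET and VO2max) with a
  one-minute on-transient demand lag and flat-equivalent speed conversion.
- **Supramaximal verification**: accepts the ramp VO2max when the
  verification-bout peak agrees within 3% (inclusive).
- **Quality control**: excludes athletes whose CS deviates from the
  50%-delta speed by ≥ 3.5% (pacing screen) or whose verification bout
  fails, with per-athlete reasons and partition-consistent summary counts.
- **Prediction model**: forward stepwise OLS of relative VO2max on CS
  (forced) and sex (enters at p < 0.05), plus the package's reference
  equation `VO2max = 8.449·CS + 4.387·sex + 14.683` (SEE 3.34 mL/kg/min).
- **Reliability statistics**: typical error with chi-square CI, CV%
  (linear and log), consistency ICC(3,1), Pearson r, paired t, and the
  SEE→TE conversion `te_from_see()`.
- **Seeded synthetic-cohort generator**: renders ground-truth athletes,
  1-Hz 3MT speed traces and full GXT gas-exchange sessions (with optional
  pacing and verification violators) so the entire pipeline can be
  validated end to end without laboratory data.

See `vignettes/methods.Rmd` for the full methods description.

## Worked example

A seeded 37-athlete cohort with 9 injected pacing violators and 3
verification violators, run through the whole pipeline:

```r
library(critspeed)

cfg <- gen_config(n_athletes = 37, n_pacing_violators = 9,
                  n_vp_violators = 3, seed = 42)
rep <- run_full(cfg)
print(rep)
```

```
Field-test analysis run
  cohort: 37 in, 25 valid, 12 excluded (9 pacing, 3 verification, 0 both)
VO2max prediction model (cs + sex)
  VO2max = 9.498 * CS + 6.936 * sex + 9.103
  SEE = 3.504 mL/kg/min, n = 25, R2 = 0.804
Reliability report (n = 25 pairs)
  TE   = 2.372 (95% CI 1.852-3.300)
  CV%  = 5.08
  ICC  = 0.891
  r    = 0.896 (p = 1.34e-09)
  t    = -0.000 (p = 1)
```

(At n = 25 the fitted coefficients are sample estimates with wide standard
errors; at n = 50,000 the same pipeline recovers the reference coefficients
to within a few hundredths — see the acceptance script below.)

Per-athlete results, including exclusion reasons:

```r
head(rep$cohort[, c("id", "cs", "dprime", "vo2max_ramp",
                    "fifty_delta", "predicted_vo2max", "reason")], 4)
```

```
  id       cs   dprime vo2max_ramp fifty_delta predicted_vo2max reason
1  1 3.098973 89.30422    37.43663    2.771345         38.53689 pacing
2  2 3.941770 83.52183    49.73587    3.613201         53.47797 pacing
3  3 4.131324 86.69013    47.03703    3.665897         55.27836 pacing
4  4 4.776788 91.47530    58.35778    4.316439         61.40900 pacing
```

Single building blocks work standalone. A rendered 3MT trace for an athlete
with true CS 3.6 m/s and true D' 210 m round-trips through the extractor:

```r
tr <- render_allout_trace(list(id = 1L, true_cs = 3.6, true_dprime = 210),
                          gen_config(seed = 1))
compute_allout(tr)
```

```
3-minute all-out test result
  S150s: 5.010 m/s
  CS:    3.597 m/s
  D':    212.1 m
```

And the reference prediction equation:

```r
predict_vo2max(3.56, sex = 1)
#> [1] 49.14844
```

## Reproduction

Run the test suite against the installed package:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "critspeed", load_package = "installed")'
```

The suite (512 assertions) includes per-module unit tests, randomized
property tests against brute-force oracles (window means, v-slope search,
OLS normal equations, two-highest-bin rule, reliability invariances), and
`tests/testthat/test-acceptance.R` with one block per acceptance criterion.

Run the acceptance script (writes JSON; all randomness derives from
`--seed`):

```sh
Rscript scripts/acceptance.R --seed 7 --out results/acceptance.json
```

which reports, for example:

```
  t2: value = 14.683, n = 1        # Eq. intercept at CS = 0, female
  t4: value = 8.46875, n = 50000   # recovered CS coefficient
  t5: value = 4.31337, n = 50000   # recovered sex coefficient
  t6: value = 3.32583, n = 50000   # recovered SEE
  t7: value = 0.819402, n = 10000  # extracted-CS vs VO2max Pearson r
```

t4–t6 come from a 50,000-athlete end-to-end run: athlete truths are
sampled, 3MT traces rendered with measurement noise, CS extracted from each
trace, and the stepwise model refit on the extracted values; t7 is the
Pearson correlation between extracted CS and observed VO2max on the first
10,000 athletes. The whole script runs in a few seconds on one CPU.

## License

MIT (see `LICENSE`).
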