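# smoltsar

Carryover-effects analysis of smolt-to-adult survival for Snake River
spring/summer Chinook salmon.

Juvenile Chinook either migrate in-river through the Columbia/Snake
hydropower system or are barged ("transported") around it. Transportation
raises hydrosystem survival to ~100%, but the altered freshwater experience
can carry over into *lower* survival after release. This package implements
the full statistical pipeline used to quantify that trade-off from
PIT-tag-style cohort data:

1. **Synthetic cohorts** (`generate_environment()`, `generate_cohort()`):
   tag records and daily river/ocean series with the exact statistical
   structure the model assumes, from known parameters — the test surface
   for everything downstream.
2. **Covariate engineering** (`build_design_table()` and friends): DOY
   100–180 window filter, right-aligned 7-day rolling means, OLS
   residualization (temperature on timing; estuary/plume metrics on flow),
   binary PDO phase index `I` (1 when the May–September mean PDO < 0), and
   standardization.
3. **Survival model** (`fit_glmm()`): per-fish Bernoulli outcomes with

   ```
   logit(p_ij) = b0 + b0j + (b1 + b1j) d + (b2 + b2j) d^2 + sum_k bk x_k,
   b.j ~ independent N(0, sigma.^2) by outmigration year
   ```

   fitted by Laplace-approximated maximum likelihood (own implementation;
   validated in-suite against IRLS, adaptive Gauss–Hermite quadrature and
   lme4), with AICc.
4. **Model space and averaging** (`enumerate_models()`, `model_average()`):
   the constrained all-subsets space — 2 timing sets × subsets of {t, f} ×
   subsets of {T, U, E, V} × {I} × 3 random structures = **768 models**,
   cumulative groupings MT/MT-FW/MT-FW-M/MT-FW-M-C of sizes 6/18/360/384 —
   ΔAICc weights, the 99% confidence set, conditional averaged coefficients
   with unconditional SEs and relative importance, and the per-grouping
   weight partition.
5. **Differential delayed mortality** (`simulate_D()`): parametric draws
   from each confidence-set model's MVN sampling distribution, weighted on
   the probability scale, ratioed into `D = S_transport / S_run_of_river`
   per day and cool/warm PDO phase, against the 1.0 and 0.5 thresholds.

## Worked example

A reduced space (timing × {t, f} × {I} × 3 random structures, 48 models) on
a synthetic cohort whose truth has a strong cool-ocean benefit
(`beta_I = 0.9`) and a negative timing slope:

```r
library(smoltsar)
env    <- generate_environment(n_years = 8, cool_year_fraction = 0.5, seed = 1)
truth  <- true_parameters(beta_0 = qlogis(0.02), beta_d = -0.3, beta_I = 0.9,
                          sigma_0 = 0.2, n_years = 8, fish_per_year = 1250)
cohort <- generate_cohort(truth, env, seed = 2)
space  <- enumerate_models(freshwater = c("t", "f"), marine = character(0),
                           climate = "I")
avg    <- model_average(fit_model_space(space, cohort$design))
avg
```

```
<averaging_result> 48 models, 32 in the 99% confidence set
  grouping n_set n_all min_delta_set max_delta_set ... weight_set weight_all
        MT     3     6      7.148778      9.150388 ... 0.01076612 0.01276702
     MT-FW     5    18      6.966376      9.139480 ... 0.01654145 0.02379514
 MT-FW-M-C    24    24      0.000000      9.151907 ... 0.96343783 0.96343783

Model-averaged coefficients (conditional):
   covariate averaged_beta unconditional_se ... relative_importance significance_p
 (Intercept)      -3.67003          0.13944 ...              1.0000     1.115e-152
           d      -0.33884          0.52124 ...              1.0000      5.157e-01
          d2       0.07297          1.00664 ...              0.2683      9.422e-01
           t       0.05633          0.06334 ...              0.3553      3.738e-01
           f      -0.01702          0.07740 ...              0.2716      8.259e-01
           I       0.66798          0.16961 ...              0.9724      8.204e-05
```

Reading this: the climate grouping carries 96% of the total weight (the
generating truth has a strong `I` effect), the averaged `I` coefficient
0.67 ± 0.17 recovers the true 0.9 within sampling error and is the only
clearly significant covariate, and the timing slope −0.34 matches the true
−0.3. `relative_importance` is the summed confidence-set weight of models
containing each covariate.

Simulating D between a transported and a run-of-river fit then follows

```r
grid <- scenario_covariates(cohort$design, "cool")   # phase-average covariates
ds   <- simulate_D(avg_transport, avg_runofriver, grid,
                   n_draws = 1000, seed = 3)
ds$summary   # per-day median D, 95% band, fractions above 1 and 0.5
```

(identical inputs on both sides give `median D range: 1 - 1` exactly — one
of the suite's identities).

## Further reading

`vignettes/smoltsar-methods.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, numerical edge-case policy, and known
limitations.
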