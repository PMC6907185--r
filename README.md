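# lifelogpvar

Panel vector autoregression for detecting early warning signs of
depression recurrence in lifelog data.

Patients in remission from recurrent major depression can be followed for
a year with a smartphone diary and a wearable: daily noon-to-noon sleep,
meals, sitting-idly time and UV exposure, weekly K6 distress self-reports,
monthly PHQ-9 interviews. Because lifestyle and mood feed back on each
other, the package models the five weekly series jointly as a panel VAR
with patient fixed effects,

    Y_it = Y_it-1 A1 + ... + Y_it-p Ap + X_it B + v_i + e_it,

estimated by one-step GMM on forward-orthogonal-deviation (Helmert)
transformed data with lagged-level instruments and patient-clustered
standard errors. Lag order is selected by the multivariate coefficient of
determination CD = 1 − det(Σ̂_e)/det(Σ̂_Y) among stable fits (all companion
eigenvalues inside the unit circle). A positive coefficient from the
long-sleep dummy at lag 3 into the distress equation is the early-warning
signal: an unusually long-sleep week predicts higher distress three weeks
later. Coefficients on the ln(K6+1) response scale back-transform to K6
points via K6' = exp(β)·(K6+1) − 1.

The package covers the full analysis chain: K6/PHQ-9 scoring
(`score_k6()`, `score_phq9()`), a seeded synthetic-cohort generator
(`simulate_cohort()`) because no patient data can ship, weekly feature
engineering (`build_panel()`), Little's MCAR test with a
covariate-dependent-missingness variant and weighted regression
imputation (`little_mcar_test()`, `cdm_test()`, `impute_panel()`), a
two-stage variable screen (`screen_candidates()`), the estimator
(`pvar()`, `select_lag()`) and effect reporting (`implied_k6()`,
`run_pipeline()`).

## Worked example

```r
library(lifelogpvar)

# simulate the default synthetic cohort (89 patients, 52 weeks, a true
# +0.25 lag-3 long-sleep effect), run the full pipeline, fit up to lag 4
res <- run_pipeline(cohort_config(), out_dir = "pvar-out", p_max = 4)

res$mcar
#> Little's MCAR test: chi-square = 5.781, df = 2, p-value = 0.05555 (2 patterns)

res$lag_selection$table
#>   p        CD max_modulus stable
#> 1 1 0.2623320   0.3610892   TRUE
#> 2 2 0.3092119   0.5686455   TRUE
#> 3 3 0.3354653   0.6270038   TRUE
#> 4 4 0.3362948   0.6738427   TRUE

res$fit
#> Panel VAR(4) fitted by GMM on forward orthogonal deviations
#> Endogenous: y, lunch_z, uv_logz, long_sleep, sit_dummy
#> Exogenous:  season, pseudo_pos
#> Panels: 89   Avg weeks per panel: 46.03   Observations: 4097
#> CD: 0.33629   Max eigenvalue modulus: 0.6738   Stable: TRUE

b <- res$fit$A[[3]]["long_sleep", "y"]   # 0.253 (SE 0.019)
implied_k6(b, 5)
#> [1] 6.728
```

The missingness test does not reject MCAR conditional on covariates (the
simulated K6 lapses depend only on gender and education); the CD table
levels off after lag 3 and every candidate is stable; and the fitted
lag-3 long-sleep coefficient (0.253, truth 0.25) implies that a patient
sitting at K6 = 5 is expected near K6 ≈ 6.7 three weeks after a
long-sleep week. `summary(res$fit)` prints the full coefficient table
with standard errors in parentheses and significance stars at
0.01/0.05/0.1; `plot(res$fit)` draws the companion eigenvalues against
the unit circle.

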