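---
title: "Detecting early warning signs of depression recurrence from lifelog panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early warning signs of depression recurrence from lifelog panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifelogpvar)
```

## The problem

Depression recurs. Patients in remission who are followed with smartphone
diaries and wearables produce *lifelog panels*: daily sleep, meal, activity
and UV-exposure records, weekly K6 distress self-reports, and monthly
PHQ-9 interviews. The scientific question is whether week-to-week changes
in lifestyle — long sleep especially — *precede* rises in distress, so
that an approaching relapse can be flagged weeks ahead.

Because the relationships are bidirectional (poor sleep worsens mood, low
mood disrupts sleep), single-equation survival or regression models are
inadequate. The package therefore estimates a **panel vector
autoregression (PVAR)** with patient fixed effects,

$$Y_{it} = Y_{it-1} A_1 + Y_{it-2} A_2 + \dots + Y_{it-p} A_p + X_{it} B + v_i + e_{it},$$

where $Y_{it}$ is the $1 \times 5$ vector of weekly endogenous variables —
the transformed distress response, standardised lunch-skip count,
log-standardised UV dose, the long-sleep dummy, and the sitting-idly
dummy — $X_{it}$ holds the exogenous December/January and pseudo-positive
dummies, $v_i$ is a patient fixed effect per equation, and $e_{it}$ is an
idiosyncratic error. The off-diagonal elements of the lag matrices $A_j$
are the early-warning signals: a positive entry from the long-sleep dummy
at lag 3 into the response equation says that an unusually long-sleep week
predicts higher distress three weeks later.

## Variable construction

* **Response.** $y = \ln(\mathrm{K6}+1)/\sqrt{\mathrm{episodes}}$. The log
  tames the right skew of K6 totals (0–24); dividing by the square root of
  the number of prior depressive episodes levels the response across
  patients whose reporting rises with episode history.
* **Sleep days.** A day's sleep is measured noon-to-noon (episodes
  spanning noon are split, `sleep_day_hours()`). A day is a *long-sleep
  day* when its hours exceed the trailing 7-day mean plus one sample SD,
  a *short-sleep day* below mean minus SD. The trailing window excludes
  the index day — a window containing the day itself dampens the rule —
  and with fewer than 7 prior days the flags are missing, not zero. The
  weekly dummy applies the any-day rule: Table-level prevalences near 4%
  are only compatible with a 0/1 weekly variable if a single flagged day
  suffices.
* **Lunch and UV.** The weekly lunch-skip count (0–7) and the weekly mean
  UV dose are standardised *within patient* (mean 0, SD 1 over that
  patient's weeks) to absorb heterogeneity in eating habits and outdoor
  time. For UV the order of operations is $\ln(\bar{uv}_w + 1)$ first,
  then standardisation: the reverse order ("log of the standardised
  value") is undefined for non-positive z-scores, so log-then-standardise
  is the only well-defined reading. UV days on which the wearable
  collected fewer than 80% of the 1440 daily minutes (1152) are treated
  as missing before weekly averaging.
* **Sitting idly.** The weekly dummy is 1 when the week's mean daily
  sitting-idly hours exceeds the patient's study-period mean plus one SD,
  mirroring the long-sleep construction (the threshold multiplier is an
  argument). Any mean-plus-SD rule on a unimodal weekly distribution
  flags its own extremes, so this dummy is intrinsically noisier than the
  sleep dummies.
* **Exogenous dummies.** Seasonality is a December/January indicator. The
  *pseudo-positive* dummy (K6 > 9 while PHQ-9 < 5, both strict) marks
  weeks where the self-report alarms but the interview does not — a false
  alarm of recurrence; the monthly PHQ-9 is carried forward within its
  4-week block.
* **Weeks** are 7-day blocks from each patient's entry date, not calendar
  weeks, so the analytic weight (weeks from entry) is well defined from
  week 1.

## Missingness

Weekly K6 self-reports lapse. `little_mcar_test()` implements the
chi-square test of MCAR: the observed-data mean and covariance are
estimated by EM under multivariate normality (convergence when the
relative change of the observed-data log-likelihood falls below 1e-6,
at most 500 iterations), and the statistic sums, over missingness
patterns, the Mahalanobis distances between each pattern's observed means
and the grand estimates. `cdm_test()` conditions the test on fully
observed baseline covariates by residualising each tested variable on
them first, so missingness that is driven purely by a covariate (MAR of
the covariate-dependent kind) no longer triggers rejection.

Missing K6, UV and lunch values are then filled by **single weighted
regression imputation** (`impute_panel()`): the K6 model regresses the
total on the carried PHQ-9 score, weekly sleep summaries, the long/short
sleep dummies and baseline demographics, with the weeks-from-entry
analytic weight (inversely proportional to the observation variance in a
lengthening diary); predictions are clipped to [0, 24]. Multiple
imputation would propagate uncertainty better but cannot feed a single
GMM fit; the SD underestimation of single imputation is a known,
accepted limitation here.

Two design points deserve emphasis:

* The imputation model **includes lags 1–3 of the sleep dummies as
  auxiliary variables** (argument `aux_lags`). An imputation model that
  omits regressors of the analysis model biases their coefficients toward
  zero; with ~15% of weeks imputed the lag-3 long-sleep coefficient loses
  about a sixth of its magnitude without the auxiliaries.
* Observed cells are never overwritten, every filled cell is flagged, and
  rows whose predictors are missing stay missing (they only break the
  estimation spells at panel edges).

## Estimation

Fixed effects in a dynamic panel bias least squares even with many
patients, so estimation is GMM on **forward orthogonal deviations**
(`fod()`): each observation is replaced by its scaled deviation from the
mean of its *future* observations,
$\tilde{x}_t = \sqrt{T_t/(T_t+1)}\,(x_t - \bar{x}_{>t})$. This
annihilates $v_i$ exactly, keeps transformed errors white when the
originals are, and — unlike first differencing — does not induce serial
correlation. The transformed system is estimated equation by equation by
one-step GMM with weighting matrix $(Z'Z)^{-1}$ and patient-clustered
standard errors.

**Instruments** are untransformed lagged levels of the endogenous
variables in collapsed form (one column per lag and variable), zero-filled
where a lag reaches before a patient's spell — the standard
unbalanced-panel convention that keeps every usable observation. Under
serially uncorrelated errors any level dated $t-1$ or earlier is valid
for the FOD equation at $t$; the package default uses lags
$1..p{+}1$ (`inst_start = 1`, `inst_depth = p + 1`). Starting at lag 1 is
deliberate: deeper starting lags are also valid but much weaker — for a
weakly autocorrelated binary regressor such as the long-sleep dummy,
instruments starting at lag $p{+}1$ are nearly uncorrelated with the
transformed regressor and the coefficient of interest becomes practically
unidentified. Both settings are arguments, so the conservative deep-lag
configuration remains available.

Note that while the FOD transform removes patient constants *exactly*
(tested to machine precision), the instrument levels shift with any added
constant, so the finite-sample GMM estimate is only asymptotically
invariant — the fixed effect is handled by the transform, not by the
instruments.

**Lag order** is chosen by the multivariate coefficient of determination
$CD = 1 - \det(\hat\Sigma_e)/\det(\hat\Sigma_Y)$, computed for
$p = 1..p_{\max}$ on the common estimation sample (all candidate fits
drop the first $p_{\max}$ weeks, so their CDs are comparable), keeping
the stable order with the largest CD. **Stability** requires all
eigenvalues of the $kp \times kp$ companion matrix strictly inside the
unit circle (numerically, modulus < 1 − 1e-8); an unstable fit
invalidates the GMM specification and `select_lag()` refuses it.

**Effect size.** A coefficient $\beta$ on the $\ln(\mathrm{K6}+1)$ scale
back-transforms through `implied_k6()`:
$\mathrm{K6}' = e^{\beta}(\mathrm{K6}+1) - 1$ (the episode divisor cancels
on the single-episode reporting scale). A lag-3 long-sleep coefficient of
0.172 moves a patient from K6 = 5 to 6.126 three weeks later; 0.271 moves
5 to 6.868.

## The synthetic cohort

No patient data ship with the package; `simulate_cohort()` generates a
cohort with the statistical structure the analysis assumes, and its
defaults *are* the study conditions: 89 patients, 52 weeks, weekly K6
with covariate-dependent missingness (logistic in gender and education,
marginal ≈ 15%, inside the realistic 10–30% band), monthly PHQ-9, daily
sleep averaging 8.0 h, weekly long/short-sleep prevalence 4%, lunch-skip
counts with mean ≈ 2.5 and strong between-patient heterogeneity
(Beta-distributed propensities), lognormal UV (weekly mean ≈ 16, SD ≈ 13)
with 10% daily device dropout, and a **true lag-3 long-sleep coefficient
of +0.25** in the response equation — the signal every end-to-end test
must recover.

Design choices:

* The five weekly endogenous series follow the VAR directly at the weekly
  level (the estimator consumes weekly data); daily records are then
  disaggregated *consistently*, so that re-running the preprocessing
  rules on the daily files reproduces the weekly truth exactly. The
  disaggregation works on the 2-decimal scale written to CSV — the same
  numbers the preprocessing sees — which makes the trailing-window sleep
  rule agree bit for bit.
* Binary endogenous variables (long sleep, sitting idly) follow a
  linear-probability recursion: the Bernoulli success probability is the
  linear VAR index, clamped to [0, 1]. The conditional mean is then linear
  in the lags, so the PVAR is the correctly specified conditional-mean
  model and coefficient recovery is meaningful.
* Patient fixed effects enter as draws around the stationary level of
  each variable; a 20-week burn-in is discarded so series start near
  stationarity; unstable coefficient configurations are refused.
* Daily sleep follows an alternating short-night/long-night pattern
  (bimodal around the patient mean) with small reporting jitter. This is
  what keeps the *weekly* flag prevalence at 4%: the trailing mean ± SD
  rule is scale-free, and for any unimodal i.i.d. day distribution it
  flags roughly 15% of days (≈ 70% of weeks under the any-day rule); only
  a shoulder-heavy distribution keeps ordinary days inside the band.

**What the generator does not emulate** — and hence what green tests do
not certify about real cohorts: the marginal daily sleep SD is ≈ 0.9 h,
below the ≈ 1.6 h a real cohort shows (a 4% weekly exceedance rate under
the mean ± SD rule is mathematically incompatible with high-variance
i.i.d.-like daily sleep); activity diaries, GPS mobility and the
16-activity classifier are out of scope; questionnaire totals are
simulated directly rather than item by item; and true missingness in real
data may be MNAR, which nothing here can detect.

## Problem sizes and numerics

The test suite runs the full pipeline at the default 89 × 52 design
(seconds per fit), oracle-equivalence on a single 5000-week panel,
parameter recovery at 200 × 80, and the MCAR size study with 2000
replicates of n = 200 on 4 variables — sizes chosen so each check has
clear statistical power while the whole suite stays interactive.
Numerical tie-breaks worth knowing: zero-variance series standardise to
all zeros with a warning; a degenerate pooled t-test returns t = 0, p = 1
on equal means and an infinite statistic with p = 0 otherwise; screening
ties in |r| break by variable name; stability uses a 1e-8 margin inside
the unit circle; EM tolerance is 1e-6 on the relative log-likelihood.

## Known limitations

Single imputation understates standard errors; imputed response weeks
still attenuate the response's own-lag coefficients (the cross-lag
early-warning coefficient is protected by the auxiliary-lag imputation
model but autoregressive terms are not). One-step GMM is the only
weighting implemented; two-step/iterated GMM, impulse responses, Granger
tests and cross-sectional dependence corrections are out of scope. The
CDM test conditions on a configurable covariate set; it cannot
distinguish MAR from MNAR.
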