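#' Back-transform a response-scale coefficient to the K6 scale
#'
#' The PVAR response is \eqn{\ln(K6+1)} (divided by the square root of the
#' episode count, which cancels when the effect is reported on the
#' single-episode scale). A coefficient `beta` on that scale implies that
#' a patient currently at `k6_now` moves to
#' \deqn{K6' = e^{\beta} (K6 + 1) - 1.}
#' So the headline lag-3 long-sleep coefficient of 0.172 moves a patient
#' from K6 = 5 to 6.126 three weeks later.
#'
#' @param beta Coefficient on the log(K6+1) response scale.
#' @param k6_now Current K6 score in 0..24.
#' @return Implied K6 score; values above 24 are clipped with a warning.
#' @examples
#' implied_k6(0.172, 5)
#' implied_k6(0.271, 5)
#' @export
implied_k6 <- function(beta, k6_now) {
  if (any(k6_now < 0 | k6_now > 24)) stop("k6_now must lie in [0, 24]")
  out <- exp(beta) * (k6_now + 1) - 1
  if (any(out > 24)) {
    warning("implied K6 above the scale maximum; clipped to 24")
    out <- pmin(out, 24)
  }
  out
}

#' Significance stars
#'
#' Marker convention of the coefficient tables: `***` for p < 0.01, `**`
#' for p < 0.05, `*` for p < 0.1, empty otherwise (boundaries excluded).
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of markers.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 0.01) "***" else if (pp < 0.05) "**" else if (pp < 0.1) "*" else ""
  }, character(1))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, preprocess, missingness testing, imputation,
#' screening, lag selection, estimation and effect reporting, writing
#' every stage's artifact to `out_dir`:
#' `profiles.csv`, `daily.csv`, `weekly.csv`, `config.json` (cohort),
#' `panel.csv`, `panel_imputed.csv`, `imputation_report.json`,
#' `screening_report.json`, `pvar_fit.json`, `coef_table.txt`, and
#' `report.json` (CD table, selected lag, stability, implied-K6 effects).
#' The run is fully reproducible from the config seed; any stage failure
#' halts with the stage name.
#'
#' @param config A [cohort_config()]; its `seed` governs all randomness.
#' @param out_dir Output directory.
#' @param p_max Largest lag order tried during CD-based selection.
#' @param cdm_covariates Baseline covariates conditioned on in the
#'   missingness test.
#' @param k6_now Reference K6 score for the implied-effect
#'   back-transformation.
#' @return Invisibly, a list with `panel`, `mcar`, `imputation`,
#'   `screening`, `lag_selection`, `fit`, `report`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = tempfile("pvar"),
                         p_max = 4L, cdm_covariates = c("gender", "education"),
                         k6_now = 5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")

  cohort <- stage("simulate", simulate_cohort(config))
  write_cohort(cohort, out_dir)

  panel <- stage("preprocess",
                 build_panel(cohort$daily, cohort$weekly, cohort$profiles))
  utils::write.csv(panel, file.path(out_dir, "panel.csv"), row.names = FALSE)

  md <- merge(panel, cohort$profiles[, c("patient", cdm_covariates)],
              by = "patient", sort = FALSE)
  mcar <- stage("missingness-test",
                cdm_test(md, variables = c("k6_total", "lunch_skips",
                                           "uv_mean"),
                         covariates = cdm_covariates))

  imp <- stage("impute", impute_panel(panel, cohort$profiles))
  utils::write.csv(imp$panel, file.path(out_dir, "panel_imputed.csv"),
                   row.names = FALSE)
  wj(list(cdm_test = list(statistic = mcar$statistic, df = mcar$df,
                          p_value = mcar$p.value,
                          n_patterns = mcar$n_patterns,
                          applicable = mcar$applicable),
          models = imp$report), "imputation_report.json")

  scr <- stage("screen",
               screen_candidates(imp$panel,
                                 candidates = c("sit_mean", "lunch_skips",
                                                "uv_mean")))
  wj(list(shortlist = scr$shortlist, table = scr$table),
     "screening_report.json")

  endo <- c("y", "lunch_z", "uv_logz", "long_sleep", "sit_dummy")
  exo <- c("season", "pseudo_pos")
  sel <- stage("lag-selection",
               select_lag(imp$panel, endo, exo, p_max = p_max))
  fit <- sel$fits[[sel$selected]]

  wj(list(lags = fit$lags,
          endogenous = fit$endogenous, exogenous = fit$exogenous,
          A = lapply(fit$A, function(m) as.data.frame(m)),
          B = as.data.frame(fit$B),
          se_A = lapply(fit$se_A, function(m) as.data.frame(m)),
          se_B = as.data.frame(fit$se_B),
          sigma_e = as.data.frame(fit$sigma_e),
          cd = fit$cd, moduli = fit$moduli, stable = fit$stable,
          n_panels = fit$n_panels, t_bar = fit$t_bar, nobs = fit$nobs),
     "pvar_fit.json")
  writeLines(c(
    sprintf("Panel VAR(%d): %d panels, avg %.2f weeks, n = %d, CD = %.5f",
            fit$lags, fit$n_panels, fit$t_bar, fit$nobs, fit$cd),
    utils::capture.output(print(coef_table(fit), right = TRUE))),
    file.path(out_dir, "coef_table.txt"))

  effects <- NULL
  if (fit$lags >= 3L) {
    b3 <- fit$A[[3]]["long_sleep", "y"]
    effects <- list(
      lag3_long_sleep_beta = b3,
      lag3_long_sleep_se = fit$se_A[[3]]["long_sleep", "y"],
      k6_now = k6_now,
      implied_k6 = round(implied_k6(b3, k6_now), 3),
      implied_k6_raw = implied_k6(b3, k6_now))
  }
  report <- list(seed = config$seed,
                 n_patients = config$n_patients, weeks = config$weeks,
                 cd_table = sel$table, selected_lag = sel$selected,
                 stable = fit$stable, cd = fit$cd,
                 n_panels = fit$n_panels, t_bar = fit$t_bar,
                 nobs = fit$nobs, effects = effects)
  wj(report, "report.json")

  invisible(list(panel = panel, mcar = mcar, imputation = imp,
                 screening = scr, lag_selection = sel, fit = fit,
                 report = report, out_dir = out_dir))
}
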