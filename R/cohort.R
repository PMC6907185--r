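#' Default configuration for the synthetic lifelog cohort
#'
#' Returns the full set of data-generating parameters used by
#' [simulate_cohort()]. Defaults emulate a one-year maintenance-therapy
#' cohort: 89 patients followed for 52 weeks, weekly K6 self-reports with
#' covariate-dependent missingness, monthly PHQ-9 interviews, daily
#' noon-to-noon sleep near 8.0 h (SD about 1.6), weekly long/short-sleep
#' prevalence near 4\%, lunch-skip counts averaging about 2.5 of 7 days
#' with strong between-patient heterogeneity, and lognormal weekly UV doses
#' (mean about 16.5, SD about 16.7) with device-dropout missingness.
#'
#' The five weekly endogenous series (transformed K6 response,
#' standardised lunch skips, log-standardised UV, long-sleep dummy,
#' sitting-idly dummy) follow a stable panel VAR of order `p` with
#' patient fixed effects. Binary series use a linear-probability recursion
#' (Bernoulli draws whose success probability is the linear VAR index), so
#' the conditional mean stays linear in the lags and the PVAR is the
#' correct model for the simulated data. The default truth places a
#' coefficient of `+0.25` on the third lag of the long-sleep dummy in the
#' response equation -- the early-warning signal the analysis is designed
#' to detect.
#'
#' @param n_patients Number of patients.
#' @param weeks Weeks of follow-up per patient.
#' @param p True lag order of the weekly process.
#' @param A List of `p` 5x5 coefficient matrices; `A[[j]][i, m]` is the
#'   effect of variable `i` at lag `j` on variable `m` (row-vector
#'   convention). Must satisfy the stability condition.
#' @param b_season Length-5 vector of effects of the December/January dummy.
#' @param sigma Length-5 error SDs (entries for the two binary variables
#'   are ignored; their noise is Bernoulli).
#' @param fe_sd Length-5 SDs of the zero-mean patient fixed effects on the
#'   stationary level of each variable.
#' @param mu_y Population mean of `ln(K6+1)` before the episode divisor.
#' @param long_prev,short_prev,sit_prev Stationary prevalences of the
#'   weekly long-sleep, short-sleep and sitting-idly dummies.
#' @param sleep_mean,sleep_between_sd Daily sleep-hours population mean
#'   and between-patient SD.
#' @param sleep_amp,sleep_amp_sd,sleep_jitter Within-patient sleep follows
#'   an alternating short-night/long-night pattern: each day sits
#'   `sleep_amp` hours above or below the patient mean (amplitude varying
#'   across patients with SD `sleep_amp_sd`) plus reporting jitter of SD
#'   `sleep_jitter`. The bimodal shoulders keep exceedances of the
#'   trailing mean + SD rule rare, so the weekly long/short-sleep
#'   prevalence stays near the configured 4\% instead of the ~50\% an
#'   i.i.d. Gaussian day model would produce; the price is a daily SD
#'   below the target cohort's (see the methods vignette on why a 4\%
#'   exceedance rate forces low-variance regular sleep).
#' @param lunch_beta Two shape parameters of the Beta distribution of each
#'   patient's lunch-skip propensity.
#' @param uv_meanlog,uv_between_sd,uv_sdlog Lognormal parameters of the
#'   weekly UV dose.
#' @param uv_dropout Daily probability that the wearable collects fewer
#'   than 1152 valid minutes (UV dose missing that day).
#' @param miss_intercept,miss_gender,miss_education Logistic coefficients
#'   of the K6 missingness mechanism (covariates only -- MAR by
#'   construction); defaults give a marginal weekly missing rate near
#'   15\%.
#' @param seed Integer seed; every random draw is governed by it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 89L,
                          weeks = 52L,
                          p = 3L,
                          A = NULL,
                          b_season = c(0, -0.05, -0.20, -0.015, 0),
                          sigma = c(0.22, 0.75, 0.60, NA, NA),
                          fe_sd = c(0.30, 0.25, 0.25, 0.010, 0.010),
                          mu_y = 1.40,
                          long_prev = 0.04,
                          short_prev = 0.04,
                          sit_prev = 0.04,
                          sleep_mean = 8.0,
                          sleep_between_sd = 0.6,
                          sleep_amp = 1.45,
                          sleep_amp_sd = 0.20,
                          sleep_jitter = 0.15,
                          lunch_beta = c(0.5, 0.9),
                          uv_meanlog = 2.60,
                          uv_between_sd = 0.50,
                          uv_sdlog = 0.70,
                          uv_dropout = 0.10,
                          miss_intercept = -2.6,
                          miss_gender = 0.55,
                          miss_education = 0.25,
                          seed = 20161001L) {
  if (is.null(A)) {
    A1 <- diag(c(0.35, 0.30, 0.35, 0.20, 0.20))
    A1[2, 1] <- 0.03   # lunch skips -> next-week distress, mild
    A1[3, 1] <- -0.02  # UV exposure -> next-week distress, mild protective
    A2 <- diag(c(0.15, 0.10, 0.12, 0.05, 0.05))
    A3 <- diag(c(0.05, 0.03, 0.05, 0.02, 0.02))
    A3[4, 1] <- 0.25   # long sleep three weeks ago raises this week's response
    A3[4, 2] <- 0.20   # ... and lunch skipping
    A <- list(A1, A2, A3)
  }
  cfg <- list(n_patients = as.integer(n_patients), weeks = as.integer(weeks),
              p = as.integer(length(A)), A = A, b_season = b_season,
              sigma = sigma, fe_sd = fe_sd, mu_y = mu_y,
              long_prev = long_prev, short_prev = short_prev,
              sit_prev = sit_prev, sleep_mean = sleep_mean,
              sleep_between_sd = sleep_between_sd,
              sleep_amp = sleep_amp, sleep_amp_sd = sleep_amp_sd,
              sleep_jitter = sleep_jitter, lunch_beta = lunch_beta,
              uv_meanlog = uv_meanlog, uv_between_sd = uv_between_sd,
              uv_sdlog = uv_sdlog, uv_dropout = uv_dropout,
              miss_intercept = miss_intercept, miss_gender = miss_gender,
              miss_education = miss_education, seed = as.integer(seed),
              burn_in = 20L)
  if (as.integer(p) != cfg$p && !is.null(A)) cfg$p <- length(A)
  class(cfg) <- "cohort_config"
  cfg
}

#' Companion-matrix stability of a set of VAR coefficient matrices
#'
#' @param A List of `p` square k x k coefficient matrices (row-vector
#'   convention, as in [cohort_config()] and [pvar()]).
#' @param tol Margin inside the unit circle; default `1e-8`.
#' @return List with `moduli` (eigenvalue moduli of the kp x kp companion
#'   matrix, decreasing) and logical `stable`.
#' @export
var_stability <- function(A, tol = 1e-8) {
  k <- nrow(A[[1]])
  p <- length(A)
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[1:k, (j - 1) * k + 1:k] <- t(A[[j]])
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  mod <- sort(Mod(eigen(comp, only.values = TRUE)$values), decreasing = TRUE)
  list(moduli = mod, stable = max(mod) < 1 - tol)
}

#' Simulate a weekly panel from a VAR with patient fixed effects
#'
#' Low-level generator used both by [simulate_cohort()] and directly in
#' parameter-recovery studies: `N` patients, `T` weeks, a k-variate VAR(p)
#' with additive patient fixed effects and optional exogenous regressors.
#' Variables flagged in `binary` follow the linear-probability recursion
#' (Bernoulli draw with the linear index as success probability, clamped
#' to `[0, 1]`); the rest get Gaussian errors. A burn-in is discarded so
#' recorded series start near stationarity.
#'
#' @param N,T Panels and recorded periods per panel.
#' @param A List of p coefficient matrices, `A[[j]][i, m]` the effect of
#'   variable i at lag j on variable m. Must be stable.
#' @param sigma Length-k Gaussian error SDs (ignored for binary columns).
#' @param mu Length-k stationary means, or an N x k matrix of per-patient
#'   means (fixed effects enter through these levels).
#' @param binary Logical length-k; which columns are Bernoulli.
#' @param B Optional q x k exogenous coefficient matrix.
#' @param X Optional `T x q` (or `N*T x q`) exogenous design, recycled per
#'   patient when `T x q`.
#' @param burn_in Discarded initial periods.
#' @return Data frame with `patient`, `week`, and the k series `V1..Vk`
#'   (or `colnames(A[[1]])` when set).
#' @export
simulate_pvar_panel <- function(N, T, A, sigma, mu, binary = NULL,
                                B = NULL, X = NULL, burn_in = 20L) {
  st <- var_stability(A)
  if (!st$stable) {
    stop("true coefficient matrices violate the stability condition ",
         "(max eigenvalue modulus ", format(max(st$moduli), digits = 4), ")")
  }
  k <- nrow(A[[1]])
  p <- length(A)
  if (is.null(binary)) binary <- rep(FALSE, k)
  if (is.null(dim(mu))) mu <- matrix(mu, N, k, byrow = TRUE)
  Asum <- Reduce(`+`, A)
  total <- burn_in + T
  if (!is.null(B)) {
    if (is.null(X)) stop("B given without exogenous design X")
    X <- as.matrix(X)
  }
  out <- vector("list", N)
  for (i in seq_len(N)) {
    alpha <- drop(mu[i, , drop = FALSE] %*% (diag(k) - Asum))
    Y <- matrix(NA_real_, total, k)
    for (t0 in seq_len(p)) Y[t0, ] <- mu[i, ]
    for (t in (p + 1):total) {
      idx <- alpha
      for (j in seq_len(p)) idx <- idx + drop(Y[t - j, , drop = FALSE] %*% A[[j]])
      if (!is.null(B)) {
        tx <- t - burn_in
        if (tx >= 1 && tx <= nrow(X)) idx <- idx + drop(X[tx, , drop = FALSE] %*% B)
      }
      val <- idx
      cont <- !binary
      val[cont] <- idx[cont] + stats::rnorm(sum(cont), 0, sigma[cont])
      if (any(binary)) {
        pr <- pmin(pmax(idx[binary], 0), 1)
        val[binary] <- stats::rbinom(sum(binary), 1L, pr)
      }
      Y[t, ] <- val
    }
    Y <- Y[(burn_in + 1):total, , drop = FALSE]
    df <- data.frame(patient = i, week = seq_len(T))
    out[[i]] <- cbind(df, as.data.frame(Y))
  }
  res <- do.call(rbind, out)
  vn <- colnames(A[[1]])
  if (!is.null(vn)) names(res)[-(1:2)] <- vn
  rownames(res) <- NULL
  res
}

#' Simulate a full synthetic lifelog cohort
#'
#' Generates baseline profiles, daily lifelog records (with a 7-day
#' pre-entry lead-in so the trailing sleep window is defined from study
#' week 1), weekly K6 with covariate-dependent missingness, and monthly
#' PHQ-9, all driven by the weekly VAR truth in `config`. Daily records are
#' disaggregated consistently with the weekly truth: a long-sleep week
#' contains exactly the days that trip the trailing-window rule, weekly
#' lunch-skip counts scatter over the days of the week, and weekly UV
#' spreads over days subject to the wear-time validity rule.
#'
#' @param config A [cohort_config()] object.
#' @return List of class `"lifelog_cohort"` with data frames `profiles`,
#'   `daily`, `weekly`, and the `config` (including seed) echoed back.
#'   Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  st <- var_stability(cfg$A)
  if (!st$stable) {
    stop("configured coefficient matrices are unstable (max modulus ",
         format(max(st$moduli), digits = 4), "); refusing to simulate")
  }
  set.seed(cfg$seed)
  N <- cfg$n_patients
  T <- cfg$weeks
  k <- 5L

  ## -- baseline profiles -------------------------------------------------
  entry <- as.Date("2016-10-01") + sample.int(182L, N, replace = TRUE) - 1L
  age <- pmin(pmax(round(stats::rnorm(N, 44.3, 10.8)), 22L), 69L)
  profiles <- data.frame(
    patient = sprintf("P%03d", seq_len(N)),
    gender = stats::rbinom(N, 1L, 0.55),
    education = sample(1:3, N, replace = TRUE, prob = c(0.034, 0.225, 0.741)),
    occupation = sample(1:7, N, replace = TRUE,
                        prob = c(0.539, 0.135, 0.034, 0.067, 0.034, 0.157, 0.034)),
    marital = sample(1:4, N, replace = TRUE, prob = c(0.326, 0.124, 0.011, 0.539)),
    age = age,
    episodes = 1L + stats::rpois(N, 1.5),
    entry_date = entry,
    stringsAsFactors = FALSE
  )

  ## -- weekly endogenous truth ------------------------------------------
  mu <- matrix(0, N, k)
  mu[, 1] <- (cfg$mu_y + stats::rnorm(N, 0, cfg$fe_sd[1])) / sqrt(profiles$episodes)
  mu[, 2] <- stats::rnorm(N, 0, cfg$fe_sd[2])
  mu[, 3] <- stats::rnorm(N, 0, cfg$fe_sd[3])
  mu[, 4] <- pmax(cfg$long_prev + stats::rnorm(N, 0, cfg$fe_sd[4]), 0.005)
  mu[, 5] <- pmax(cfg$sit_prev + stats::rnorm(N, 0, cfg$fe_sd[5]), 0.005)
  binary <- c(FALSE, FALSE, FALSE, TRUE, TRUE)

  lat <- vector("list", N)
  for (i in seq_len(N)) {
    wk_dates <- profiles$entry_date[i] + (seq_len(T) - 1L) * 7L
    X <- matrix(seasonal_dummy(wk_dates), ncol = 1)
    lat[[i]] <- simulate_pvar_panel(
      1L, T, cfg$A, sigma = cfg$sigma, mu = mu[i, , drop = FALSE],
      binary = binary, B = matrix(cfg$b_season, nrow = 1), X = X,
      burn_in = cfg$burn_in)
    lat[[i]]$patient <- profiles$patient[i]
  }
  lat <- do.call(rbind, lat)
  names(lat)[3:7] <- c("y", "lunch_z", "uv_z", "long", "sit")

  ## -- weekly observables ------------------------------------------------
  weekly <- lat[, c("patient", "week")]
  ep <- profiles$episodes[match(lat$patient, profiles$patient)]
  weekly$k6_true <- pmin(pmax(round(exp(lat$y * sqrt(ep)) - 1), 0L), 24L)
  weekly$phq9_total <- NA_integer_
  isassess <- lat$week %% 4L == 0L
  weekly$phq9_total[isassess] <- pmin(pmax(
    round(0.9 * weekly$k6_true[isassess] +
            stats::rnorm(sum(isassess), 0, 1.5)), 0L), 27L)

  weekly$k6_total <- inject_missingness(
    weekly$k6_true, profiles[match(weekly$patient, profiles$patient), ],
    list(intercept = cfg$miss_intercept, gender = cfg$miss_gender,
         education = cfg$miss_education))
  weekly$short <- stats::rbinom(nrow(weekly), 1L, cfg$short_prev)

  ## patient-level lifelog parameters
  sleep_mu <- stats::rnorm(N, cfg$sleep_mean, cfg$sleep_between_sd)
  sleep_a <- pmax(stats::rnorm(N, cfg$sleep_amp, cfg$sleep_amp_sd), 0.8)
  lunch_p <- stats::rbeta(N, cfg$lunch_beta[1], cfg$lunch_beta[2])
  uv_mu <- stats::rnorm(N, cfg$uv_meanlog, cfg$uv_between_sd)
  sit_mu <- abs(stats::rnorm(N, 1.0, 0.5))

  weekly$lunch_count <- NA_integer_
  weekly$uv_week <- NA_real_
  weekly$sit_week <- NA_real_
  ii <- match(weekly$patient, profiles$patient)
  weekly$lunch_count <- pmin(pmax(
    as.integer(round(7 * lunch_p[ii] + 1.5 * lat$lunch_z)), 0L), 7L)
  weekly$uv_week <- exp(uv_mu[ii] + cfg$uv_sdlog * lat$uv_z)
  weekly$sit_week <- pmax(sit_mu[ii] + 2.0 * lat$sit +
                            stats::rnorm(nrow(weekly), 0, 0.15), 0)

  ## -- daily disaggregation ---------------------------------------------
  daily <- vector("list", N)
  for (i in seq_len(N)) {
    wk <- weekly[weekly$patient == profiles$patient[i], ]
    wk <- wk[order(wk$week), ]
    lg <- lat$long[lat$patient == profiles$patient[i]][order(lat$week[lat$patient == profiles$patient[i]])]
    nd <- 7L + 7L * T                       # 7-day lead-in + study days
    dates <- profiles$entry_date[i] - 7L + seq_len(nd) - 1L
    # alternating short/long nights around the patient mean: bimodal
    # shoulders keep daily SD realistic without tripping the trailing
    # mean + SD rule on ordinary days
    sgn <- numeric(nd)
    sgn[1] <- sample(c(-1, 1), 1L)
    flip <- stats::runif(nd) < 0.85         # alternation-prone nights
    for (d in 2:nd) sgn[d] <- if (flip[d]) -sgn[d - 1] else sgn[d - 1]
    base <- sleep_mu[i] + sgn * sleep_a[i] +
      stats::rnorm(nd, 0, cfg$sleep_jitter)
    # work on the 2-decimal scale that is written to daily.csv, so the
    # trailing-window rule evaluates identically downstream
    sleep <- round(pmin(pmax(base, 0), 24), 2)
    long_day <- short_day <- integer(T)
    for (w in seq_len(T)) {
      long_day[w] <- if (lg[w] == 1L) sample.int(7L, 1L) else 0L
      sd_ <- if (wk$short[w] == 1L) sample.int(7L, 1L) else 0L
      if (sd_ == long_day[w] && sd_ > 0L) sd_ <- (sd_ %% 7L) + 1L
      short_day[w] <- sd_
    }
    for (d in 8:nd) {
      w <- (d - 8L) %/% 7L + 1L            # study week of day d
      dow <- (d - 8L) %% 7L + 1L
      win <- sleep[(d - 7):(d - 1)]
      m7 <- mean(win); s7 <- stats::sd(win)
      if (dow == long_day[w]) {
        v <- round(min(m7 + s7 + 0.3 + abs(stats::rnorm(1, 0, 0.5)), 24), 2)
        if (v <= m7 + s7) v <- round(m7 + s7 + 0.31, 2)
        sleep[d] <- v
      } else if (dow == short_day[w]) {
        v <- round(max(m7 - s7 - 0.3 - abs(stats::rnorm(1, 0, 0.5)), 0.2), 2)
        if (v >= m7 - s7 && m7 - s7 > 0.5) v <- round(m7 - s7 - 0.31, 2)
        sleep[d] <- v
      } else if (sleep[d] > m7 + s7 || sleep[d] < m7 - s7) {
        # rare accidental exceedance: pull just inside the band so the
        # weekly dummy stays exactly the configured truth
        v <- round(m7 + sign(sleep[d] - m7) * max(s7 - 0.05, 0) * 0.98, 2)
        if (v > m7 + s7 || v < m7 - s7) v <- round(m7, 2)
        sleep[d] <- v
      }
    }
    lunch <- rep(1L, nd)
    uvmin <- integer(nd)
    uvdose <- numeric(nd)
    sit <- numeric(nd)
    drop_day <- stats::runif(nd) < cfg$uv_dropout
    uvmin[drop_day] <- sample(0:1151, sum(drop_day), replace = TRUE)
    uvmin[!drop_day] <- sample(1152:1440, sum(!drop_day), replace = TRUE)
    g_lead <- exp(stats::rnorm(7, -0.045, 0.3))
    uvdose[1:7] <- exp(uv_mu[i]) * g_lead
    sit[1:7] <- pmax(sit_mu[i] + stats::rnorm(7, 0, 0.35), 0)
    for (w in seq_len(T)) {
      dsel <- 7L + (w - 1L) * 7L + 1:7
      skip <- sample.int(7L, wk$lunch_count[w])
      lunch[dsel[skip]] <- 0L
      g <- exp(stats::rnorm(7, -0.045, 0.3))
      uvdose[dsel] <- wk$uv_week[w] * g
      sit[dsel] <- pmax(wk$sit_week[w] + stats::rnorm(7, 0, 0.35), 0)
    }
    uvdose[drop_day] <- NA_real_
    daily[[i]] <- data.frame(
      patient = profiles$patient[i], date = dates,
      sleep_hours = round(pmin(pmax(sleep, 0), 24), 2),
      uv_minutes = uvmin, uv_dose = round(uvdose, 2),
      lunch_eaten = lunch, sit_hours = round(sit, 2),
      stringsAsFactors = FALSE)
  }
  daily <- do.call(rbind, daily)
  rownames(daily) <- NULL

  weekly_out <- weekly[, c("patient", "week", "k6_total", "phq9_total")]
  structure(list(profiles = profiles, daily = daily, weekly = weekly_out,
                 truth = lat, config = cfg),
            class = "lifelog_cohort")
}

#' Delete weekly values under a covariate-dependent (MAR) mechanism
#'
#' Each value is deleted independently with probability
#' `plogis(intercept + gender * coef + education * coef)` computed from the
#' patient's fully observed baseline covariates. Because the mechanism may
#' reference covariates only -- never the value being deleted -- the
#' missingness is MAR (covariate-dependent) by construction; a mechanism
#' naming the target variable is refused as MNAR.
#'
#' @param values Numeric/integer vector of weekly values.
#' @param covariates Data frame (one row per value) with columns `gender`
#'   and `education`.
#' @param mechanism List with `intercept`, `gender`, `education` logistic
#'   coefficients. Any element named after the deleted variable (e.g.
#'   `k6_total`, `value`) is a configuration error.
#' @return `values` with deleted entries set to `NA`.
#' @export
inject_missingness <- function(values, covariates, mechanism) {
  bad <- intersect(names(mechanism), c("value", "values", "k6_total", "target"))
  if (length(bad)) {
    stop("missingness mechanism references the value being deleted (",
         paste(bad, collapse = ", "), "): that is MNAR, unsupported")
  }
  eta <- mechanism$intercept +
    mechanism$gender * covariates$gender +
    mechanism$education * covariates$education
  pr <- stats::plogis(eta)
  miss <- stats::runif(length(values)) < pr
  values[miss] <- NA
  values
}

#' Write a simulated cohort to CSV files with a JSON sidecar
#'
#' @param cohort A `"lifelog_cohort"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`profiles.csv`, `daily.csv`,
#'   `weekly.csv`, `config.json`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lifelog_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("profiles.csv", "daily.csv", "weekly.csv",
                            "config.json"))
  utils::write.csv(cohort$profiles, paths[1], row.names = FALSE)
  utils::write.csv(cohort$daily, paths[2], row.names = FALSE)
  utils::write.csv(cohort$weekly, paths[3], row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$A <- lapply(cfg$A, function(m) unclass(as.data.frame(m)))
  jsonlite::write_json(cfg, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
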