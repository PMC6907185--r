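# EM estimation of a multivariate-normal mean and covariance under
# arbitrary missingness patterns. Hand-rolled because no installed package
# provides it; standard E-step conditional-moment sweep grouped by pattern.
# Convergence on the observed-data log-likelihood.
em_norm <- function(Y, tol = 1e-6, max_iter = 500L) {
  Y <- as.matrix(Y)
  keep <- rowSums(!is.na(Y)) > 0L
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y); pdim <- ncol(Y)
  if (n < pdim + 1L) stop("too few rows for covariance estimation")
  mu <- colMeans(Y, na.rm = TRUE)
  S <- diag(apply(Y, 2, stats::var, na.rm = TRUE), pdim)
  pat <- apply(!is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pat)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sum_y <- numeric(pdim)
    sum_yy <- matrix(0, pdim, pdim)
    ll <- 0
    for (g in groups) {
      o <- which(!is.na(Y[g[1], ]))
      m <- setdiff(seq_len(pdim), o)
      Yo <- Y[g, o, drop = FALSE]
      So <- S[o, o, drop = FALSE]
      Soi <- solve(So)
      dev <- sweep(Yo, 2, mu[o])
      # observed-data log-likelihood contribution
      ll <- ll - 0.5 * length(g) * (length(o) * log(2 * pi) +
                                      determinant(So)$modulus) -
        0.5 * sum((dev %*% Soi) * dev)
      Yfull <- matrix(0, length(g), pdim)
      Yfull[, o] <- Yo
      if (length(m)) {
        Bm <- S[m, o, drop = FALSE] %*% Soi
        Yfull[, m] <- matrix(mu[m], length(g), length(m), byrow = TRUE) +
          dev %*% t(Bm)
        Cm <- S[m, m, drop = FALSE] - Bm %*% S[o, m, drop = FALSE]
      }
      sum_y <- sum_y + colSums(Yfull)
      sum_yy <- sum_yy + crossprod(Yfull)
      if (length(m)) {
        sum_yy[m, m] <- sum_yy[m, m] + length(g) * Cm
      }
    }
    mu <- sum_y / n
    S <- sum_yy / n - tcrossprod(mu)
    if (abs(ll - ll_old) < tol * (abs(ll_old) + tol)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = S, loglik = ll, iterations = it,
       patterns = groups, n = n)
}

#' Little's test of missing completely at random
#'
#' Computes Little's chi-square statistic
#' \deqn{d^2 = \sum_j n_j (\bar{y}_{obs,j} - \hat\mu_j)' \hat\Sigma_j^{-1}
#'       (\bar{y}_{obs,j} - \hat\mu_j)}
#' over the missingness patterns j, where the grand mean and covariance are
#' maximum-likelihood estimates from EM under multivariate normality and
#' the subscript j restricts to the variables observed in pattern j.
#' Under MCAR, \eqn{d^2} is asymptotically chi-square with
#' \eqn{\sum_j p_j - p} degrees of freedom. With a single pattern
#' (complete data) the test is not applicable: statistic 0, df 0.
#'
#' @param data Data frame or matrix of the variables to test (numeric,
#'   `NA` for missing).
#' @param variables Optional character vector selecting columns.
#' @param tol,max_iter EM convergence tolerance (relative log-likelihood
#'   change) and iteration cap.
#' @return Object of class `"mcar_test"`: `statistic`, `df`, `p.value`,
#'   `n_patterns`, `applicable`, `mu`, `sigma`.
#' @references Little, R. J. A. (1988). A test of missing completely at
#'   random for multivariate data with missing values. JASA 83, 1198-1202.
#' @export
little_mcar_test <- function(data, variables = NULL, tol = 1e-6,
                             max_iter = 500L) {
  Y <- as.matrix(if (is.null(variables)) data else data[, variables, drop = FALSE])
  storage.mode(Y) <- "double"
  Y <- Y[rowSums(!is.na(Y)) > 0L, , drop = FALSE]
  pdim <- ncol(Y)
  pat <- apply(!is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  if (length(unique(pat)) < 2L) {
    out <- list(statistic = 0, df = 0L, p.value = NA_real_,
                n_patterns = length(unique(pat)), applicable = FALSE,
                mu = colMeans(Y, na.rm = TRUE), sigma = stats::cov(Y,
                use = "pairwise.complete.obs"))
    class(out) <- "mcar_test"
    return(out)
  }
  em <- em_norm(Y, tol = tol, max_iter = max_iter)
  d2 <- 0
  df <- 0L
  for (g in em$patterns) {
    o <- which(!is.na(Y[g[1], ]))
    ybar <- colMeans(Y[g, o, drop = FALSE])
    dlt <- ybar - em$mu[o]
    d2 <- d2 + length(g) * drop(t(dlt) %*% solve(em$sigma[o, o, drop = FALSE]) %*% dlt)
    df <- df + length(o)
  }
  df <- df - pdim
  out <- list(statistic = d2, df = df,
              p.value = stats::pchisq(d2, df, lower.tail = FALSE),
              n_patterns = length(em$patterns), applicable = TRUE,
              mu = em$mu, sigma = em$sigma)
  class(out) <- "mcar_test"
  out
}

#' @export
print.mcar_test <- function(x, ...) {
  if (!x$applicable) {
    cat("Little's MCAR test: not applicable (",
        x$n_patterns, " missingness pattern)\n", sep = "")
  } else {
    cat(sprintf(
      "Little's MCAR test: chi-square = %.3f, df = %d, p-value = %.4g (%d patterns)\n",
      x$statistic, x$df, x$p.value, x$n_patterns))
  }
  invisible(x)
}

#' Covariate-dependent-missingness (CDM) variant of Little's test
#'
#' Tests MCAR *conditional on covariates*: each tested variable is
#' regressed on the (fully observed) covariates by least squares, and
#' Little's test is applied to the residuals. Missingness driven purely by
#' an included covariate therefore no longer triggers rejection, while
#' missingness related to the variable's own level still does.
#'
#' @param data Data frame containing both tested variables and covariates.
#' @param variables Character vector of variables to test.
#' @param covariates Character vector of fully observed covariate columns
#'   (factors allowed).
#' @inheritParams little_mcar_test
#' @return An `"mcar_test"` object (on the residual scale).
#' @export
cdm_test <- function(data, variables, covariates, tol = 1e-6,
                     max_iter = 500L) {
  if (any(!stats::complete.cases(data[, covariates, drop = FALSE]))) {
    stop("CDM covariates must be fully observed")
  }
  R <- matrix(NA_real_, nrow(data), length(variables),
              dimnames = list(NULL, variables))
  for (v in variables) {
    f <- stats::as.formula(paste0("`", v, "` ~ ",
                                  paste0("`", covariates, "`", collapse = " + ")))
    fit <- stats::lm(f, data = data, na.action = stats::na.exclude)
    R[, v] <- data[[v]] - stats::predict(fit, newdata = data)
  }
  little_mcar_test(R, tol = tol, max_iter = max_iter)
}

#' Fit a weighted-regression imputation model
#'
#' Least squares with analytic weights: coefficients minimise
#' \eqn{\sum_i w_i (y_i - x_i'\beta)^2}, fitted only on rows where the
#' target is observed. With equal weights this is ordinary least squares;
#' the intended weight is the number of weeks from study entry, which is
#' inversely proportional to the observation variance in a lengthening
#' diary. Categorical predictors are one-hot encoded against their first
#' level.
#'
#' @param data Data frame.
#' @param target Name of the variable to impute.
#' @param predictors Character vector of predictor columns.
#' @param weights Name of the (strictly positive) weight column.
#' @param range Optional length-2 numeric; predictions are clipped into
#'   this interval at imputation time (e.g. `c(0, 24)` for K6).
#' @return Object of class `"imputation_model"` wrapping the `lm` fit.
#' @export
fit_weighted_imputer <- function(data, target, predictors, weights,
                                 range = NULL) {
  w <- data[[weights]]
  train <- !is.na(data[[target]]) &
    stats::complete.cases(data[, predictors, drop = FALSE])
  if (any(w[train] <= 0)) stop("analytic weights must be strictly positive")
  f <- stats::as.formula(paste0("`", target, "` ~ ",
                                paste0("`", predictors, "`", collapse = " + ")))
  td <- data[train, , drop = FALSE]
  fit <- stats::lm(f, data = td, weights = w[train])
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient imputation design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(fit = fit, target = target, predictors = predictors,
                 weights = weights, range = range, n_train = sum(train)),
            class = "imputation_model")
}

#' Impute missing target values with a fitted model
#'
#' Replaces missing cells of the model's target by regression predictions.
#' Observed cells are never touched; rows whose predictors are missing stay
#' missing (and are counted); predictions are clipped into the model's
#' `range` when one was set.
#'
#' @param data Data frame to complete.
#' @param model An `"imputation_model"`.
#' @return List: `data` (completed), `imputed` (logical flag per row),
#'   `n_imputed`, `n_unimputable`.
#' @export
impute <- function(data, model) {
  stopifnot(inherits(model, "imputation_model"))
  tgt <- model$target
  miss <- is.na(data[[tgt]])
  can <- miss & stats::complete.cases(data[, model$predictors, drop = FALSE])
  if (any(can)) {
    pred <- stats::predict(model$fit, newdata = data[can, , drop = FALSE])
    if (!is.null(model$range)) {
      pred <- pmin(pmax(pred, model$range[1]), model$range[2])
    }
    data[[tgt]][can] <- pred
  }
  list(data = data, imputed = can, n_imputed = sum(can),
       n_unimputable = sum(miss & !can))
}

#' Impute the analysis panel (K6, UV, lunch)
#'
#' Applies the weighted-regression imputation to the three variables the
#' panel analysis needs complete. K6 totals are imputed on the raw 0--24
#' scale from the carried-forward PHQ-9 score, weekly sleep summaries,
#' long/short-sleep dummies and baseline covariates, with the
#' weeks-from-entry analytic weight, then clipped and rounded to the K6
#' scale and propagated through the response transform. The standardised
#' UV and lunch variables are imputed from the lifelog predictors with the
#' same machinery.
#'
#' Because the imputation model must carry the variables of the analysis
#' model to avoid biasing its coefficients toward zero, lags
#' `1..aux_lags` of the long- and short-sleep dummies are added to the K6
#' predictor set as auxiliary variables (set `aux_lags = 0` for the bare
#' predictor list).
#'
#' @param panel Panel from [build_panel()].
#' @param profiles Baseline covariates (for gender/education/occupation/
#'   marital predictors).
#' @param k6_predictors,lifelog_predictors Predictor sets; defaults follow
#'   the K6 recipe above.
#' @param aux_lags Number of lags of the sleep dummies appended to the K6
#'   imputation model as auxiliaries (default 3, the horizon of the
#'   early-warning effect the analysis targets).
#' @return List: completed `panel` with `imp_k6`, `imp_uv`, `imp_lunch`
#'   flag columns, and `report` (per-variable counts and model summaries).
#' @export
impute_panel <- function(panel, profiles,
                         k6_predictors = c("phq9_carried", "sleep_mean",
                                           "long_sleep", "short_sleep",
                                           "gender", "education",
                                           "occupation", "marital"),
                         lifelog_predictors = c("sleep_mean", "long_sleep",
                                                "short_sleep",
                                                "phq9_carried"),
                         aux_lags = 3L) {
  pr <- profiles[, c("patient", "gender", "education", "occupation",
                     "marital")]
  for (cc in c("education", "occupation", "marital")) {
    pr[[cc]] <- factor(pr[[cc]])
  }
  d <- merge(panel, pr, by = "patient", sort = FALSE)
  d <- d[order(d$patient, d$week), ]
  aux <- character(0)
  if (aux_lags > 0L) {
    lag_by_patient <- function(x, l) {
      stats::ave(x, d$patient, FUN = function(v) c(rep(NA, l),
                                                   utils::head(v, -l)))
    }
    for (l in seq_len(aux_lags)) {
      d[[paste0(".long_l", l)]] <- lag_by_patient(d$long_sleep, l)
      d[[paste0(".short_l", l)]] <- lag_by_patient(d$short_sleep, l)
      aux <- c(aux, paste0(".long_l", l), paste0(".short_l", l))
    }
    k6_predictors <- c(k6_predictors, aux)
  }

  mk6 <- fit_weighted_imputer(d, "k6_total", k6_predictors, "weight",
                              range = c(0, 24))
  res <- impute(d, mk6)
  d <- res$data
  d$imp_k6 <- res$imputed
  d$k6_total[d$imp_k6] <- round(d$k6_total[d$imp_k6])
  d$y <- transform_response(d$k6_total, d$episodes)
  d$pseudo_pos <- pseudo_positive_dummy(d$k6_total, d$phq9_carried)
  d$pseudo_pos[is.na(d$pseudo_pos)] <- 0L

  muv <- fit_weighted_imputer(d, "uv_logz", lifelog_predictors, "weight")
  res <- impute(d, muv)
  d <- res$data
  d$imp_uv <- res$imputed

  mlz <- fit_weighted_imputer(d, "lunch_z", lifelog_predictors, "weight")
  res <- impute(d, mlz)
  d <- res$data
  d$imp_lunch <- res$imputed

  report <- list(
    k6 = list(n_train = mk6$n_train, n_imputed = sum(d$imp_k6),
              coef = stats::coef(mk6$fit)),
    uv = list(n_train = muv$n_train, n_imputed = sum(d$imp_uv),
              coef = stats::coef(muv$fit)),
    lunch = list(n_train = mlz$n_train, n_imputed = sum(d$imp_lunch),
                 coef = stats::coef(mlz$fit))
  )
  d <- d[, setdiff(names(d), c("gender", "education", "occupation",
                               "marital", aux))]
  list(panel = d, report = report)
}
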