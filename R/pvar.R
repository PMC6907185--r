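#' Forward orthogonal deviations (Helmert transform)
#'
#' Replaces each observation by its deviation from the mean of all
#' *future* available observations, scaled by
#' \eqn{c_t = \sqrt{T_t/(T_t+1)}} where \eqn{T_t} is the number of future
#' available values. The transform annihilates any additive patient-level
#' constant exactly while keeping transformed errors homoskedastic and
#' serially uncorrelated when the original errors are. The last available
#' observation has no future and is dropped (`NA`).
#'
#' @param x Numeric series for one patient, in time order (`NA` allowed;
#'   missing entries are skipped when averaging the future).
#' @return Numeric vector of the same length; `NA` where the transform is
#'   undefined.
#' @examples
#' fod(c(1, 2, 3))  # -1.2247, -0.7071, NA
#' @export
fod <- function(x) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2L) return(out)
  obs <- which(!is.na(x))
  for (t in obs) {
    fut <- obs[obs > t]
    Tt <- length(fut)
    if (Tt == 0L) next
    out[t] <- sqrt(Tt / (Tt + 1)) * (x[t] - mean(x[fut]))
  }
  out
}

#' Multivariate coefficient of determination
#'
#' `CD = 1 - det(sigma_e) / det(sigma_y)`: the proportion of the
#' (generalised) variance of the dependent variables that the model
#' explains. Equals 1 for a perfect fit and 0 when the residual covariance
#' matches the dependent-variable covariance.
#'
#' @param sigma_e k x k residual covariance matrix.
#' @param sigma_y k x k covariance matrix of the dependent variables.
#' @return Scalar CD in `(-Inf, 1]`.
#' @export
compute_cd <- function(sigma_e, sigma_y) {
  dy <- det(sigma_y)
  if (!is.finite(dy) || abs(dy) < .Machine$double.eps) {
    stop("dependent-variable covariance is singular; CD undefined")
  }
  1 - det(sigma_e) / dy
}

# Split one patient's rows into maximal spells of consecutive time points
# with complete endogenous+exogenous data. Returns a list of row-index
# vectors (into the patient's ordered rows).
find_spells <- function(times, complete) {
  runs <- list()
  cur <- integer(0)
  for (r in seq_along(times)) {
    if (complete[r] && (length(cur) == 0L || times[r] == times[cur[length(cur)]] + 1L)) {
      cur <- c(cur, r)
    } else {
      if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
      cur <- if (complete[r]) r else integer(0)
    }
  }
  if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
  runs
}

#' Build GMM design for a panel VAR
#'
#' Internal workhorse shared by [pvar()] and [select_lag()]: constructs the
#' forward-orthogonal-deviation responses and regressors and the
#' lagged-level instrument matrix, spell by spell. Instruments are
#' untransformed levels of the endogenous variables at lags
#' `inst_start .. inst_start + inst_depth - 1`, in collapsed form (one
#' column per lag and variable), with unavailable lags zero-filled -- the
#' standard unbalanced-panel convention, which keeps every usable
#' observation in the estimation sample. Exogenous covariates instrument
#' themselves (FOD-transformed).
#'
#' @param data Long-format data frame.
#' @param endogenous,exogenous Character vectors of column names.
#' @param lags VAR order p.
#' @param id,time Column names of the panel and time indices.
#' @param inst_start First instrumenting level lag (>= 1).
#' @param inst_depth Number of instrumenting lags (>= 1).
#' @param sample_lags Require this many consecutive prior periods for an
#'   observation to enter the sample (defaults to `lags`; set higher to
#'   compare models of different order on a common sample).
#' @return List with matrices `Y` (FOD responses), `X` (FOD regressors),
#'   `Z` (instruments), vector `cluster` (panel id per row), and counts.
#' @keywords internal
pvar_design <- function(data, endogenous, exogenous = NULL, lags = 1L,
                        id = "patient", time = "week",
                        inst_start = 1L, inst_depth = lags + 1L,
                        sample_lags = lags) {
  if (inst_depth < 1L) stop("instrument depth must be >= 1 (no instruments)")
  if (inst_start < 1L) stop("instrument lags must start at 1 or deeper")
  if (sample_lags < lags) stop("sample_lags must be >= lags")
  k <- length(endogenous)
  q <- length(exogenous)
  p <- as.integer(lags)
  vars <- c(endogenous, exogenous)
  data <- data[order(data[[id]], data[[time]]), ]
  complete <- stats::complete.cases(data[, vars, drop = FALSE])

  xnames <- c(paste(rep(endogenous, p), rep(paste0("l", 1:p), each = k)),
              exogenous)
  znames <- c(paste(rep(endogenous, inst_depth),
                    rep(paste0("L", inst_start + seq_len(inst_depth) - 1L),
                        each = k)), exogenous)
  Ys <- Xs <- Zs <- list()
  cl <- list()
  for (pid in unique(data[[id]])) {
    di <- data[data[[id]] == pid, ]
    for (sp in find_spells(di[[time]], complete[data[[id]] == pid])) {
      L <- length(sp)
      if (L < sample_lags + 2L) next           # need lags plus a future obs
      Ylev <- as.matrix(di[sp, endogenous, drop = FALSE])
      rows <- (sample_lags + 1L):L
      # level blocks: response, p lags of regressors, exogenous
      M <- matrix(NA_real_, length(rows), k + k * p + q)
      M[, 1:k] <- Ylev[rows, ]
      for (j in seq_len(p)) {
        M[, k + (j - 1L) * k + 1:k] <- Ylev[rows - j, ]
      }
      if (q > 0L) {
        M[, k + k * p + 1:q] <- as.matrix(di[sp[rows], exogenous, drop = FALSE])
      }
      Mt <- apply(M, 2, fod)
      if (is.null(dim(Mt))) Mt <- matrix(Mt, nrow = 1)
      keep <- seq_len(length(rows) - 1L)       # last row has no future
      if (length(keep) == 0L) next
      Mt <- Mt[keep, , drop = FALSE]
      # instruments: zero-filled lagged levels, aligned with kept rows
      Zi <- matrix(0, length(keep), k * inst_depth + q)
      for (l in seq_len(inst_depth)) {
        lag <- inst_start + l - 1L
        src <- rows[keep] - lag
        ok <- src >= 1L
        Zi[ok, (l - 1L) * k + 1:k] <- Ylev[src[ok], ]
      }
      if (q > 0L) Zi[, k * inst_depth + 1:q] <- Mt[, k + k * p + 1:q]
      Ys[[length(Ys) + 1L]] <- Mt[, 1:k, drop = FALSE]
      Xs[[length(Xs) + 1L]] <- Mt[, k + seq_len(k * p + q), drop = FALSE]
      Zs[[length(Zs) + 1L]] <- Zi
      cl[[length(cl) + 1L]] <- rep(pid, length(keep))
    }
  }
  if (length(Ys) == 0L) {
    stop("estimation sample is empty after lag trimming")
  }
  Y <- do.call(rbind, Ys); colnames(Y) <- endogenous
  X <- do.call(rbind, Xs); colnames(X) <- xnames
  Z <- do.call(rbind, Zs); colnames(Z) <- znames
  list(Y = Y, X = X, Z = Z, cluster = unlist(cl), k = k, p = p, q = q,
       endogenous = endogenous, exogenous = exogenous)
}

#' Fit a panel vector autoregression by GMM on forward orthogonal deviations
#'
#' Estimates the k-variate panel VAR with patient fixed effects
#' \deqn{Y_{it} = Y_{it-1} A_1 + \dots + Y_{it-p} A_p + X_{it} B + v_i + e_{it}}
#' by one-step system GMM: the fixed effects \eqn{v_i} are annihilated by
#' the forward-orthogonal-deviation (Helmert) transform, and the
#' transformed regressors are instrumented with untransformed lagged
#' levels of the endogenous variables (weighting matrix
#' \eqn{(Z'Z)^{-1}}). Standard errors are clustered by patient. Lagged
#' levels dated `t-1` and deeper are valid instruments under serially
#' uncorrelated errors; the default uses lags `1..p+1` in collapsed form,
#' which keeps the instrument count modest on short panels while retaining
#' instrument strength.
#'
#' @inheritParams pvar_design
#' @param data Long-format data frame, one row per patient-week.
#' @param endogenous Character vector of endogenous variable columns.
#' @param exogenous Optional character vector of exogenous dummy columns.
#' @param lags VAR order p (>= 1).
#' @return Object of class `"pvar"`: coefficient matrices `A` (list of p,
#'   `A[[j]][i, m]` = effect of variable i at lag j on equation m) and `B`
#'   (q x k), matching `se_A`/`se_B`, `coef`/`se`/`pvalues` in stacked
#'   form, residual covariance `sigma_e`, FOD dependent covariance
#'   `sigma_y`, `cd`, companion `eigenvalues` (complex) and `moduli`,
#'   `stable`, sample sizes `n_panels`, `t_bar`, `nobs`, and the design
#'   matrices for diagnostics.
#' @seealso [select_lag()], [var_stability()], [compute_cd()]
#' @examples
#' \donttest{
#' A <- list(matrix(c(0.5, 0.1, 0.1, 0.4), 2, 2))
#' pan <- simulate_pvar_panel(50, 30, A, sigma = c(1, 1),
#'                            mu = c(0, 0), burn_in = 10)
#' fit <- pvar(pan, endogenous = c("V1", "V2"), lags = 1)
#' summary(fit)
#' }
#' @export
pvar <- function(data, endogenous, exogenous = NULL, lags = 1L,
                 id = "patient", time = "week",
                 inst_start = 1L, inst_depth = lags + 1L,
                 sample_lags = lags) {
  d <- pvar_design(data, endogenous, exogenous, lags, id, time,
                   inst_start, inst_depth, sample_lags)
  Y <- d$Y; X <- d$X; Z <- d$Z
  if (ncol(Z) < ncol(X)) {
    stop("under-identified: ", ncol(Z), " instruments for ", ncol(X),
         " parameters; increase inst_depth")
  }
  ZtZ <- crossprod(Z)
  W <- tryCatch(solve(ZtZ), error = function(e) {
    stop("singular instrument weighting matrix Z'Z; reduce inst_depth ",
         "or use collapsed instruments")
  })
  ZtX <- crossprod(Z, X)
  ZtY <- crossprod(Z, Y)
  H <- crossprod(ZtX, W %*% ZtX)
  beta <- solve(H, crossprod(ZtX, W %*% ZtY))   # (kp+q) x k
  E <- Y - X %*% beta
  n <- nrow(Y)
  k <- d$k; p <- d$p; q <- d$q

  # patient-clustered GMM sandwich, equation by equation
  Mb <- solve(H, t(ZtX) %*% W)                  # (kp+q) x (#inst)
  se <- matrix(NA_real_, nrow(beta), k, dimnames = dimnames(beta))
  ids <- d$cluster
  uid <- unique(ids)
  for (m in seq_len(k)) {
    S <- matrix(0, ncol(Z), ncol(Z))
    for (g in uid) {
      sel <- ids == g
      zg <- crossprod(Z[sel, , drop = FALSE], E[sel, m])
      S <- S + tcrossprod(zg)
    }
    V <- Mb %*% S %*% t(Mb)
    se[, m] <- sqrt(pmax(diag(V), 0))
  }
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  A <- lapply(seq_len(p), function(j) {
    Aj <- beta[(j - 1L) * k + 1:k, , drop = FALSE]
    rownames(Aj) <- d$endogenous
    Aj
  })
  seA <- lapply(seq_len(p), function(j) {
    s <- se[(j - 1L) * k + 1:k, , drop = FALSE]
    rownames(s) <- d$endogenous
    s
  })
  B <- seB <- NULL
  if (q > 0L) {
    B <- beta[k * p + 1:q, , drop = FALSE]; rownames(B) <- d$exogenous
    seB <- se[k * p + 1:q, , drop = FALSE]; rownames(seB) <- d$exogenous
  }
  sigma_e <- crossprod(E) / n
  Yc <- sweep(Y, 2, colMeans(Y))
  sigma_y <- crossprod(Yc) / n
  st <- var_stability(A)
  comp_eig <- companion_eigenvalues(A)
  out <- list(A = A, B = B, se_A = seA, se_B = seB,
              coef = beta, se = se, zvalues = zval, pvalues = pval,
              sigma_e = sigma_e, sigma_y = sigma_y,
              cd = compute_cd(sigma_e, sigma_y),
              eigenvalues = comp_eig, moduli = st$moduli,
              stable = st$stable,
              n_panels = length(uid), t_bar = n / length(uid), nobs = n,
              residuals = E, fitted = X %*% beta,
              endogenous = d$endogenous, exogenous = d$exogenous,
              lags = p, inst_start = inst_start, inst_depth = inst_depth,
              call = match.call())
  class(out) <- "pvar"
  out
}

# Complex eigenvalues of the companion matrix of a coefficient-matrix list.
companion_eigenvalues <- function(A) {
  k <- nrow(A[[1]]); p <- length(A)
  comp <- matrix(0, k * p, k * p)
  for (j in seq_len(p)) comp[1:k, (j - 1) * k + 1:k] <- t(A[[j]])
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  eigen(comp, only.values = TRUE)$values
}

#' Select the PVAR lag order by the multivariate coefficient of determination
#'
#' Fits the model for `p = 1..p_max` on the common estimation sample (all
#' fits require `p_max` consecutive prior periods, so CD values are
#' comparable), and selects the stable order with the largest CD.
#'
#' @inheritParams pvar
#' @param p_max Largest order to consider.
#' @return List with `selected` (chosen p), `table` (data frame of p, CD,
#'   max eigenvalue modulus, stable flag), and `fits` (the `"pvar"`
#'   objects). Errors, listing eigenvalue moduli per order, when no
#'   candidate is stable.
#' @export
select_lag <- function(data, endogenous, exogenous = NULL, p_max = 4L,
                       id = "patient", time = "week", inst_start = 1L,
                       inst_depth = NULL) {
  stopifnot(p_max >= 1L)
  fits <- lapply(seq_len(p_max), function(p) {
    pvar(data, endogenous, exogenous, lags = p, id = id, time = time,
         inst_start = inst_start,
         inst_depth = if (is.null(inst_depth)) p + 1L else inst_depth,
         sample_lags = p_max)
  })
  tab <- data.frame(
    p = seq_len(p_max),
    CD = vapply(fits, function(f) f$cd, numeric(1)),
    max_modulus = vapply(fits, function(f) max(f$moduli), numeric(1)),
    stable = vapply(fits, function(f) f$stable, logical(1))
  )
  if (!any(tab$stable)) {
    stop("no stable lag order in 1..", p_max, "; max eigenvalue moduli: ",
         paste(sprintf("p=%d: %.4f", tab$p, tab$max_modulus), collapse = ", "))
  }
  sel <- tab$p[tab$stable][which.max(tab$CD[tab$stable])]
  list(selected = sel, table = tab, fits = fits)
}

#' @export
print.pvar <- function(x, ...) {
  cat("Panel VAR(", x$lags, ") fitted by GMM on forward orthogonal deviations\n",
      sep = "")
  cat("Endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  if (!is.null(x$exogenous)) {
    cat("Exogenous: ", paste(x$exogenous, collapse = ", "), "\n")
  }
  cat(sprintf("Panels: %d   Avg weeks per panel: %.2f   Observations: %d\n",
              x$n_panels, x$t_bar, x$nobs))
  cat(sprintf("CD: %.5f   Max eigenvalue modulus: %.4f   Stable: %s\n",
              x$cd, max(x$moduli), x$stable))
  invisible(x)
}

#' @export
summary.pvar <- function(object, ...) {
  structure(list(fit = object, table = coef_table(object)),
            class = "summary.pvar")
}

#' @export
print.summary.pvar <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (standard errors in parentheses; *** p<0.01, ** p<0.05, * p<0.1):\n\n")
  print(x$table, right = TRUE)
  invisible(x)
}

#' Plain-text coefficient table with significance stars
#'
#' One row per regressor (lagged endogenous variables, then exogenous
#' dummies), one column per equation; each cell holds the coefficient with
#' significance stars over its standard error in parentheses, in the layout
#' used for reporting PVAR estimates.
#'
#' @param fit A `"pvar"` object.
#' @return A character data frame (2 text rows per regressor).
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "pvar"))
  rn <- rownames(fit$coef)
  out <- matrix("", nrow = 2L * length(rn), ncol = ncol(fit$coef))
  colnames(out) <- fit$endogenous
  lab <- character(2L * length(rn))
  for (r in seq_along(rn)) {
    lab[2 * r - 1] <- rn[r]
    for (m in seq_len(ncol(fit$coef))) {
      out[2 * r - 1, m] <- paste0(formatC(fit$coef[r, m], format = "g", digits = 3),
                                  significance_stars(fit$pvalues[r, m]))
      out[2 * r, m] <- paste0("(", formatC(fit$se[r, m], format = "g", digits = 3), ")")
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(df) <- make.unique(c(rbind(rn, paste0(rn, " "))))
  df
}

#' @export
coef.pvar <- function(object, ...) object$coef

#' @export
residuals.pvar <- function(object, ...) object$residuals

#' @export
fitted.pvar <- function(object, ...) object$fitted

#' One-step-ahead prediction from a fitted panel VAR
#'
#' Given the last `p` weeks of a patient's endogenous levels (and current
#' exogenous values), returns the expected next-week endogenous vector
#' *excluding* the patient fixed effect (which the FOD transform removes
#' and the GMM estimator therefore does not identify). Useful for
#' comparing relative week-on-week movements.
#'
#' @param object A `"pvar"` fit.
#' @param history p x k matrix of endogenous levels, oldest row first.
#' @param exog Optional length-q vector of exogenous values for the
#'   predicted week.
#' @param ... Unused.
#' @return Named length-k numeric vector.
#' @export
predict.pvar <- function(object, history, exog = NULL, ...) {
  p <- object$lags
  k <- length(object$endogenous)
  history <- as.matrix(history)
  if (nrow(history) < p) stop("need ", p, " rows of history")
  history <- history[nrow(history) - p + seq_len(p), , drop = FALSE]
  out <- numeric(k)
  for (j in seq_len(p)) {
    out <- out + drop(history[nrow(history) - j + 1L, , drop = FALSE] %*% object$A[[j]])
  }
  if (!is.null(object$B)) {
    if (is.null(exog)) exog <- rep(0, nrow(object$B))
    out <- out + drop(matrix(exog, nrow = 1) %*% object$B)
  }
  names(out) <- object$endogenous
  out
}

#' Simulate panels from a fitted panel VAR
#'
#' Draws `nsim` synthetic panels from the fitted coefficient matrices with
#' Gaussian errors at the estimated residual covariance and zero fixed
#' effects -- a parametric-bootstrap device for inspecting the dynamics the
#' fit implies.
#'
#' @param object A `"pvar"` fit (must be stable).
#' @param nsim Number of panels.
#' @param seed Optional integer seed.
#' @param nweeks Weeks per simulated panel.
#' @param ... Unused.
#' @return Data frame as from [simulate_pvar_panel()].
#' @export
simulate.pvar <- function(object, nsim = 1, seed = NULL, nweeks = 52L, ...) {
  if (!object$stable) stop("fitted model is unstable; refusing to simulate")
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$endogenous)
  sig <- sqrt(pmax(diag(object$sigma_e), 0))
  A <- lapply(object$A, function(m) {
    dimnames(m) <- list(object$endogenous, object$endogenous); m
  })
  simulate_pvar_panel(nsim, nweeks, A, sigma = sig, mu = rep(0, k),
                      burn_in = 20L)
}

#' Plot companion eigenvalues against the unit circle
#'
#' @param x A `"pvar"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pvar <- function(x, ...) {
  ev <- x$eigenvalues
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::plot(cos(th), sin(th), type = "l", lty = 2, asp = 1,
                 xlab = "Re", ylab = "Im",
                 main = "Companion eigenvalues and the unit circle", ...)
  graphics::points(Re(ev), Im(ev), pch = 19)
  invisible(x)
}
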