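#' Pooled-variance two-sample t-test
#'
#' Equal-variance (homogeneous) two-sample t-test, the screen used to find
#' activity variables whose weekly means differ between long/short-sleep
#' weeks and the rest. Wraps [stats::t.test()] with `var.equal = TRUE`,
#' adding explicit handling of degenerate zero-variance groups: equal
#' means give `t = 0, p = 1`; unequal means give an infinite statistic
#' with `p = 0` and a `degenerate` flag.
#'
#' @param a,b Numeric vectors (each of length >= 2; `NA` dropped).
#' @return List with `statistic`, `df`, `p.value`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing observations")
  }
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = df, p.value = 1,
                  mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, df = df,
                p.value = 0, mean_a = mean(a), mean_b = mean(b),
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

#' Two-stage variable screen for PVAR regressors
#'
#' Step 1 runs the pooled-variance t-test for each candidate activity
#' variable, splitting patient-weeks by the long-sleep dummy and,
#' separately, by the short-sleep dummy; a candidate survives when either
#' split is significant at `alpha` (union of the two separate splits).
#' Step 2 ranks the survivors by the absolute pooled Pearson correlation
#' with the K6 score and returns the top `k`. Ties in |r| break by
#' variable name order, so the shortlist is a deterministic function of
#' the panel.
#'
#' @param panel Data frame of patient-weeks.
#' @param candidates Character vector of candidate activity columns.
#' @param k6 Name of the K6 column used for the correlations.
#' @param long,short Names of the weekly long/short-sleep dummy columns.
#' @param alpha Step-1 significance level.
#' @param k Number of variables to select.
#' @return List with `shortlist` (character), `table` (per-candidate t,
#'   df, p for both splits, r, survived flag). An empty shortlist is
#'   returned, with a message, when nothing survives step 1.
#' @export
screen_candidates <- function(panel, candidates, k6 = "k6_total",
                              long = "long_sleep", short = "short_sleep",
                              alpha = 0.05, k = 2L) {
  if (length(candidates) < 1L) stop("need at least one candidate variable")
  tab <- data.frame(variable = candidates, t_long = NA_real_,
                    p_long = NA_real_, t_short = NA_real_,
                    p_short = NA_real_, r = NA_real_,
                    survived = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    v <- panel[[candidates[i]]]
    tl <- two_sample_t(v[panel[[long]] == 1L], v[panel[[long]] == 0L])
    ts <- two_sample_t(v[panel[[short]] == 1L], v[panel[[short]] == 0L])
    tab$t_long[i] <- tl$statistic; tab$p_long[i] <- tl$p.value
    tab$t_short[i] <- ts$statistic; tab$p_short[i] <- ts$p.value
    tab$r[i] <- stats::cor(v, panel[[k6]], use = "complete.obs")
    tab$survived[i] <- tl$p.value < alpha || ts$p.value < alpha
  }
  surv <- tab[tab$survived, ]
  if (nrow(surv) == 0L) {
    message("no candidate survived the t-test screen at alpha = ", alpha)
    return(list(shortlist = character(0), table = tab))
  }
  surv <- surv[order(-abs(surv$r), surv$variable), ]
  list(shortlist = utils::head(surv$variable, k), table = tab)
}
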