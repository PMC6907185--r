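#' Noon-to-noon sleep hours for one day
#'
#' A "day" of sleep is the total time asleep between noon of the previous
#' calendar day and noon of the index day, so that one night's sleep is
#' attributed to the morning it ends on. Sleep episodes spanning noon are
#' split across the two adjacent days.
#'
#' @param intervals Data frame with POSIXct columns `start` and `end`, one
#'   row per sleep episode for one patient. Episodes must not overlap.
#' @param date The index `Date`.
#' @param tz Time zone used to place noon; default `"UTC"`.
#' @return Hours of sleep in `[0, 24]` falling inside
#'   `[noon(date - 1), noon(date))`.
#' @examples
#' iv <- data.frame(
#'   start = as.POSIXct("2017-01-01 23:00", tz = "UTC"),
#'   end   = as.POSIXct("2017-01-02 07:00", tz = "UTC")
#' )
#' sleep_day_hours(iv, as.Date("2017-01-02"))
#' @export
sleep_day_hours <- function(intervals, date, tz = "UTC") {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(0)
  st <- as.numeric(intervals$start)
  en <- as.numeric(intervals$end)
  if (any(en < st)) stop("sleep interval with end before start")
  o <- order(st)
  if (any(st[o][-1] < en[o][-length(en)])) {
    stop("overlapping sleep intervals")
  }
  noon_hi <- as.numeric(as.POSIXct(paste(as.Date(date), "12:00:00"), tz = tz))
  noon_lo <- noon_hi - 86400
  overlap <- pmin(en, noon_hi) - pmax(st, noon_lo)
  sum(pmax(overlap, 0)) / 3600
}

#' Long- and short-sleep day flags
#'
#' A day is a long-sleep day when its noon-to-noon sleep exceeds the mean of
#' the preceding 7 days plus one (sample) standard deviation, and a
#' short-sleep day when it falls below the mean minus one standard
#' deviation. The trailing window excludes the index day; with fewer than 7
#' prior days the flags are undefined (`NA`), not zero.
#'
#' @param hours Numeric vector of daily sleep hours in chronological order
#'   (may contain `NA`).
#' @return Data frame with integer columns `long` and `short`, one row per
#'   input day.
#' @export
long_short_sleep_flags <- function(hours) {
  n <- length(hours)
  long <- short <- rep(NA_integer_, n)
  if (n <= 7L) return(data.frame(long = long, short = short))
  for (d in 8:n) {
    win <- hours[(d - 7):(d - 1)]
    if (anyNA(win) || is.na(hours[d])) next
    m <- mean(win)
    s <- stats::sd(win)
    long[d] <- as.integer(hours[d] > m + s)
    short[d] <- as.integer(hours[d] < m - s)
  }
  data.frame(long = long, short = short)
}

#' Weekly sleep dummies from daily flags
#'
#' The weekly long (short) sleep dummy is 1 when any day of the week is
#' flagged; days with missing flags are ignored. A week with no non-missing
#' daily flag yields `NA`.
#'
#' @param flags Integer vector of 0/1/NA daily flags for one week.
#' @return Integer 0/1 or `NA`.
#' @export
weekly_sleep_dummy <- function(flags) {
  obs <- flags[!is.na(flags)]
  if (length(obs) == 0L) return(NA_integer_)
  as.integer(any(obs == 1L))
}

#' UV wear-time validity rule
#'
#' The wearable samples UV exposure every minute; a day's UV dose counts as
#' missing when fewer than 80\% of the 1440 daily minutes (1152 min) were
#' collected.
#'
#' @param minutes Integer minutes collected, in 0..1440. Vectorised.
#' @return Logical; `TRUE` when the day's UV value is valid.
#' @export
uv_daily_valid <- function(minutes) {
  if (any(minutes < 0 | minutes > 1440, na.rm = TRUE)) {
    stop("UV minutes collected must lie in [0, 1440]")
  }
  minutes >= 1152
}

#' Weekly lunch-skip count
#'
#' Number of days in the week on which lunch was not eaten, counting only
#' days with a non-missing flag.
#'
#' @param eaten Integer vector of up to 7 daily lunch-eaten flags (0/1/NA).
#' @return Integer count in 0..7.
#' @export
lunch_skip_count <- function(eaten) {
  if (length(eaten) > 7L) stop("a week has at most 7 daily lunch flags")
  as.integer(sum(eaten == 0L, na.rm = TRUE))
}

#' Per-patient standardisation
#'
#' Centres and scales a patient's weekly series by the patient's own mean
#' and sample standard deviation over non-missing weeks, absorbing
#' between-patient heterogeneity in level and spread. A zero-variance series
#' is returned as all zeros with a warning.
#'
#' @param x Numeric series for one patient (may contain `NA`).
#' @return Numeric series with patient mean 0 and SD 1 over non-missing
#'   entries.
#' @export
standardise_series <- function(x) {
  obs <- !is.na(x)
  if (sum(obs) < 2L) stop("need at least 2 non-missing values to standardise")
  m <- mean(x[obs])
  s <- stats::sd(x[obs])
  if (s == 0) {
    warning("zero-variance series standardised to all zeros")
    x[obs] <- 0
    return(x)
  }
  (x - m) / s
}

#' Transformed distress response
#'
#' The response modelled by the PVAR is \eqn{\ln(K6 + 1)/\sqrt{episodes}}:
#' the log damps the right skew of K6 totals, and dividing by the square
#' root of the patient's number of prior depressive episodes balances the
#' response across patients whose reporting level grows with episode
#' history.
#'
#' @param k6 K6 total(s) in 0..24 (`NA` allowed).
#' @param episodes Number of prior depressive episodes (integer >= 1).
#' @return Numeric response value(s).
#' @examples
#' transform_response(5, 4)   # log(6)/2
#' @export
transform_response <- function(k6, episodes) {
  if (any(episodes < 1, na.rm = TRUE)) stop("episodes must be >= 1")
  if (any(k6 < 0 | k6 > 24, na.rm = TRUE)) stop("K6 total out of range [0, 24]")
  log(k6 + 1) / sqrt(episodes)
}

#' December/January seasonal dummy
#'
#' @param date `Date` vector.
#' @return Integer 0/1; 1 iff the month is December or January.
#' @export
seasonal_dummy <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  as.integer(m %in% c(12L, 1L))
}

#' Pseudo-positive dummy
#'
#' A week is a pseudo-positive -- a false alarm of recurrence -- when the
#' self-reported K6 signals distress (`k6 > 9`) while the interviewer-
#' administered PHQ-9 does not (`phq9 < 5`). Both inequalities are strict.
#' `NA` in either score yields `NA`.
#'
#' @param k6,phq9 Integer totals (vectorised).
#' @return Integer 0/1/NA.
#' @export
pseudo_positive_dummy <- function(k6, phq9) {
  as.integer(k6 > 9L & phq9 < 5L)
}

#' Build the weekly analysis panel
#'
#' Aggregates daily lifelog records and weekly/monthly questionnaires into
#' the panel the PVAR consumes: one row per patient-week (7-day blocks from
#' each patient's entry date) carrying the transformed response, the
#' long/short-sleep dummies, per-patient standardised lunch-skip counts,
#' log-then-standardised weekly UV, the sitting-idly dummy, the seasonal and
#' pseudo-positive exogenous dummies, the weeks-from-entry analytic weight,
#' and the raw weekly aggregates with missingness flags.
#'
#' Construction rules:
#' \itemize{
#'   \item Daily long/short-sleep flags compare each day to its trailing
#'     7-day window (see [long_short_sleep_flags()]); weekly dummies use the
#'     any-day rule.
#'   \item Daily UV doses on days failing the wear-time rule
#'     ([uv_daily_valid()]) are treated as missing; the weekly UV variable
#'     is \eqn{\ln(\bar{uv}_w + 1)} then standardised per patient.
#'   \item The sitting-idly dummy is 1 when the week's mean daily
#'     sitting-idly hours exceeds the patient's study-period mean plus
#'     `sit_sd_mult` standard deviations (mirroring the long-sleep rule).
#'   \item Monthly PHQ-9 totals are carried forward within their 4-week
#'     block for the pseudo-positive rule.
#' }
#'
#' @param daily Data frame of daily records: `patient`, `date`,
#'   `sleep_hours`, `uv_minutes`, `uv_dose`, `lunch_eaten`, `sit_hours`.
#' @param weekly Data frame of questionnaires: `patient`, `week`,
#'   `k6_total`, `phq9_total` (PHQ-9 `NA` on non-assessment weeks).
#'   Optional item columns `k6_item1..6` / `phq9_item1..9` are scored and
#'   checked against the totals when present.
#' @param profiles Data frame of baseline covariates: `patient`, `gender`,
#'   `education`, `occupation`, `marital`, `age`, `episodes`, `entry_date`.
#' @param sit_sd_mult Multiplier on the patient SD in the sitting-idly
#'   rule; default 1.
#' @return Data frame, one row per patient-week, with columns documented
#'   above plus `miss_k6`, `miss_uv`, `miss_lunch` indicator flags.
#' @export
build_panel <- function(daily, weekly, profiles, sit_sd_mult = 1) {
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(nm, " is missing columns: ", paste(miss, collapse = ", "))
  }
  need(daily, c("patient", "date", "sleep_hours", "uv_minutes", "uv_dose",
                "lunch_eaten", "sit_hours"), "daily")
  need(weekly, c("patient", "week", "k6_total"), "weekly")
  need(profiles, c("patient", "gender", "education", "occupation", "marital",
                   "age", "episodes", "entry_date"), "profiles")
  if (!"phq9_total" %in% names(weekly)) weekly$phq9_total <- NA_integer_

  # item-level questionnaire columns, when present, are validated against
  # the totals
  k6_items <- paste0("k6_item", 1:6)
  if (all(k6_items %in% names(weekly))) {
    weekly$k6_total <- vapply(seq_len(nrow(weekly)), function(i) {
      reconcile_total(weekly$k6_total[i],
                      as.integer(weekly[i, k6_items]), score_k6, "K6")
    }, integer(1))
  }

  daily$date <- as.Date(daily$date)
  profiles$entry_date <- as.Date(profiles$entry_date)
  daily <- daily[order(daily$patient, daily$date), ]

  out <- lapply(split(seq_len(nrow(profiles)), seq_len(nrow(profiles))), function(i) {
    pr <- profiles[i, ]
    dd <- daily[daily$patient == pr$patient, ]
    ww <- weekly[weekly$patient == pr$patient, ]
    if (nrow(ww) == 0L) return(NULL)
    ww <- ww[order(ww$week), ]

    # align daily records on days-from-entry; lead-in days (before entry)
    # only feed the trailing sleep window
    doff <- as.integer(dd$date - pr$entry_date)  # 0 = first study day
    fl <- long_short_sleep_flags(dd$sleep_hours)
    uv_day <- ifelse(uv_daily_valid(dd$uv_minutes), dd$uv_dose, NA_real_)

    nw <- max(ww$week)
    agg <- data.frame(week = seq_len(nw))
    pick <- function(w) which(doff >= (w - 1L) * 7L & doff < w * 7L)
    agg$long_sleep <- vapply(agg$week, function(w) weekly_sleep_dummy(fl$long[pick(w)]), integer(1))
    agg$short_sleep <- vapply(agg$week, function(w) weekly_sleep_dummy(fl$short[pick(w)]), integer(1))
    agg$sleep_mean <- vapply(agg$week, function(w) {
      x <- dd$sleep_hours[pick(w)]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    agg$sleep_sd <- vapply(agg$week, function(w) {
      x <- dd$sleep_hours[pick(w)]
      if (sum(!is.na(x)) < 2L) NA_real_ else stats::sd(x, na.rm = TRUE)
    }, numeric(1))
    agg$lunch_skips <- vapply(agg$week, function(w) {
      x <- dd$lunch_eaten[pick(w)]
      if (all(is.na(x))) NA_integer_ else lunch_skip_count(x)
    }, integer(1))
    agg$uv_mean <- vapply(agg$week, function(w) {
      x <- uv_day[pick(w)]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    agg$sit_mean <- vapply(agg$week, function(w) {
      x <- dd$sit_hours[pick(w)]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    agg$week_start <- pr$entry_date + (agg$week - 1L) * 7L

    p <- merge(agg, ww[, c("week", "k6_total", "phq9_total")],
               by = "week", all.x = TRUE)
    p <- p[order(p$week), ]
    p$patient <- pr$patient
    p$episodes <- pr$episodes

    # monthly PHQ-9 carried forward within its 4-week block
    p$phq9_carried <- p$phq9_total
    last <- NA_integer_
    for (r in seq_len(nrow(p))) {
      if (!is.na(p$phq9_total[r])) last <- p$phq9_total[r]
      p$phq9_carried[r] <- last
    }

    # sitting-idly dummy: week mean above patient study-period mean + SD
    mu <- mean(p$sit_mean, na.rm = TRUE)
    sdv <- stats::sd(p$sit_mean, na.rm = TRUE)
    p$sit_dummy <- if (is.na(sdv) || sdv == 0) {
      ifelse(is.na(p$sit_mean), NA_integer_, 0L)
    } else {
      as.integer(p$sit_mean > mu + sit_sd_mult * sdv)
    }

    safe_std <- function(x) {
      if (sum(!is.na(x)) < 2L) return(rep(NA_real_, length(x)))
      standardise_series(x)
    }
    p$y <- transform_response(p$k6_total, pr$episodes)
    p$lunch_z <- safe_std(as.numeric(p$lunch_skips))
    p$uv_logz <- safe_std(log(p$uv_mean + 1))
    p$season <- seasonal_dummy(p$week_start)
    p$pseudo_pos <- pseudo_positive_dummy(p$k6_total, p$phq9_carried)
    # exogenous dummies must be complete for estimation; a week with no K6
    # cannot be a pseudo-positive
    p$pseudo_pos[is.na(p$pseudo_pos)] <- 0L
    p$weight <- p$week
    p$miss_k6 <- as.integer(is.na(p$k6_total))
    p$miss_uv <- as.integer(is.na(p$uv_mean))
    p$miss_lunch <- as.integer(is.na(p$lunch_skips))
    p
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  cols <- c("patient", "week", "week_start", "y", "long_sleep", "short_sleep",
            "lunch_z", "uv_logz", "sit_dummy", "season", "pseudo_pos",
            "weight", "k6_total", "phq9_total", "phq9_carried", "episodes",
            "sleep_mean", "sleep_sd", "lunch_skips", "uv_mean", "sit_mean",
            "miss_k6", "miss_uv", "miss_lunch")
  out[, cols]
}
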