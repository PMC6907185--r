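# Shared fixtures built in code.

# A small stable bivariate VAR(1) truth used across estimator tests.
A2x2 <- function() list(matrix(c(0.5, 0.1, 0.1, 0.4), 2, 2, byrow = TRUE))

# Tiny daily/weekly/profiles triple for preprocessing tests: one patient,
# nw weeks plus the 7-day lead-in, deterministic values.
tiny_inputs <- function(nw = 6L, entry = as.Date("2016-12-01")) {
  nd <- 7L + 7L * nw
  daily <- data.frame(
    patient = "P1",
    date = entry - 7L + seq_len(nd) - 1L,
    sleep_hours = rep(8, nd),
    uv_minutes = rep(1440L, nd),
    uv_dose = rep(15, nd),
    lunch_eaten = rep(1L, nd),
    sit_hours = rep(1, nd)
  )
  weekly <- data.frame(patient = "P1", week = seq_len(nw),
                       k6_total = c(3L, 5L, 2L, 8L, 1L, 4L)[seq_len(nw)],
                       phq9_total = ifelse(seq_len(nw) %% 4L == 0L, 4L, NA))
  profiles <- data.frame(patient = "P1", gender = 1L, education = 2L,
                         occupation = 1L, marital = 4L, age = 40,
                         episodes = 4L, entry_date = entry)
  list(daily = daily, weekly = weekly, profiles = profiles)
}
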