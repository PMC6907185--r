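test_that("Little's test handles complete data as not applicable", {
  Y <- matrix(rnorm(100), 25, 4)
  out <- little_mcar_test(Y)
  expect_false(out$applicable)
  expect_identical(out$statistic, 0)
  expect_identical(out$df, 0L)
})

test_that("Little's statistic is invariant to affine rescaling of variables", {
  set.seed(21)
  Y <- matrix(rnorm(400), 100, 4)
  Y[runif(400) < 0.15] <- NA
  a <- little_mcar_test(Y)
  Ys <- sweep(sweep(Y, 2, c(2, -3, 0.5, 10), `*`), 2, c(1, 2, 3, 4), `+`)
  b <- little_mcar_test(Ys)
  # equal up to the EM stopping rule (scale changes the likelihood path)
  expect_lt(abs(a$statistic - b$statistic) / a$statistic, 1e-3)
  expect_identical(a$df, b$df)
})

test_that("Little's test has power against a mean shift in the missing stratum", {
  set.seed(22)
  rej <- 0L
  for (r in 1:20) {
    n <- 200
    y2 <- rnorm(n)
    y1 <- 0.8 * y2 + rnorm(n, 0, 0.6)
    y1[y2 > 0 & runif(n) < 0.6] <- NA       # MAR on the observed variable
    p <- little_mcar_test(cbind(y1, y2))$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej, 15L)
})

test_that("CDM variant conditions out covariate-driven missingness", {
  set.seed(23)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  d <- data.frame(x = x,
                  y1 = 1.5 * x + rnorm(n),
                  y2 = -1.0 * x + rnorm(n))
  d$y1[x == 1 & runif(n) < 0.5] <- NA       # missingness purely via x
  raw <- little_mcar_test(d[, c("y1", "y2")])
  cdm <- cdm_test(d, c("y1", "y2"), "x")
  expect_lt(raw$p.value, 0.01)
  expect_gt(cdm$p.value, 0.05)
  # complete data: not applicable
  expect_false(cdm_test(data.frame(x = x, y1 = rnorm(n)), "y1", "x")$applicable)
  # missing covariates are refused
  d$x[1] <- NA
  expect_error(cdm_test(d, c("y1", "y2"), "x"), "fully observed")
})

test_that("CDM on a null covariate matches the raw test closely", {
  set.seed(24)
  n <- 2000
  d <- data.frame(z = rnorm(n), y1 = rnorm(n), y2 = rnorm(n))
  d$y1[runif(n) < 0.2] <- NA
  raw <- little_mcar_test(d[, c("y1", "y2")])
  cdm <- cdm_test(d, c("y1", "y2"), "z")
  expect_lt(abs(cdm$statistic - raw$statistic), 0.1)
  expect_identical(cdm$df, raw$df)
})

test_that("weighted imputer solves the weighted normal equations", {
  d <- data.frame(x = c(0, 1, 2), y = c(0, 1, 5), w = c(1, 1, 3))
  m <- fit_weighted_imputer(d, "y", "x", "w")
  # hand-solved 2x2 weighted normal equations: intercept -9/16, slope 43/16
  expect_equal(unname(coef(m$fit)), c(-9 / 16, 43 / 16))
  # exact linear data: any weights recover slope 2, intercept 0
  d2 <- data.frame(x = 1:6, y = 2 * (1:6), w = c(1, 3, 2, 5, 1, 2))
  m2 <- fit_weighted_imputer(d2, "y", "x", "w")
  expect_equal(unname(coef(m2$fit)), c(0, 2), tolerance = 1e-10)
  # weight scale invariance
  d3 <- d; d3$w <- d$w * 17
  m3 <- fit_weighted_imputer(d3, "y", "x", "w")
  expect_equal(coef(m3$fit), coef(m$fit))
  # rank deficiency names the collinear column
  d4 <- data.frame(x = 1:5, x2 = 2 * (1:5), y = rnorm(5), w = 1)
  expect_error(fit_weighted_imputer(d4, "y", c("x", "x2"), "w"), "collinear")
  # non-positive weights are refused
  d5 <- d; d5$w[1] <- 0
  expect_error(fit_weighted_imputer(d5, "y", "x", "w"), "positive")
})

test_that("impute never touches observed cells and flags every filled one", {
  set.seed(25)
  d <- data.frame(x = rnorm(50), w = 1)
  d$y <- 3 + 2 * d$x + rnorm(50, 0, 0.1)
  miss <- c(3, 7, 20)
  truth <- d$y
  d$y[miss] <- NA
  m <- fit_weighted_imputer(d, "y", "x", "w")
  out <- impute(d, m)
  expect_identical(out$data$y[-miss], truth[-miss])
  expect_identical(which(out$imputed), as.integer(miss))
  expect_identical(out$n_imputed, 3L)
  # complete input: identity
  d2 <- d; d2$y <- truth
  out2 <- impute(d2, m)
  expect_identical(out2$data, d2)
  expect_identical(out2$n_imputed, 0L)
  # predictor missing on a row to impute: left missing, counted
  d3 <- d; d3$x[3] <- NA
  out3 <- impute(d3, m)
  expect_true(is.na(out3$data$y[3]))
  expect_identical(out3$n_unimputable, 1L)
  # range clipping
  mc <- fit_weighted_imputer(d, "y", "x", "w", range = c(0, 4))
  outc <- impute(d, mc)
  expect_true(all(outc$data$y[outc$imputed] <= 4))
})

test_that("regression imputation recovers a known K6~PHQ-9 slope under MAR", {
  set.seed(26)
  R <- 120
  slopes <- numeric(R)
  for (r in seq_len(R)) {
    n <- 300
    phq <- pmax(rnorm(n, 8, 3), 0)
    k6 <- 1 + 0.8 * phq + rnorm(n, 0, 1.5)
    d <- data.frame(phq = phq, k6 = k6, w = 1)
    d$k6[phq > 8 & runif(n) < 0.5] <- NA    # MAR given the predictor
    m <- fit_weighted_imputer(d, "k6", "phq", "w")
    full <- impute(d, m)$data
    slopes[r] <- coef(lm(k6 ~ phq, full))[2]
  }
  mc_se <- sd(slopes) / sqrt(R)
  expect_lt(abs(mean(slopes) - 0.8), 2 * mc_se + 1e-8)
})

test_that("panel imputation completes K6/UV/lunch and preserves observed data", {
  co <- simulate_cohort(cohort_config(n_patients = 25L, weeks = 30L,
                                      seed = 14L))
  p <- build_panel(co$daily, co$weekly, co$profiles)
  out <- impute_panel(p, co$profiles)
  d <- out$panel
  obs <- !is.na(p$k6_total)
  expect_identical(d$k6_total[obs], as.numeric(p$k6_total[obs]))
  expect_true(all(d$k6_total >= 0 & d$k6_total <= 24, na.rm = TRUE))
  # bookkeeping: imputed + still-missing = missing before
  expect_identical(sum(d$imp_k6) + sum(is.na(d$k6_total)),
                   sum(is.na(p$k6_total)))
  expect_true(all(!is.na(d$y[d$imp_k6])))
})
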