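test_that("forward orthogonal deviations match direct evaluation", {
  expect_equal(fod(c(1, 2, 3)),
               c((1 - 2.5) * sqrt(2 / 3), (2 - 3) * sqrt(1 / 2), NA))
  # constant series is annihilated
  expect_equal(fod(rep(7, 10))[1:9], rep(0, 9))
  # shift invariance
  set.seed(41)
  x <- rnorm(20)
  expect_equal(fod(x + 10), fod(x))
  # short series: nothing to transform
  expect_true(all(is.na(fod(3))))
  # gaps: future mean uses available values only
  x <- c(1, NA, 3, 5)
  f <- fod(x)
  expect_equal(f[1], sqrt(2 / 3) * (1 - 4))
  expect_true(is.na(f[2]))
})

test_that("FOD annihilates arbitrary patient constants to machine precision", {
  set.seed(42)
  for (r in 1:10) {
    pan <- simulate_pvar_panel(6, 15, A2x2(), sigma = c(1, 1),
                               mu = matrix(0, 6, 2), burn_in = 5)
    shifted <- pan
    offs <- rnorm(6, 0, 50)
    shifted$V1 <- shifted$V1 + offs[shifted$patient]
    shifted$V2 <- shifted$V2 + offs[shifted$patient] * 2
    for (pid in 1:6) {
      a <- fod(pan$V1[pan$patient == pid])
      b <- fod(shifted$V1[shifted$patient == pid])
      expect_equal(a, b, tolerance = 1e-12)
    }
    # the FOD design matrices (responses and regressors) are identical;
    # the level instruments shift, which is why the fixed effect must be
    # removed by the transform rather than by the instruments
    d1 <- lifelogpvar:::pvar_design(pan, c("V1", "V2"), lags = 1)
    d2 <- lifelogpvar:::pvar_design(shifted, c("V1", "V2"), lags = 1)
    expect_equal(d1$Y, d2$Y, tolerance = 1e-12)
    expect_equal(d1$X, d2$X, tolerance = 1e-12)
  }
})

test_that("instrument matrix holds collapsed zero-filled lagged levels", {
  set.seed(43)
  pan <- simulate_pvar_panel(3, 10, A2x2(), sigma = c(1, 1), mu = c(0, 0),
                             burn_in = 5)
  # spec configuration: start at lag p+1 with depth 1 -> the t-2 levels
  d <- lifelogpvar:::pvar_design(pan, c("V1", "V2"), lags = 1,
                                 inst_start = 2, inst_depth = 1)
  expect_identical(ncol(d$Z), 2L)            # depth x k columns
  p1 <- pan[pan$patient == 1, ]
  rows <- 2:9                                # t = 2..9 (t = 10 lost to FOD)
  zexp <- rbind(c(0, 0), as.matrix(p1[rows[-1] - 2, c("V1", "V2")]))
  expect_equal(unname(d$Z[1:8, ]), unname(zexp))
  # depth 0 is a misconfiguration
  expect_error(lifelogpvar:::pvar_design(pan, c("V1", "V2"), lags = 1,
                                         inst_depth = 0), "depth")
  # under-identification is caught
  expect_error(pvar(pan, c("V1", "V2"), lags = 2, inst_start = 2,
                    inst_depth = 1), "under-identified")
})

test_that("noiseless deterministic process is identified exactly", {
  A <- A2x2()
  # deterministic recursion from random start values, no noise
  set.seed(44)
  mk <- function() {
    y <- matrix(0, 20, 2)
    y[1, ] <- rnorm(2)
    for (t in 2:20) y[t, ] <- drop(y[t - 1, , drop = FALSE] %*% A[[1]])
    y
  }
  pan <- do.call(rbind, lapply(1:4, function(i) {
    y <- mk()
    data.frame(patient = i, week = 1:20, V1 = y[, 1], V2 = y[, 2])
  }))
  fit <- pvar(pan, c("V1", "V2"), lags = 1)
  expect_equal(unname(fit$A[[1]]), unname(A[[1]]), tolerance = 1e-8)
  expect_equal(fit$cd, 1, tolerance = 1e-8)
})

test_that("estimation is deterministic for identical inputs", {
  set.seed(45)
  pan <- simulate_pvar_panel(10, 15, A2x2(), sigma = c(1, 1), mu = c(0, 0))
  f1 <- pvar(pan, c("V1", "V2"), lags = 1)
  f2 <- pvar(pan, c("V1", "V2"), lags = 1)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("CD follows the determinant formula on constructed cases", {
  expect_equal(compute_cd(matrix(0, 2, 2), diag(2)), 1)
  expect_equal(compute_cd(diag(2), diag(2)), 0)
  expect_equal(compute_cd(diag(0.5, 2), diag(2)), 0.75)
  expect_error(compute_cd(diag(2), matrix(0, 2, 2)), "singular")
})

test_that("companion eigenvalues match closed forms", {
  s <- var_stability(list(diag(0.5, 3)))
  expect_equal(s$moduli, rep(0.5, 3))
  expect_true(s$stable)
  s1 <- var_stability(list(diag(1, 2)))
  expect_equal(max(s1$moduli), 1)
  expect_false(s1$stable)
  # k=1, p=2: companion [[0.5, 0.3], [1, 0]], quadratic roots
  s2 <- var_stability(list(matrix(0.5), matrix(0.3)))
  roots <- sort(c((0.5 + sqrt(1.45)) / 2, abs((0.5 - sqrt(1.45)) / 2)),
                decreasing = TRUE)
  expect_equal(s2$moduli, roots, tolerance = 1e-10)
  expect_true(s2$stable)
})

test_that("CD and stability agree with brute-force recomputation from the fit", {
  set.seed(46)
  pan <- simulate_pvar_panel(20, 25, A2x2(), sigma = c(1, 1),
                             mu = matrix(rnorm(40), 20, 2))
  fit <- pvar(pan, c("V1", "V2"), lags = 1)
  E <- residuals(fit)
  n <- nrow(E)
  se <- crossprod(E) / n
  expect_equal(unname(fit$sigma_e), unname(se))
  expect_equal(fit$cd, 1 - det(se) / det(fit$sigma_y))
  # companion matrix rebuilt by hand
  comp <- t(fit$A[[1]])
  expect_equal(fit$moduli, sort(Mod(eigen(comp)$values), decreasing = TRUE))
  expect_identical(fit$stable, max(fit$moduli) < 1 - 1e-8)
})

test_that("lag selection reports a full CD table and picks a stable order", {
  set.seed(47)
  pan <- simulate_pvar_panel(40, 40, A2x2(), sigma = c(1, 1),
                             mu = matrix(rnorm(80), 40, 2))
  sel <- select_lag(pan, c("V1", "V2"), p_max = 3)
  expect_identical(nrow(sel$table), 3L)
  expect_true(all(sel$table$stable))
  expect_identical(sel$selected,
                   sel$table$p[which.max(sel$table$CD)])
  # VAR(1) truth: CD gain beyond p=1 is small on the common sample
  expect_lt(max(sel$table$CD) - sel$table$CD[1], 0.02)
  # p_max = 1 trivially selects 1
  expect_identical(select_lag(pan, c("V1", "V2"), p_max = 1)$selected, 1L)
})

test_that("fit object methods expose coefficients, residuals and predictions", {
  set.seed(48)
  pan <- simulate_pvar_panel(15, 20, A2x2(), sigma = c(1, 1), mu = c(0, 0))
  fit <- pvar(pan, c("V1", "V2"), lags = 1)
  expect_s3_class(fit, "pvar")
  expect_identical(dim(coef(fit)), c(2L, 2L))
  expect_identical(dim(residuals(fit)), dim(fitted(fit)))
  expect_output(print(fit), "Panel VAR")
  expect_output(print(summary(fit)), "standard errors")
  # one-step prediction equals the linear recursion
  h <- matrix(c(1, 2), 1, 2)
  expect_equal(unname(predict(fit, h)), unname(drop(h %*% fit$A[[1]])))
  # simulate() round-trips through the generator only for stable fits
  sim <- simulate(fit, nsim = 2, seed = 1, nweeks = 10)
  expect_identical(nrow(sim), 20L)
})
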