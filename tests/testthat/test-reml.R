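test_that("REML with an iid error model gives the unbiased variance
           estimator, d = n - k, and the classical OLS interval", {
  set.seed(61)
  dat <- make_its_data(40)
  fit <- its_fit(y ~ x + time, dat, method = "reml", order = c(0, 0))
  ols <- its_fit(y ~ x + time, dat, method = "ols")
  expect_equal(fit$sigma2, sum(residuals(ols)^2) / 37, tolerance = 1e-10)
  expect_equal(fit$extras$d, 37)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
  expect_equal(fit$ci, ols$ci, tolerance = 1e-6)
  sat <- satterthwaite_df(fit)
  expect_equal(sat$d, 37)
  expect_equal(sat$var_phi, 2 * sat$phi^2 / 37)
})

test_that("REML estimates agree with the nlme::gls oracle", {
  skip_if_not_installed("nlme")
  set.seed(62)
  dat <- make_its_data(30, theta = c(0.6, 0.4, 0.2))
  g <- nlme::gls(y ~ x + time, dat,
                 correlation = nlme::corARMA(p = 0, q = 3),
                 method = "REML")
  fit <- its_fit(y ~ x + time, dat, method = "reml", order = c(0, 3),
                 kr = FALSE)
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-4)
  expect_equal(unname(fit$extras$theta),
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  # nlme reports the marginal error variance sigma^2 * (1 + sum theta^2)
  expect_equal(fit$sigma2 * (1 + sum(fit$extras$theta^2)), g$sigma^2,
               tolerance = 1e-3)
  expect_equal(fit$extras$se_unadj, sqrt(diag(vcov(g)))[["x"]],
               tolerance = 1e-4)

  # AR(1) error model against the corAR1 oracle
  dat2 <- make_its_data(40, theta = c(0.9, 0.6, 0.3))
  g2 <- nlme::gls(y ~ x + time, dat2, correlation = nlme::corAR1(),
                  method = "REML")
  fit2 <- its_fit(y ~ x + time, dat2, method = "reml", order = c(1, 0),
                  kr = FALSE)
  expect_equal(unname(coef(fit2)), unname(coef(g2)), tolerance = 1e-4)
  expect_equal(fit2$extras$phi_ar,
               unname(coef(g2$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
})

test_that("Satterthwaite df is invariant to rescaling the outcome", {
  set.seed(63)
  dat <- make_its_data(30, theta = c(0.5, 0.3, 0.1))
  f1 <- its_fit(y ~ x + time, dat, method = "reml", order = c(0, 3))
  dat$y <- 10 * dat$y
  f2 <- its_fit(y ~ x + time, dat, method = "reml", order = c(0, 3))
  expect_equal(f2$extras$d, f1$extras$d, tolerance = 1e-3)
})

test_that("REML error-model estimates are less downward-biased than ML", {
  set.seed(64)
  nrep <- 150
  th_ml <- th_reml <- matrix(NA_real_, nrep, 3)
  X <- model.matrix(its_design(20))
  truth <- c(0.6, 0.4, 0.2)
  for (i in seq_len(nrep)) {
    dat <- make_its_data(20, theta = truth)
    ml <- itsreg:::.fit_arma(X, dat$y, 0L, 3L)
    rm_ <- tryCatch(itsreg:::.reml_state(X, dat$y, 0L, 3L),
                    error = function(e) NULL)
    if (!ml$converged || is.null(rm_) || !isTRUE(rm_$ok)) next
    th_ml[i, ] <- ml$extras$theta
    th_reml[i, ] <- rm_$theta
  }
  ok <- stats::complete.cases(th_ml) & stats::complete.cases(th_reml)
  med_ml <- apply(th_ml[ok, ], 2, median)
  med_reml <- apply(th_reml[ok, ], 2, median)
  # ML medians sit below the truth; REML medians sit closer to it
  expect_true(all(med_ml < truth))
  expect_true(sum(abs(med_reml - truth) < abs(med_ml - truth)) >= 2)
})

test_that("REML and ML intervention estimates agree on moderately long
           series", {
  set.seed(65)
  dat <- make_its_data(300, theta = c(0.6, 0.3, 0.1))
  X <- model.matrix(its_design(300))
  ml <- itsreg:::.fit_arma(X, dat$y, 0L, 3L)
  rml <- itsreg:::.reml_state(X, dat$y, 0L, 3L)
  expect_equal(unname(rml$beta["x"]), unname(ml$coefficients["x"]),
               tolerance = 1e-2)
})

test_that("the Kenward-Roger adjustment inflates the SE", {
  set.seed(66)
  nrep <- 60
  bigger <- logical(nrep)
  X <- model.matrix(its_design(20))
  for (i in seq_len(nrep)) {
    dat <- make_its_data(20, theta = c(0.4, 0.2, 0.1))
    f <- tryCatch(
      itsreg:::.fit_reml(X, dat$y, p = 0L, q = 3L, kr = TRUE),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) { bigger[i] <- NA; next }
    bigger[i] <- f$se["x"] >= f$extras$se_unadj - 1e-10
  }
  expect_gt(mean(bigger, na.rm = TRUE), 0.9)
})

test_that("restricted likelihood is invariant to translating the response
           by a column span of the design", {
  set.seed(67)
  dat <- make_its_data(30, theta = c(0.5, 0.2, 0.1))
  X <- model.matrix(its_design(30))
  s1 <- itsreg:::.reml_state(X, dat$y, 0L, 3L)
  s2 <- itsreg:::.reml_state(X, dat$y + drop(X %*% c(5, -2, 0.3)), 0L, 3L)
  expect_equal(s1$theta, s2$theta, tolerance = 1e-5)
  expect_equal(s1$sigma2, s2$sigma2, tolerance = 1e-5)
})

test_that("REML on very short series surfaces failure instead of crashing", {
  set.seed(68)
  dat <- make_its_data(12, theta = c(0.9, 0.8, 0.7))
  fit <- its_fit(y ~ x + time, dat, method = "reml", order = c(0, 3))
  expect_s3_class(fit, "its_fit")
  expect_type(fit$converged, "logical")
  expect_error(its_fit(y ~ x + time, make_its_data(8), method = "reml",
                       order = c(2, 3)),
               "too short")
})

test_that("MA error-model REML df is below n - k under estimated
           autocorrelation but stays positive", {
  set.seed(69)
  dat <- make_its_data(50)
  f <- its_fit(y ~ x + time, dat, method = "reml", order = c(0, 3))
  expect_gt(f$extras$d, 0)
  expect_lt(f$extras$d, 47)
})
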