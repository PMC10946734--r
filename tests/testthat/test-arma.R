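test_that("conditional likelihood reduces to the iid regression likelihood
           when p = q = 0", {
  set.seed(41)
  dat <- make_its_data(30)
  X <- model.matrix(its_design(30))
  beta <- c(4, -1, -1 / 30)
  ll <- arma_conditional_loglik(dat$y, X, beta, sigma2 = 1.3)
  eps <- dat$y - drop(X %*% beta)
  expect_equal(ll, sum(dnorm(eps, 0, sqrt(1.3), log = TRUE)))
  # and equals the exact likelihood in that case
  expect_equal(ll, arma_exact_loglik(dat$y, X, beta, sigma2 = 1.3),
               tolerance = 1e-10)
})

test_that("conditional MA(1) likelihood follows the innovation recursion
           term by term", {
  set.seed(42)
  y <- c(3.9, 3.1, 4.4)
  X <- cbind(1, c(0, 0, 1))
  beta <- c(4, -1); th <- 0.5; s2 <- 1.2
  # eta_{-1} = 0, so eps0 = eta0; eta1 = eps1 - th*eps0;
  # eta2 = eps2 - th*eta1 = eps2 - th*(eps1 - th*eps0)
  eps <- y - drop(X %*% beta)
  eta <- c(eps[1], eps[2] - th * eps[1],
           eps[3] - th * (eps[2] - th * eps[1]))
  expect_equal(arma_conditional_loglik(y, X, beta, theta = th, sigma2 = s2),
               sum(dnorm(eta, 0, sqrt(s2), log = TRUE)))
})

test_that("non-invertible MA recursion is detected and flagged", {
  set.seed(43)
  dat <- make_its_data(200)
  X <- model.matrix(its_design(200))
  expect_warning(
    ll <- arma_conditional_loglik(dat$y, X, c(4, -1, -0.005), theta = 3,
                                  sigma2 = 1),
    "explosive")
  expect_identical(ll, -Inf)
})

test_that("exact likelihood equals the dense multivariate-normal oracle", {
  set.seed(44)
  for (i in 1:5) {
    n <- sample(c(25, 50, 100), 1)
    theta <- runif(3, -0.5, 0.9)
    s2 <- runif(1, 0.5, 2)
    dat <- make_its_data(n, theta = pmax(theta, 0))
    X <- model.matrix(its_design(n))
    beta <- c(3.5, -0.8, -0.01)
    V <- ma_cov_oracle(theta, s2, n)
    expect_equal(
      arma_exact_loglik(dat$y, X, beta, theta = theta, sigma2 = s2),
      mvn_loglik_oracle(dat$y, drop(X %*% beta), V),
      tolerance = 1e-6)
  }
  # ARMA(1,1): psi-weight autocovariance against a brute-force psi sum
  phi <- 0.6; th <- 0.4
  g <- arma_autocov(phi = phi, theta = th, sigma2 = 1, lag_max = 3)
  psi <- c(1, ARMAtoMA(ar = phi, ma = th, lag.max = 2000))
  g_bf <- sapply(0:3, function(k) sum(psi[1:(2000 - k)] * psi[(1 + k):2000]))
  expect_equal(g, g_bf, tolerance = 1e-8)
})

test_that("conditional and exact likelihoods agree per observation on long
           series", {
  set.seed(45)
  n <- 4000
  dat <- make_its_data(n, theta = c(0.6, 0.3, 0.1))
  X <- model.matrix(its_design(n))
  beta <- c(4, -1, -1 / n)
  th <- c(0.6, 0.3, 0.1)
  lc <- arma_conditional_loglik(dat$y, X, beta, theta = th, sigma2 = 1)
  le <- arma_exact_loglik(dat$y, X, beta, theta = th, sigma2 = 1)
  expect_lt(abs(lc - le) / n, 1e-3)
})

test_that("the exact likelihood is maximised near the true parameters", {
  set.seed(46)
  n <- 200
  better <- logical(50)
  X <- model.matrix(its_design(n))
  for (i in 1:50) {
    dat <- make_its_data(n, theta = c(0.8, 0.5, 0.2))
    at_truth <- arma_exact_loglik(dat$y, X, c(4, -1, -1 / n),
                                  theta = c(0.8, 0.5, 0.2), sigma2 = 1)
    perturbed <- arma_exact_loglik(dat$y, X, c(4, -1, -1 / n),
                                   theta = c(0.3, 0.1, 0), sigma2 = 1.5)
    better[i] <- at_truth > perturbed
  }
  expect_gt(mean(better), 0.9)
})

test_that("ARMA(0,0) maximum likelihood equals OLS with the ML variance", {
  set.seed(47)
  dat <- make_its_data(60)
  fit <- its_fit(y ~ x + time, dat, method = "arma", order = c(0, 0))
  ols <- its_fit(y ~ x + time, dat, method = "ols")
  expect_equal(coef(fit), coef(ols), tolerance = 1e-6)
  expect_equal(fit$sigma2, sum(residuals(ols)^2) / 60, tolerance = 1e-4)
})

test_that("the Kalman-filter likelihood agrees with the dense exact
           likelihood at the fitted parameters", {
  set.seed(48)
  dat <- make_its_data(60, theta = c(0.7, 0.4, 0.2))
  fit <- its_fit(y ~ x + time, dat, method = "ma", order = 3)
  X <- fit$X
  expect_equal(
    fit$loglik,
    arma_exact_loglik(dat$y, X, coef(fit), theta = fit$extras$theta,
                      sigma2 = fit$sigma2),
    tolerance = 1e-4)
})

test_that("AICc applies the small-sample penalty to the AIC", {
  set.seed(49)
  dat <- make_its_data(50, theta = c(0.4, 0.2, 0))
  fit <- its_fit(y ~ x + time, dat, method = "arma", order = c(0, 0))
  k <- 4  # intercept, x, time, sigma2
  expect_equal(fit$extras$aicc,
               -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (50 - k - 1))
  # the penalty at n = 50, k = 5 is 2*5*6/44
  expect_equal(itsreg:::.aicc(0, 5, 50), 10 + 2 * 5 * 6 / 44)
})

test_that("stepwise AICc selection respects the order constraint and
           prefers white noise for independent errors", {
  set.seed(50)
  picks <- matrix(NA_integer_, 30, 2)
  X <- model.matrix(its_design(200))
  for (i in 1:30) {
    y <- drop(X %*% c(4, -1, -0.005)) + rnorm(200)
    sel <- arma_select(X, y)
    picks[i, ] <- c(sel$p, sel$q)
  }
  expect_true(all(picks <= 5))
  expect_gt(mean(picks[, 1] == 0 & picks[, 2] == 0), 0.5)
})

test_that("true-model MA(3) fits recover the generating coefficients", {
  set.seed(51)
  th_hat <- matrix(NA_real_, 50, 3)
  X <- model.matrix(its_design(300))
  for (i in 1:50) {
    dat <- make_its_data(300, theta = c(0.8, 0.5, 0.2))
    fit <- itsreg:::.fit_arma(X, dat$y, 0L, 3L)
    th_hat[i, ] <- fit$extras$theta
  }
  expect_equal(colMeans(th_hat), c(0.8, 0.5, 0.2), tolerance = 0.05)
})
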