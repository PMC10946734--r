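# Independent oracles used across the test files.  These deliberately use
# different code paths from the package implementation (explicit matrix
# inverses, determinant(), stats::lm) so agreement is a genuine
# cross-check.

# Explicit-inverse GLS with AR(1) covariance Sigma_ij = phi^|i-j|/(1-phi^2).
gls_ar1_oracle <- function(X, y, phi) {
  n <- nrow(X)
  Sigma <- toeplitz(phi^(0:(n - 1))) / (1 - phi^2)
  Si <- solve(Sigma)
  A <- solve(t(X) %*% Si %*% X)
  beta <- unname(drop(A %*% t(X) %*% Si %*% y))
  r <- y - drop(X %*% beta)
  sigma2 <- drop(t(r) %*% Si %*% r) / (n - ncol(X))
  list(beta = beta, vcov = unname(sigma2 * A))
}

# Dense multivariate-normal log-density with explicit inverse and
# determinant() (the package uses a Cholesky factorisation instead).
mvn_loglik_oracle <- function(y, mean, V) {
  n <- length(y)
  r <- y - mean
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(V) %*% r))
}

# MA(q) covariance matrix assembled directly from the defining recursion
# gamma_k = sigma2 * sum th_i th_{i+k} (with th_0 = 1), independent of
# arma_autocov's psi-weight route.
ma_cov_oracle <- function(theta, sigma2, n) {
  th <- c(1, theta)
  q <- length(theta)
  g <- sapply(0:(n - 1), function(k) {
    if (k > q) return(0)
    sigma2 * sum(th[1:(q + 1 - k)] * th[(1 + k):(q + 1)])
  })
  toeplitz(g)
}

# Segmented-regression test data with MA(3) errors, built inline (not via
# the package generator) for fixtures where independence matters.
make_its_data <- function(n, theta = c(0, 0, 0), beta = c(4, -1, -1 / n),
                          tau = n %/% 2) {
  x <- as.numeric(seq_len(n) - 1 >= tau)
  tt <- 0:(n - 1)
  th <- c(theta, rep(0, 3 - length(theta)))
  h <- rnorm(n + 3)
  eps <- h[4:(n + 3)] + th[1] * h[3:(n + 2)] + th[2] * h[2:(n + 1)] +
    th[3] * h[1:n]
  data.frame(time = tt, x = x, y = beta[1] + beta[2] * x + beta[3] * tt + eps)
}
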