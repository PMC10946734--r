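#' Autocovariance function of a stationary ARMA process
#'
#' Autocovariances \eqn{\gamma_0, ..., \gamma_{lag\_max}} of the ARMA(p,q)
#' process
#' \eqn{\epsilon_t = \phi_1\epsilon_{t-1} + \dots + \phi_p\epsilon_{t-p} +
#' \eta_t + \theta_1\eta_{t-1} + \dots + \theta_q\eta_{t-q}},
#' computed from the infinite moving-average representation
#' \eqn{\gamma_k = \sigma^2 \sum_j \psi_j \psi_{j+k}} with the
#' \eqn{\psi}-weights truncated far into their geometric decay.  Exact for
#' pure MA models.
#'
#' @param phi AR coefficients (possibly empty).
#' @param theta MA coefficients (possibly empty).
#' @param sigma2 Innovation variance.
#' @param lag_max Largest lag required.
#' @return Numeric vector `gamma[0..lag_max]`.
#' @export
arma_autocov <- function(phi = numeric(), theta = numeric(), sigma2 = 1,
                         lag_max = 0) {
  p <- length(phi); q <- length(theta)
  if (p > 0 && any(Mod(polyroot(c(1, -phi))) <= 1 + 1e-10))
    stop("AR polynomial has roots on or inside the unit circle")
  L <- lag_max + q + if (p > 0) 500L else 0L
  psi <- c(1, if (L > 0) ARMAtoMA(ar = phi, ma = theta, lag.max = L))
  vapply(0:lag_max, function(k) {
    idx <- seq_len(length(psi) - k)
    sigma2 * sum(psi[idx] * psi[idx + k])
  }, numeric(1))
}

#' Conditional log-likelihood of regression with ARMA errors
#'
#' Gaussian log-likelihood conditional on the first `p` errors and with
#' pre-sample innovations fixed at zero: the errors
#' \eqn{\epsilon_t = y_t - X_t\beta} are held at their observed values
#' for `t < p`, the innovations are recovered recursively as
#' \deqn{\eta_t = \epsilon_t - \sum_i \phi_i \epsilon_{t-i}
#'       - \sum_j \theta_j \eta_{t-j},}
#' and the normal density of \eqn{\eta_t} is summed over `t = p, ..., n-1`.
#'
#' @param y Response vector.
#' @param X Design matrix.
#' @param beta Regression coefficients.
#' @param phi,theta ARMA coefficients.
#' @param sigma2 Innovation variance.
#' @return Log-likelihood value.  A non-invertible MA part can make the
#'   recursion explosive; this is detected and returned as `-Inf` with a
#'   warning.
#' @export
arma_conditional_loglik <- function(y, X, beta, phi = numeric(),
                                    theta = numeric(), sigma2) {
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  eps <- y - drop(as.matrix(X) %*% beta)
  n <- length(eps)
  p <- length(phi); q <- length(theta)
  if (n <= p + q) stop("series too short for the requested orders")
  eta <- numeric(n)
  for (t in seq.int(p + 1L, n)) {
    ar <- if (p > 0) sum(phi * eps[t - seq_len(p)]) else 0
    ma <- 0
    if (q > 0) {
      lags <- t - seq_len(q)
      valid <- lags >= p + 1L   # pre-sample innovations fixed at zero
      if (any(valid))
        ma <- sum(theta[valid] * eta[lags[valid]])
    }
    eta[t] <- eps[t] - ar - ma
  }
  use <- seq.int(p + 1L, n)
  if (max(abs(eta[use])) > 1e8 * (1 + max(abs(eps)))) {
    warning("explosive innovation recursion (non-invertible MA part?)")
    return(-Inf)
  }
  sum(dnorm(eta[use], mean = 0, sd = sqrt(sigma2), log = TRUE))
}

#' Exact log-likelihood of regression with ARMA errors
#'
#' Full Gaussian log-likelihood of
#' \eqn{y \sim N(X\beta, \Sigma)} where \eqn{\Sigma} is the stationary
#' ARMA(p,q) autocovariance matrix, evaluated through the Cholesky factor
#' of the dense Toeplitz covariance built from [arma_autocov()].
#'
#' @inheritParams arma_conditional_loglik
#' @return Log-likelihood value.
#' @export
arma_exact_loglik <- function(y, X, beta, phi = numeric(),
                              theta = numeric(), sigma2) {
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  n <- length(y)
  g <- arma_autocov(phi, theta, sigma2 = sigma2, lag_max = n - 1L)
  V <- toeplitz(g)
  L <- chol(V)
  r <- y - drop(as.matrix(X) %*% beta)
  z <- backsolve(L, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Bias-corrected AIC; k counts all free parameters (ARMA coefficients,
# regression coefficients and the innovation variance).
.aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Reject fitted ARMA polynomials with roots (numerically) on the unit
# circle: near-cancelling or boundary fits produce unusable variance
# estimates, and automatic selection software excludes them.
.arma_roots_ok <- function(fit, p, q, tol = 1.001) {
  co <- coef(fit)
  if (p > 0 && any(Mod(polyroot(c(1, -co[seq_len(p)]))) < tol))
    return(FALSE)
  if (q > 0 && any(Mod(polyroot(c(1, co[p + seq_len(q)]))) < tol))
    return(FALSE)
  TRUE
}

# Regression with ARMA(p,q) errors by maximum likelihood via stats::arima
# (Kalman-filter exact likelihood, CSS starting values).  Returns NULL on
# optimiser failure so callers can skip the candidate.
.arima_fit <- function(X, y, p, q, method = "CSS-ML") {
  xreg <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(arima(y, order = c(p, 0L, q), xreg = xreg,
                           include.mean = TRUE, method = method)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit
}

# Lean fit record from an ARMA-error regression.  dist = "normal" uses
# standard-normal CIs (the convention of ARMA software); "t" uses n - k.
.fit_arma <- function(X, y, p, q, dist = "normal", level = 0.95,
                      method_tag = sprintf("arma(%d,%d)", p, q),
                      arima_method = "CSS-ML") {
  n <- length(y)
  fit <- .arima_fit(X, y, p, q, method = arima_method)
  k_reg <- ncol(X)
  cn <- colnames(X)
  if (is.null(fit)) {
    beta <- setNames(rep(NA_real_, k_reg), cn)
    return(.fit_record(method_tag, beta, matrix(NA_real_, k_reg, k_reg),
                       df = Inf, level = level, converged = FALSE,
                       extras = list(p = p, q = q)))
  }
  co <- coef(fit)
  reg_names <- c("intercept", setdiff(cn, "(Intercept)"))
  beta <- co[reg_names]
  names(beta) <- cn
  V <- fit$var.coef
  vb <- matrix(NA_real_, k_reg, k_reg, dimnames = list(cn, cn))
  ok <- all(reg_names %in% rownames(V))
  if (ok) vb <- V[reg_names, reg_names, drop = FALSE]
  dimnames(vb) <- list(cn, cn)
  converged <- ok && all(is.finite(diag(vb))) && all(diag(vb) >= 0)
  kfree <- length(co) + 1L
  df <- if (identical(dist, "t")) n - k_reg else Inf
  .fit_record(method_tag, beta, vb, df = df, level = level,
              resid = as.numeric(fit$residuals), sigma2 = fit$sigma2,
              converged = converged, loglik = fit$loglik,
              extras = list(p = p, q = q,
                            phi = if (p) co[seq_len(p)] else numeric(),
                            theta = if (q) co[p + seq_len(q)] else numeric(),
                            aicc = .aicc(fit$loglik, kfree, n)))
}

#' Stepwise AICc selection of an ARMA error model
#'
#' Hyndman-Khandakar-style stepwise search over ARMA(p,q) error models for
#' the regression of `y` on the columns of `X` (no differencing, no
#' seasonality).  The search starts from the candidate set
#' (0,0), (1,0), (0,1), (2,2), then repeatedly moves to the neighbour
#' (each of p and/or q changed by one, clipped to `[0, max_p] x [0, max_q]`)
#' with the smallest bias-corrected AIC until no neighbour improves.
#' Ties are broken in favour of fewer parameters (smaller `p + q`, then
#' smaller `q`).  Candidate fits that fail to converge, have unusable
#' variance estimates, or have AR/MA roots numerically on the unit circle
#' (near-cancelling boundary fits) are skipped.
#'
#' Candidate models are fitted by full maximum likelihood throughout:
#' conditional-sum-of-squares likelihoods are not comparable across
#' different AR orders (the conditioning set changes), which inflates the
#' selected orders if used for the comparison.
#'
#' @param X Design matrix (with intercept column).
#' @param y Response vector.
#' @param max_p,max_q Largest orders considered (default 5).
#' @return List with elements `p`, `q`, `aicc`, `trace` (data frame of
#'   visited models) and `fit` (the winning fit record).
#' @export
arma_select <- function(X, y, max_p = 5L, max_q = 5L) {
  n <- length(y)
  search_method <- "CSS-ML"
  cache <- new.env(parent = emptyenv())
  try_pq <- function(p, q) {
    key <- paste(p, q)
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- .arima_fit(X, y, p, q, method = search_method)
    aicc <- if (is.null(fit) || !.arma_roots_ok(fit, p, q) ||
                any(!is.finite(diag(fit$var.coef)))) Inf
            else .aicc(fit$loglik, length(coef(fit)) + 1L, n)
    rec <- list(p = p, q = q, aicc = aicc)
    cache[[key]] <- rec
    rec
  }
  better <- function(a, b) {
    # TRUE if candidate a beats incumbent b (AICc, then parsimony)
    if (a$aicc < b$aicc - 1e-8) return(TRUE)
    if (a$aicc > b$aicc + 1e-8) return(FALSE)
    if (a$p + a$q != b$p + b$q) return(a$p + a$q < b$p + b$q)
    a$q < b$q
  }
  start <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(2L, 2L))
  best <- NULL
  for (pq in start) {
    if (pq[1] > max_p || pq[2] > max_q) next
    cand <- try_pq(pq[1], pq[2])
    if (is.null(best) || better(cand, best)) best <- cand
  }
  if (!is.finite(best$aicc)) {
    cand <- try_pq(0L, 0L)
    if (!is.finite(cand$aicc))
      stop("all candidate ARMA models failed to fit")
  }
  repeat {
    p <- best$p; q <- best$q
    moves <- list(c(p - 1, q), c(p + 1, q), c(p, q - 1), c(p, q + 1),
                  c(p - 1, q - 1), c(p + 1, q + 1),
                  c(p - 1, q + 1), c(p + 1, q - 1))
    improved <- FALSE
    for (z in moves) {
      if (z[1] < 0 || z[1] > max_p || z[2] < 0 || z[2] > max_q) next
      cand <- try_pq(z[1], z[2])
      if (better(cand, best)) { best <- cand; improved <- TRUE }
    }
    if (!improved) break
  }
  trace <- do.call(rbind, lapply(ls(cache), function(k) {
    r <- cache[[k]]
    data.frame(p = r$p, q = r$q, aicc = r$aicc)
  }))
  fit <- .fit_arma(X, y, best$p, best$q, method_tag = "arma",
                   arima_method = "CSS-ML")
  list(p = best$p, q = best$q, aicc = best$aicc, trace = trace, fit = fit)
}
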