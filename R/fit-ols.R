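# Core OLS machinery shared by all fitters.  Returns coefficient vector,
# unscaled (X'X)^{-1}, residuals and the classical variance pieces.
.ols_core <- function(X, y) {
  .check_full_rank(X)
  qrx <- qr(X)
  beta <- qr.coef(qrx, y)
  resid <- y - drop(X %*% beta)
  n <- nrow(X); k <- ncol(X)
  rss <- sum(resid^2)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(qr.R(qrx))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  list(beta = beta, resid = resid, rss = rss, sigma2 = sigma2,
       XtXinv = XtXinv, n = n, k = k, df = n - k)
}

#' Lag-truncation rules for the Newey-West variance estimator
#'
#' Deterministic choices of the maximum lag `m` entering the Bartlett
#' kernel: `"n_quarter"` uses \eqn{\lfloor n^{1/4} \rfloor};
#' `"nw_simple"` uses \eqn{\lfloor 0.75\, n^{1/3} \rfloor} (a
#' simplification of the data-dependent rule assuming AR(1) correlation
#' 0.25); `"fixed_b"` uses \eqn{\lfloor 1.3\, n^{1/2} \rfloor} (intended
#' for use with fixed-b critical values, which are not implemented here;
#' only the bandwidth rule is provided); `"fixed"` returns `m` as given.
#' The integer part (floor) is used in every rule.  For the
#' data-dependent automatic rule see [nw_auto_lag()].
#'
#' @param n Series length (at least 4).
#' @param rule One of `"n_quarter"`, `"nw_simple"`, `"fixed_b"`, `"fixed"`.
#' @param m Lag to use when `rule = "fixed"`.
#' @return Integer lag truncation, `0 <= m < n`.
#' @examples
#' select_lag(100, "nw_simple")  # 3
#' select_lag(100, "fixed_b")    # 13
#' @export
select_lag <- function(n, rule = c("n_quarter", "nw_simple", "fixed_b",
                                   "fixed"), m = NULL) {
  rule <- match.arg(rule)
  if (n < 4) stop("'n' must be at least 4")
  m <- switch(rule,
    n_quarter = floor(n^0.25),
    nw_simple = floor(0.75 * n^(1 / 3)),
    fixed_b   = floor(1.3 * sqrt(n)),
    fixed     = {
      if (is.null(m)) stop("rule = \"fixed\" requires 'm'")
      as.integer(m)
    })
  m <- as.integer(m)
  if (m < 0L || m >= n)
    stop(sprintf("lag truncation m = %d outside [0, n)", m))
  m
}

#' Automatic lag selection for the Newey-West estimator
#'
#' Data-dependent plug-in bandwidth for the Bartlett-kernel HAC variance:
#' the regression scores are collapsed to a single series
#' \eqn{v_t = \sum_j w_j X_{tj} \hat\epsilon_t} (weights 1 for every
#' column except the intercept, which gets 0), autocovariances
#' \eqn{\hat\sigma_j} of \eqn{v_t} are accumulated up to the pilot lag
#' \eqn{l = \lfloor 4 (n/100)^{2/9} \rfloor}, and the lag is
#' \deqn{m = \lfloor 1.1447\, ((\hat s_1/\hat s_0)^2)^{1/3}\, n^{1/3} \rfloor}
#' with \eqn{\hat s_0 = \hat\sigma_0 + 2\sum_{j=1}^{l}\hat\sigma_j} and
#' \eqn{\hat s_1 = 2\sum_{j=1}^{l} j\,\hat\sigma_j}, clipped to
#' `[0, n - 1]`.
#'
#' @param X Design matrix used in the OLS fit.
#' @param resid OLS residuals.
#' @param weights Optional weight vector for collapsing the score columns;
#'   defaults to 1 everywhere except an intercept column.
#' @return Integer lag.  Degenerate scores (zero variance) give `m = 0`
#'   with a warning.
#' @export
nw_auto_lag <- function(X, resid, weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(resid) != n) stop("'resid' must have length nrow(X)")
  if (is.null(weights)) {
    weights <- rep(1, ncol(X))
    icpt <- which(apply(X, 2, function(col) all(col == col[1])))
    weights[icpt] <- 0
    if (all(weights == 0)) weights <- rep(1, ncol(X))
  }
  v <- drop((X * resid) %*% weights)
  l <- floor(4 * (n / 100)^(2 / 9))
  sig <- vapply(0:l, function(j) sum(v[(j + 1):n] * v[1:(n - j)]) / n,
                numeric(1))
  s0 <- sig[1] + 2 * sum(sig[-1])
  s1 <- 2 * sum((1:l) * sig[-1])
  if (!is.finite(s0) || s0 == 0) {
    warning("degenerate score series; using m = 0")
    return(0L)
  }
  m <- floor(1.1447 * ((s1 / s0)^2)^(1 / 3) * n^(1 / 3))
  as.integer(min(max(m, 0), n - 1L))
}

#' Newey-West HAC covariance matrix of OLS coefficients
#'
#' Bartlett-kernel sandwich estimator
#' \deqn{(X'X)^{-1}\Big[\sum_{j=-m}^{m} w_{|j|} \sum_t u_t u_{t-j}'\Big](X'X)^{-1},}
#' where \eqn{u_t = X_t \hat\epsilon_t} and \eqn{w_j = 1 - j/(m+1)}.
#' With `m = 0` this reduces to the White/HC0 heteroskedasticity-robust
#' estimator.  The Bartlett weights guarantee a positive semi-definite
#' result.  Optional VAR(1) prewhitening of the scores (fit
#' \eqn{u_t = A u_{t-1} + e_t}, apply the kernel to \eqn{e_t}, recolor by
#' \eqn{(I - A)^{-1}}) is available but off by default.
#'
#' @param X Design matrix.
#' @param resid OLS residuals.
#' @param m Lag truncation, `0 <= m < n` (rows used after prewhitening).
#' @param prewhiten Apply VAR(1) prewhitening to the scores.
#' @param adjust Multiply by the finite-sample factor `n / (n - k)`.
#' @return Covariance matrix of the OLS coefficient vector.
#' @export
hac_vcov <- function(X, resid, m, prewhiten = FALSE, adjust = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  m <- as.integer(m)
  U <- X * resid
  D <- NULL
  if (prewhiten) {
    A <- .var1_coef(U)
    E <- U[-1L, , drop = FALSE] - U[-n, , drop = FALSE] %*% t(A)
    D <- solve(diag(k) - A)
    U <- E
  }
  nu <- nrow(U)
  if (m >= nu) {
    if (prewhiten) m <- nu - 1L   # one row is lost to the VAR(1) filter
    else stop(sprintf("lag truncation m = %d must be < %d", m, nu))
  }
  S <- crossprod(U)
  if (m > 0) {
    for (j in seq_len(m)) {
      w <- 1 - j / (m + 1)
      G <- crossprod(U[(j + 1):nu, , drop = FALSE], U[1:(nu - j), , drop = FALSE])
      S <- S + w * (G + t(G))
    }
  }
  if (prewhiten)
    S <- D %*% S %*% t(D)
  XtXinv <- chol2inv(chol(crossprod(X)))
  V <- XtXinv %*% S %*% XtXinv
  if (adjust)
    V <- V * n / (n - k)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# Least-squares VAR(1) coefficient matrix for prewhitening, with the usual
# safeguard against (near-)unit roots.
.var1_coef <- function(U) {
  n <- nrow(U)
  Y <- U[-1L, , drop = FALSE]
  Z <- U[-n, , drop = FALSE]
  A <- t(qr.coef(qr(Z), Y))
  A[!is.finite(A)] <- 0
  sv <- svd(A)
  if (any(sv$d > 0.97)) {
    sv$d <- pmin(sv$d, 0.97)
    A <- sv$u %*% (sv$d * t(sv$v))
  }
  A
}

# Lean OLS fit record used by its_fit() and the simulation engine.
.fit_ols <- function(X, y, level = 0.95) {
  o <- .ols_core(X, y)
  vcov <- o$sigma2 * o$XtXinv
  .fit_record("ols", o$beta, vcov, df = o$df, level = level,
              resid = o$resid, sigma2 = o$sigma2,
              extras = list())
}

# OLS point estimates with Newey-West standard errors.
.fit_nw <- function(X, y, lag = "auto", prewhiten = FALSE, dist = "t",
                    level = 0.95) {
  o <- .ols_core(X, y)
  m <- if (identical(lag, "auto")) nw_auto_lag(X, o$resid)
       else if (is.character(lag)) select_lag(o$n, lag)
       else as.integer(lag)
  vcov <- hac_vcov(X, o$resid, m = m, prewhiten = prewhiten)
  df <- if (identical(dist, "t")) o$df else Inf
  .fit_record("nw", o$beta, vcov, df = df, level = level,
              resid = o$resid, sigma2 = o$sigma2,
              extras = list(m = m, prewhiten = prewhiten))
}

# Shared container for a fitted method: coefficients, covariance matrix,
# reference distribution (t with df, or normal when df = Inf) and CIs.
.fit_record <- function(method, beta, vcov, df, level = 0.95, resid = NULL,
                        sigma2 = NA_real_, extras = list(),
                        converged = TRUE, loglik = NA_real_) {
  se <- sqrt(pmax(diag(vcov), 0))
  q <- if (is.finite(df)) qt(1 - (1 - level) / 2, df)
       else qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = beta - q * se, upper = beta + q * se)
  rownames(ci) <- names(beta)
  list(method = method, coefficients = beta, vcov = vcov, se = se,
       df = df, level = level, ci = ci, residuals = resid,
       sigma2 = sigma2, extras = extras, converged = converged,
       loglik = loglik)
}
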