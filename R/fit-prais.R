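#' Estimate the lag-1 autoregressive coefficient from residuals
#'
#' Least-squares slope from regressing \eqn{\hat\epsilon_t} on
#' \eqn{\hat\epsilon_{t-1}}, with or without an intercept.  The raw
#' estimate is truncated into \eqn{(-0.999, 0.999)} if it falls outside
#' the stationary region, and the truncation is flagged.
#'
#' @param resid Residual series (length at least 3).
#' @param intercept Include an intercept in the lag regression (default
#'   `FALSE`: residuals are mean zero by construction).
#' @return List with `phi1`, `truncated` flag.
#' @export
estimate_phi1 <- function(resid, intercept = FALSE) {
  n <- length(resid)
  if (n < 3L) stop("need at least 3 residuals")
  if (var(resid) == 0) stop("residuals are constant; cannot estimate phi1")
  e1 <- resid[-1L]
  e0 <- resid[-n]
  phi <- if (intercept) {
    cv <- stats::cov(e0, e1)
    cv / var(e0)
  } else {
    sum(e0 * e1) / sum(e0^2)
  }
  truncated <- FALSE
  if (!is.finite(phi)) { phi <- 0; truncated <- TRUE }
  if (abs(phi) >= 1) {
    phi <- sign(phi) * 0.999
    truncated <- TRUE
  }
  list(phi1 = phi, truncated = truncated)
}

#' Prais-Winsten / Cochrane-Orcutt quasi-differencing transform
#'
#' Applies the AR(1) decorrelating transform to a response vector and
#' every column of the design matrix: for \eqn{t \ge 1},
#' \eqn{\tilde y_t = y_t - \phi_1 y_{t-1}} (likewise each design column);
#' the first row is rescaled by \eqn{\sqrt{1 - \phi_1^2}} when kept
#' (Prais-Winsten) or dropped (Cochrane-Orcutt).  The intercept column is
#' transformed like any other, so it becomes the constructed regressor
#' \eqn{z_t = 1 - \phi_1} (with \eqn{z_0 = \sqrt{1 - \phi_1^2}}) and the
#' transformed model is fitted without an additional intercept.
#'
#' @param X Design matrix (including the intercept column).
#' @param y Response vector.
#' @param phi1 AR(1) coefficient, `|phi1| < 1`.
#' @param keep_first Keep the rescaled first observation (Prais-Winsten,
#'   default) or drop it (Cochrane-Orcutt).
#' @return List with transformed `X` and `y`.
#' @examples
#' X <- cbind(1, c(0, 1)); y <- c(2, 3)
#' pw_transform(X, y, 0.5)$y  # c(2 * sqrt(0.75), 3 - 0.5 * 2)
#' @export
pw_transform <- function(X, y, phi1, keep_first = TRUE) {
  if (abs(phi1) >= 1)
    stop("|phi1| must be < 1")
  X <- as.matrix(X)
  n <- nrow(X)
  Xt <- X[-1L, , drop = FALSE] - phi1 * X[-n, , drop = FALSE]
  yt <- y[-1L] - phi1 * y[-n]
  if (keep_first) {
    s <- sqrt(1 - phi1^2)
    Xt <- rbind(s * X[1L, ], Xt)
    yt <- c(s * y[1L], yt)
    rownames(Xt) <- NULL
  }
  list(X = Xt, y = yt)
}

# Feasible GLS under AR(1) errors.  keep_first = TRUE gives Prais-Winsten,
# FALSE gives Cochrane-Orcutt.  With iterate = TRUE, phi1 is re-estimated
# from the original-scale residuals of the current coefficient estimate
# until it stabilises.  phi1 may be fixed by the caller (then no
# estimation or iteration takes place, e.g. for known-parameter GLS checks).
.fit_pw <- function(X, y, keep_first = TRUE, iterate = TRUE, tol = 1e-6,
                    max_iter = 50L, phi1 = NULL, intercept_phi = FALSE,
                    level = 0.95) {
  fixed_phi <- !is.null(phi1)
  truncated <- FALSE
  if (!fixed_phi) {
    o <- .ols_core(X, y)
    est <- estimate_phi1(o$resid, intercept = intercept_phi)
    phi1 <- est$phi1
    truncated <- est$truncated
  }
  iters <- 0L
  converged <- TRUE
  repeat {
    tr <- pw_transform(X, y, phi1, keep_first = keep_first)
    ot <- .ols_core(tr$X, tr$y)
    iters <- iters + 1L
    if (fixed_phi || !iterate) break
    resid_orig <- y - drop(X %*% ot$beta)
    est <- estimate_phi1(resid_orig, intercept = intercept_phi)
    if (est$truncated) truncated <- TRUE
    if (abs(est$phi1 - phi1) < tol) { phi1 <- est$phi1; break }
    phi1 <- est$phi1
    if (iters >= max_iter) { converged <- FALSE; break }
  }
  tr <- pw_transform(X, y, phi1, keep_first = keep_first)
  ot <- .ols_core(tr$X, tr$y)
  vcov <- ot$sigma2 * ot$XtXinv
  .fit_record(if (keep_first) "pw" else "co", ot$beta, vcov, df = ot$df,
              level = level, resid = y - drop(X %*% ot$beta),
              sigma2 = ot$sigma2, converged = converged,
              extras = list(phi1 = phi1, iterations = iters,
                            truncated = truncated))
}
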