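#' Fit a segmented regression to an interrupted time series
#'
#' Fits the segmented regression model
#' \eqn{y_t = \beta_0 + \beta_1 x_t + \beta_2 t + \gamma' c_t + \epsilon_t}
#' to an interrupted time series, accounting for autocorrelated errors by
#' one of the methods commonly used in ITS analysis:
#'
#' \describe{
#'   \item{`"ols"`}{Ordinary least squares with classical standard errors
#'     and a t(n - k) reference distribution.}
#'   \item{`"nw"`}{OLS point estimates with Newey-West
#'     (Bartlett-kernel HAC) standard errors; the lag truncation is chosen
#'     by the automatic plug-in rule by default (see [nw_auto_lag()],
#'     [select_lag()]).}
#'   \item{`"pw"`, `"co"`}{Prais-Winsten / Cochrane-Orcutt feasible GLS
#'     under AR(1) errors, iterated by default.}
#'   \item{`"arma"`}{Maximum likelihood with ARMA(p,q) errors.  When
#'     `order` is `NULL` the order is chosen by stepwise AICc search with
#'     `p, q <= 5` (see [arma_select()]); normal-quantile intervals.}
#'   \item{`"ma"`}{Maximum likelihood with a pure MA(q) error model
#'     (`order = q`, default 3); normal-quantile intervals.}
#'   \item{`"reml"`}{REML estimation of an ARMA error model (default
#'     MA(3)) with Satterthwaite degrees of freedom and, by default, the
#'     first-order Kenward-Roger variance adjustment; t(d) intervals.}
#' }
#'
#' @param formula Model formula, e.g. `y ~ x + time`.  An intercept is
#'   always included.
#' @param data Data frame containing the variables, e.g. from
#'   [read_its()] or [simulate_its()]; an [its_design()] plus `y` is also
#'   accepted via `its_fit(design = , y = )`.
#' @param method Estimation method (see Details).
#' @param intervention Name of the intervention-indicator column whose
#'   coefficient is the effect of interest (default `"x"`).
#' @param order Error-model order: `c(p, q)` for `"arma"`/`"reml"`
#'   (stepwise selection when `NULL` for `"arma"`), `q` for `"ma"`.
#' @param level Confidence level (default 0.95).
#' @param lag Newey-West lag: `"auto"` (default), a rule name accepted by
#'   [select_lag()], or an integer.
#' @param prewhiten VAR(1) prewhitening of the Newey-West scores
#'   (default `FALSE`).
#' @param iterate,tol,max_iter Iteration control for `"pw"`/`"co"`.
#' @param phi1 Optional fixed AR(1) coefficient for `"pw"`/`"co"`
#'   (skips estimation; useful for known-parameter GLS).
#' @param kr Apply the Kenward-Roger variance adjustment in `"reml"`
#'   (default `TRUE`).
#' @param design,y Alternative input: an `"its_design"` object and a
#'   response vector (used instead of `formula`/`data`).
#' @return An object of class `"its_fit"` with `print()`, `summary()`,
#'   `coef()`, `vcov()`, `confint()`, `residuals()`, `fitted()`,
#'   `predict()`, `simulate()` and `plot()` methods.  Key components:
#'   `coefficients`, `vcov`, `se`, `df` (`Inf` means standard normal),
#'   `ci` (per-coefficient intervals at `level`), `converged`, `extras`
#'   (method-specific: `phi1`, ARMA order and coefficients, HAC lag `m`,
#'   Satterthwaite `d`, ...).
#' @examples
#' dat <- simulate_its(50, theta = c(0.8, 0.5, 0.2), seed = 1)
#' fit <- its_fit(y ~ x + time, dat, method = "pw")
#' fit
#' confint(fit)
#' @export
its_fit <- function(formula = y ~ x + time, data = NULL,
                    method = c("ols", "nw", "pw", "co", "arma", "ma",
                               "reml"),
                    intervention = "x", order = NULL, level = 0.95,
                    lag = "auto", prewhiten = FALSE,
                    iterate = TRUE, tol = 1e-6, max_iter = 50L,
                    phi1 = NULL, kr = TRUE, design = NULL, y = NULL) {
  method <- match.arg(method)
  trms <- NULL
  if (!is.null(design)) {
    if (!inherits(design, "its_design"))
      stop("'design' must be an its_design object")
    if (is.null(y)) stop("'y' must be supplied with 'design'")
    X <- model.matrix(design)
    yv <- as.numeric(y)
  } else {
    if (is.null(data)) stop("'data' must be supplied")
    mf <- stats::model.frame(formula, data, na.action = na.fail)
    trms <- attr(mf, "terms")
    X <- model.matrix(trms, mf)
    yv <- stats::model.response(mf)
  }
  if (nrow(X) != length(yv)) stop("response and design lengths differ")
  .check_full_rank(X)
  if (!intervention %in% colnames(X))
    stop(sprintf("intervention column '%s' not in the design", intervention))
  j <- match(intervention, colnames(X))
  # perfect fit has no residual variation to estimate an SE from
  ols0 <- .ols_core(X, yv)
  if (ols0$rss < 1e-12 * max(1, sum(yv^2)))
    stop("degenerate fit: residuals are (numerically) zero, ",
         "standard errors are undefined")
  rec <- switch(method,
    ols = .fit_ols(X, yv, level = level),
    nw = .fit_nw(X, yv, lag = lag, prewhiten = prewhiten, level = level),
    pw = .fit_pw(X, yv, keep_first = TRUE, iterate = iterate, tol = tol,
                 max_iter = max_iter, phi1 = phi1, level = level),
    co = .fit_pw(X, yv, keep_first = FALSE, iterate = iterate, tol = tol,
                 max_iter = max_iter, phi1 = phi1, level = level),
    arma = {
      if (is.null(order)) {
        sel <- arma_select(X, yv)
        rec <- sel$fit
        rec$extras$trace <- sel$trace
        rec
      } else {
        .fit_arma(X, yv, order[1], order[2], level = level,
                  method_tag = "arma")
      }
    },
    ma = {
      qq <- if (is.null(order)) 3L else as.integer(order[length(order)])
      .fit_arma(X, yv, 0L, qq, level = level,
                method_tag = sprintf("ma(%d)", qq))
    },
    reml = {
      ord <- if (is.null(order)) c(0L, 3L) else as.integer(order)
      .fit_reml(X, yv, p = ord[1], q = ord[2], kr = kr, level = level,
                intervention = j)
    })
  rec$method <- if (method %in% c("arma", "ma")) rec$method else method
  structure(
    c(rec,
      list(call = match.call(), terms = trms, X = X, y = yv,
           n = nrow(X), k = ncol(X),
           intervention = intervention, intervention_index = j,
           fitted.values = drop(X %*% ifelse(is.na(rec$coefficients), 0,
                                             rec$coefficients)))),
    class = "its_fit")
}

#' @export
print.its_fit <- function(x, digits = 4, ...) {
  cat(sprintf("ITS segmented regression (method: %s)\n", x$method))
  est <- x$coefficients[x$intervention_index]
  ci <- x$ci[x$intervention_index, ]
  cat(sprintf("intervention effect (%s): %.*f  [%.*f, %.*f]  (%d%% CI, %s)\n",
              x$intervention, digits, est, digits, ci[1], digits, ci[2],
              round(100 * x$level),
              if (is.finite(x$df)) sprintf("t, df = %.1f", x$df)
              else "normal"))
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' @export
summary.its_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  stat <- est / se
  pval <- if (is.finite(object$df)) 2 * pt(-abs(stat), object$df)
          else 2 * pnorm(-abs(stat))
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `t value` = stat, `Pr(>|t|)` = pval,
               lower = object$ci[, 1], upper = object$ci[, 2])
  out <- list(method = object$method, coefficients = tab, df = object$df,
              extras = object$extras, converged = object$converged,
              level = object$level, n = object$n)
  class(out) <- "summary.its_fit"
  out
}

#' @export
print.summary.its_fit <- function(x, digits = 4, ...) {
  cat(sprintf("ITS segmented regression (method: %s, n = %d)\n",
              x$method, x$n))
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("reference distribution: %s\n",
              if (is.finite(x$df)) sprintf("t with %.2f df", x$df)
              else "standard normal"))
  ex <- x$extras
  if (!is.null(ex$phi1))
    cat(sprintf("AR(1) coefficient: %.4f (%d iteration%s)\n", ex$phi1,
                ex$iterations, if (ex$iterations == 1) "" else "s"))
  if (!is.null(ex$m))
    cat(sprintf("Newey-West lag truncation: m = %d\n", ex$m))
  if (!is.null(ex$p) && !is.null(ex$q))
    cat(sprintf("error model: ARMA(%d, %d)\n", ex$p, ex$q))
  if (!is.null(ex$d))
    cat(sprintf("Satterthwaite df: %.2f%s\n", ex$d,
                if (isTRUE(ex$kr)) " (Kenward-Roger adjusted SE)" else ""))
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
residuals.its_fit <- function(object, ...) object$residuals

#' @export
fitted.its_fit <- function(object, ...) object$fitted.values

#' @export
confint.its_fit <- function(object, parm, level = NULL, ...) {
  if (is.null(level) || level == object$level) {
    ci <- object$ci
  } else {
    q <- if (is.finite(object$df)) qt(1 - (1 - level) / 2, object$df)
         else qnorm(1 - (1 - level) / 2)
    ci <- cbind(object$coefficients - q * object$se,
                object$coefficients + q * object$se)
    dimnames(ci) <- dimnames(object$ci)
  }
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.its_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (is.null(object$terms))
    stop("prediction on new data requires a formula-fitted model")
  X <- model.matrix(stats::delete.response(object$terms), newdata)
  X <- X[, colnames(object$X), drop = FALSE]
  drop(X %*% object$coefficients)
}

#' Simulate responses from a fitted ITS model
#'
#' Draws new response series from the fitted mean with errors generated
#' from the fitted error model: iid normal for OLS/Newey-West, AR(1) with
#' the estimated `phi1` for Prais-Winsten/Cochrane-Orcutt, and the
#' estimated ARMA process for ARMA/MA/REML fits.
#'
#' @param object An `"its_fit"` object.
#' @param nsim Number of series.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.its_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- object$n
  mu <- object$fitted.values
  ex <- object$extras
  sims <- replicate(nsim, {
    eps <- if (!is.null(ex$phi1)) {
      # sigma2 is the innovation variance of the AR(1) error process
      drop(stats::arima.sim(list(ar = ex$phi1), n, sd = sqrt(object$sigma2)))
    } else if (!is.null(ex$p) && (ex$p > 0 || ex$q > 0)) {
      model <- list()
      phis <- if (!is.null(ex$phi_ar)) ex$phi_ar else ex$phi
      if (length(phis)) model$ar <- phis
      if (length(ex$theta)) model$ma <- ex$theta
      drop(stats::arima.sim(model, n, sd = sqrt(object$sigma2)))
    } else {
      rnorm(n, sd = sqrt(object$sigma2))
    }
    mu + eps
  })
  as.data.frame(sims)
}

#' Plot a fitted interrupted time series model
#'
#' Observed series with the fitted segmented means and a vertical line at
#' the intervention.
#'
#' @param x An `"its_fit"` object.
#' @param ... Passed to [plot()].
#' @export
plot.its_fit <- function(x, ...) {
  tcol <- if ("time" %in% colnames(x$X)) x$X[, "time"] else
    seq_len(x$n) - 1
  plot(tcol, x$y, xlab = "time", ylab = "outcome",
       main = sprintf("ITS fit (%s)", x$method), ...)
  lines(tcol, x$fitted.values, lwd = 2)
  xi <- x$X[, x$intervention]
  if (any(diff(xi) != 0))
    abline(v = tcol[which(diff(xi) != 0)[1] + 1], lty = 2)
  invisible(x)
}
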