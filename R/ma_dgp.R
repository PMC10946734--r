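#' Autocorrelation function of a moving-average process
#'
#' Closed-form lag-k autocorrelations of an MA(q) process
#' \eqn{\epsilon_t = \eta_t + \theta_1 \eta_{t-1} + \dots + \theta_q \eta_{t-q}}:
#' \deqn{\rho_k = \frac{\sum_{i=0}^{q-k} \theta_i \theta_{i+k}}
#'                     {\sum_{i=0}^{q} \theta_i^2}, \qquad \theta_0 = 1,}
#' and \eqn{\rho_k = 0} for `k > q`.
#'
#' @param theta Numeric vector of MA coefficients \eqn{(\theta_1, ..., \theta_q)}.
#' @param lag_max Number of lags to return (default `length(theta)`).
#' @return Numeric vector of autocorrelations at lags `1..lag_max`.
#' @examples
#' ma_acf(c(1, 1, 1))        # 0.75 0.50 0.25
#' ma_acf(c(0.5), lag_max = 3)
#' @export
ma_acf <- function(theta, lag_max = max(1L, length(theta))) {
  theta <- as.numeric(theta)
  if (anyNA(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite")
  th <- c(1, theta)
  q <- length(theta)
  denom <- sum(th^2)
  vapply(seq_len(lag_max), function(k) {
    if (k > q) return(0)
    sum(th[1:(q + 1 - k)] * th[(1 + k):(q + 1)]) / denom
  }, numeric(1))
}

#' Construct an MA(3) autocorrelation scenario
#'
#' A scenario is a triple of moving-average coefficients together with its
#' implied lag-1..3 autocorrelations and a qualitative label based on the
#' lag-1 autocorrelation: `"low"` if \eqn{\rho_1 < 0.3}, `"moderate"` if
#' \eqn{0.3 \le \rho_1 < 0.6}, `"high"` if \eqn{\rho_1 \ge 0.6}.
#'
#' @param theta Numeric vector of up to 3 MA coefficients (padded with
#'   zeros).
#' @param id Optional scenario identifier.
#' @return An object of class `"ma_scenario"`: a list with elements
#'   `theta`, `acf`, `label` and `id`.
#' @export
ma_scenario <- function(theta, id = NA_integer_) {
  theta <- as.numeric(theta)
  if (length(theta) > 3L)
    stop("scenarios use at most 3 MA coefficients")
  theta <- c(theta, rep(0, 3L - length(theta)))
  rho <- ma_acf(theta, lag_max = 3L)
  structure(
    list(theta = theta, acf = rho, label = .acf_label(rho[1]),
         id = as.integer(id)),
    class = "ma_scenario")
}

.acf_label <- function(rho1) {
  if (rho1 < 0.3) "low" else if (rho1 < 0.6) "moderate" else "high"
}

#' @export
print.ma_scenario <- function(x, ...) {
  cat(sprintf(
    "MA(3) scenario%s: theta = (%.3f, %.3f, %.3f), rho = (%.3f, %.3f, %.3f) [%s]\n",
    if (is.na(x$id)) "" else paste0(" ", x$id),
    x$theta[1], x$theta[2], x$theta[3],
    x$acf[1], x$acf[2], x$acf[3], x$label))
  invisible(x)
}

#' Draw MA(3) autocorrelation scenarios from nested uniform distributions
#'
#' Samples scenarios with \eqn{\theta_1 \sim U(0, 1)},
#' \eqn{\theta_2 \sim U(0, \theta_1)} and
#' \eqn{\theta_3 \sim U(0, \theta_2)}, so that the implied
#' autocorrelation is positive and decreasing over the first three lags
#' (and exactly zero beyond lag 3).  On this support
#' \eqn{\rho_1 \le 0.75}.
#'
#' @param n_scenarios Number of scenarios to draw (default 20).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and does not disturb the caller's RNG state.
#' @return A data frame of class `"ma_scenario_set"` with columns
#'   `scenario_id`, `theta1..theta3`, `rho1..rho3`, `label`.
#' @examples
#' sc <- sample_scenarios(5, seed = 1)
#' sc
#' @export
sample_scenarios <- function(n_scenarios = 20, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  th1 <- stats::runif(n_scenarios)
  th2 <- stats::runif(n_scenarios, 0, th1)
  th3 <- stats::runif(n_scenarios, 0, th2)
  rho <- t(vapply(seq_len(n_scenarios),
                  function(i) ma_acf(c(th1[i], th2[i], th3[i]), 3L),
                  numeric(3)))
  out <- data.frame(
    scenario_id = seq_len(n_scenarios),
    theta1 = th1, theta2 = th2, theta3 = th3,
    rho1 = rho[, 1], rho2 = rho[, 2], rho3 = rho[, 3],
    label = vapply(rho[, 1], .acf_label, character(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("ma_scenario_set", "data.frame")
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

# Stationary MA(3) errors: simulate n + 3 innovations and discard the
# pre-sample ones, so the error process is exactly stationary from t = 0.
# Returns an n x nsim matrix.
.sim_ma_errors <- function(n, theta, nsim = 1L, sd_innov = 1) {
  theta <- c(as.numeric(theta), rep(0, max(0L, 3L - length(theta))))[1:3]
  h <- matrix(rnorm((n + 3L) * nsim, sd = sd_innov), nrow = n + 3L)
  h[4:(n + 3L), , drop = FALSE] +
    theta[1] * h[3:(n + 2L), , drop = FALSE] +
    theta[2] * h[2:(n + 1L), , drop = FALSE] +
    theta[3] * h[1:n, , drop = FALSE]
}

#' Simulate interrupted time series with MA(3) errors
#'
#' Generates series from the segmented regression model
#' \eqn{y_t = \beta_0 + \beta_1 x_t + \beta_2 t + \epsilon_t} with
#' moving-average errors
#' \eqn{\epsilon_t = \eta_t + \theta_1\eta_{t-1} + \theta_2\eta_{t-2} +
#' \theta_3\eta_{t-3}}, \eqn{\eta_t \sim N(0, \sigma^2)} i.i.d.  The
#' default parameters are \eqn{\beta_0 = 4}, \eqn{\beta_1 = -1},
#' \eqn{\beta_2 = -1/n}, \eqn{\sigma = 1} and a mid-series intervention
#' (`tau = (n + 1) %/% 2`), i.e. a 25\% step reduction and 25\% trend reduction
#' relative to the intercept over the study period.  Pre-sample
#' innovations are drawn so the error process is exactly stationary from
#' the first observation.
#'
#' @param n Series length (at least 8).
#' @param theta MA coefficients (up to 3; defaults to white noise).
#'   May also be an `"ma_scenario"` object.
#' @param beta Regression coefficients `c(beta0, beta1, beta2)`; the
#'   trend coefficient is ignored when `trend = FALSE`.
#' @param tau Intervention index (default `(n + 1) %/% 2`).
#' @param sd_innov Innovation standard deviation (default 1).
#' @param trend Include the linear trend term (default `TRUE`).
#' @param nsim Number of independent replicate series.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return For `nsim = 1`, a data frame with columns `time`, `x`, `y`.
#'   For `nsim > 1`, a list with elements `design` (the [its_design()])
#'   and `y` (an `n` by `nsim` matrix of responses).
#' @examples
#' head(simulate_its(20, theta = c(0.8, 0.5, 0.2), seed = 1))
#' @export
simulate_its <- function(n, theta = c(0, 0, 0), beta = c(4, -1, -1 / n),
                         tau = (n + 1L) %/% 2L, sd_innov = 1, trend = TRUE,
                         nsim = 1L, seed = NULL) {
  if (inherits(theta, "ma_scenario"))
    theta <- theta$theta
  n <- as.integer(n)
  if (n < 8L)
    stop("'n' must be at least 8")
  if (sd_innov <= 0)
    stop("'sd_innov' must be positive")
  if (length(beta) < 2L)
    stop("'beta' must supply at least an intercept and an intervention effect")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  design <- its_design(n, tau = tau, trend = trend)
  X <- model.matrix(design)
  b <- c(beta[1], beta[2], if (trend) beta[3])
  mu <- drop(X %*% b)
  eps <- .sim_ma_errors(n, theta, nsim = nsim, sd_innov = sd_innov)
  Y <- mu + eps
  if (nsim == 1L)
    data.frame(time = design$frame$time, x = design$frame$x, y = drop(Y))
  else
    list(design = design, y = Y)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
  else
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
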