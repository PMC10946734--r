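# Monte-Carlo evaluation engine: simulate ITS data with MA(3) errors over
# a scenario x length grid and score each estimation method by bias,
# empirical SE, RMSE, coverage and power, with Monte-Carlo errors.

#' Configuration for a Monte-Carlo ITS simulation study
#'
#' @param n_scenarios Number of MA(3) autocorrelation scenarios to draw
#'   from the nested-uniform prior (default 20); ignored when `scenarios`
#'   is supplied.
#' @param scenarios Optional scenario table from [sample_scenarios()].
#' @param n_grid Series lengths (default `c(20, 50, 100, 300)`).
#' @param nsim Replicates per (scenario, n) cell (default 2000).
#' @param methods Methods to evaluate; any of `"ols"`, `"nw"`, `"pw"`,
#'   `"co"`, `"arma"` (stepwise AICc selection), `"ma1"`, `"ma2"`,
#'   `"ma3"` (fixed-order MA by maximum likelihood), `"reml_kr"`
#'   (MA(3) REML with Kenward-Roger adjustment), `"known_gls"`
#'   (GLS with the true error covariance; z intervals).
#' @param nsim_by_method Optional named list overriding `nsim` for
#'   selected (computationally expensive) methods; every method sees the
#'   same first `nsim` datasets of the cell.
#' @param seed Master seed; all per-cell substreams are derived from it
#'   deterministically, so any cell is reproducible in isolation.
#' @param beta0,beta1 Intercept and intervention effect of the
#'   data-generating model (defaults 4 and -1); the trend slope is
#'   `-1/n` per cell.
#' @param sd_innov Innovation standard deviation (default 1).
#' @param level Confidence level (default 0.95).
#' @return A list of class `"its_study_config"`.
#' @export
its_study_config <- function(n_scenarios = 20, scenarios = NULL,
                             n_grid = c(20, 50, 100, 300), nsim = 2000,
                             methods = c("ols", "nw", "pw", "arma", "ma3"),
                             nsim_by_method = NULL, seed = 1,
                             beta0 = 4, beta1 = -1, sd_innov = 1,
                             level = 0.95) {
  known <- c("ols", "nw", "pw", "co", "arma", "ma1", "ma2", "ma3",
             "reml_kr", "known_gls")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (nsim < 2) stop("'nsim' must be at least 2")
  if (any(n_grid < 12)) stop("all series lengths must be at least 12")
  if (!is.null(nsim_by_method)) {
    if (any(unlist(nsim_by_method) > nsim))
      stop("'nsim_by_method' cannot exceed 'nsim'")
    bad <- setdiff(names(nsim_by_method), methods)
    if (length(bad))
      stop("'nsim_by_method' names unknown methods: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_scenarios = n_scenarios, scenarios = scenarios,
                 n_grid = as.integer(n_grid), nsim = as.integer(nsim),
                 methods = methods, nsim_by_method = nsim_by_method,
                 seed = as.integer(seed), beta0 = beta0, beta1 = beta1,
                 sd_innov = sd_innov, level = level),
            class = "its_study_config")
}

# Deterministic substream seed for a (scenario, n) cell; keeps every seed
# inside the 32-bit integer range.
.cell_seed <- function(seed, scenario_id, n) {
  as.integer((as.numeric(seed) * 1000003 + scenario_id * 10007 + n * 101) %%
               2147483563 + 1)
}

# ---- lean per-cell fitters -------------------------------------------------
# Each returns an nsim x 5 matrix: est, lower, upper, df, converged.

.cell_ols <- function(X, Y, j, level) {
  n <- nrow(X); k <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  E <- Y - X %*% B
  sigma2 <- colSums(E^2) / (n - k)
  se <- sqrt(XtXinv[j, j] * sigma2)
  qv <- qt(1 - (1 - level) / 2, n - k)
  est <- B[j, ]
  cbind(est = est, lower = est - qv * se, upper = est + qv * se,
        df = n - k, converged = 1)
}

.cell_nw <- function(X, Y, j, level, prewhiten = FALSE) {
  n <- nrow(X); k <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)
  E <- Y - X %*% B
  qv <- qt(1 - (1 - level) / 2, n - k)
  out <- matrix(NA_real_, ncol(Y), 5)
  for (i in seq_len(ncol(Y))) {
    e <- E[, i]
    m <- nw_auto_lag(X, e)
    V <- hac_vcov(X, e, m = m, prewhiten = prewhiten)
    se <- sqrt(max(V[j, j], 0))
    out[i, ] <- c(B[j, i], B[j, i] - qv * se, B[j, i] + qv * se, n - k, 1)
  }
  colnames(out) <- c("est", "lower", "upper", "df", "converged")
  out
}

.cell_pw <- function(X, Y, j, level, keep_first = TRUE) {
  out <- matrix(NA_real_, ncol(Y), 5)
  for (i in seq_len(ncol(Y))) {
    rec <- .fit_pw(X, Y[, i], keep_first = keep_first, level = level)
    out[i, ] <- c(rec$coefficients[j], rec$ci[j, 1], rec$ci[j, 2],
                  rec$df, as.numeric(rec$converged))
  }
  colnames(out) <- c("est", "lower", "upper", "df", "converged")
  out
}

.cell_ma <- function(X, Y, j, level, q) {
  out <- matrix(NA_real_, ncol(Y), 5)
  for (i in seq_len(ncol(Y))) {
    rec <- .fit_arma(X, Y[, i], 0L, q, level = level)
    out[i, ] <- c(rec$coefficients[j], rec$ci[j, 1], rec$ci[j, 2],
                  rec$df, as.numeric(rec$converged))
  }
  colnames(out) <- c("est", "lower", "upper", "df", "converged")
  out
}

.cell_arma <- function(X, Y, j, level) {
  out <- matrix(NA_real_, ncol(Y), 5)
  for (i in seq_len(ncol(Y))) {
    rec <- tryCatch(arma_select(X, Y[, i])$fit, error = function(e) NULL)
    if (is.null(rec)) {
      out[i, ] <- c(NA, NA, NA, NA, 0)
    } else {
      out[i, ] <- c(rec$coefficients[j], rec$ci[j, 1], rec$ci[j, 2],
                    rec$df, as.numeric(rec$converged))
    }
  }
  colnames(out) <- c("est", "lower", "upper", "df", "converged")
  out
}

.cell_reml_kr <- function(X, Y, j, level, order = c(0L, 3L)) {
  out <- matrix(NA_real_, ncol(Y), 5)
  for (i in seq_len(ncol(Y))) {
    rec <- tryCatch(
      .fit_reml(X, Y[, i], p = order[1], q = order[2], kr = TRUE,
                level = level, intervention = j),
      error = function(e) NULL)
    if (is.null(rec) || !rec$converged) {
      out[i, ] <- c(NA, NA, NA, NA, 0)
    } else {
      out[i, ] <- c(rec$coefficients[j], rec$ci[j, 1], rec$ci[j, 2],
                    rec$extras$d, 1)
    }
  }
  colnames(out) <- c("est", "lower", "upper", "df", "converged")
  out
}

# GLS with the true MA(3) covariance and known innovation variance; the
# pivotal statistic is exactly standard normal, so coverage is exact.
.cell_known_gls <- function(X, Y, j, level, theta, sd_innov = 1) {
  n <- nrow(X)
  g <- arma_autocov(theta = theta, sigma2 = sd_innov^2, lag_max = n - 1L)
  L <- chol(toeplitz(g))
  Xs <- backsolve(L, X, transpose = TRUE)
  Ys <- backsolve(L, Y, transpose = TRUE)
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  B <- XtXinv %*% crossprod(Xs, Ys)
  se <- sqrt(XtXinv[j, j])
  qv <- qnorm(1 - (1 - level) / 2)
  est <- B[j, ]
  cbind(est = est, lower = est - qv * se, upper = est + qv * se,
        df = Inf, converged = 1)
}

.cell_fit <- function(method, X, Y, j, level, theta, sd_innov) {
  switch(method,
    ols = .cell_ols(X, Y, j, level),
    nw = .cell_nw(X, Y, j, level),
    pw = .cell_pw(X, Y, j, level, keep_first = TRUE),
    co = .cell_pw(X, Y, j, level, keep_first = FALSE),
    arma = .cell_arma(X, Y, j, level),
    ma1 = .cell_ma(X, Y, j, level, q = 1L),
    ma2 = .cell_ma(X, Y, j, level, q = 2L),
    ma3 = .cell_ma(X, Y, j, level, q = 3L),
    reml_kr = .cell_reml_kr(X, Y, j, level),
    known_gls = .cell_known_gls(X, Y, j, level, theta, sd_innov),
    stop("unknown method: ", method))
}

#' Summarise per-replicate estimates into simulation-study metrics
#'
#' Standard simulation-study estimands for an estimator of a known true
#' effect: bias, empirical SE, root mean square error, coverage of the
#' confidence interval, and power (interval excludes zero), each with its
#' Monte-Carlo standard error.  Non-converged replicates are excluded
#' from all metrics and counted.
#'
#' @param records Data frame (or matrix) with columns `est`, `lower`,
#'   `upper` and optionally `df`, `converged`.
#' @param true_beta1 True value of the intervention effect.
#' @return One-row data frame with `nsim_used`, `n_nonconverged`, `bias`,
#'   `mc_se_bias`, `emp_se`, `rmse`, `mc_se_rmse`, `coverage`,
#'   `mc_se_coverage`, `power`, `mc_se_power`, `mean_df`.
#' @examples
#' r <- data.frame(est = c(0, 2), lower = -10, upper = 10)
#' compute_metrics(r, true_beta1 = 1)  # bias 0, rmse 1, emp_se sqrt(2)
#' @export
compute_metrics <- function(records, true_beta1) {
  records <- as.data.frame(records)
  if (is.null(records$converged)) records$converged <- 1
  if (is.null(records$df)) records$df <- NA_real_
  ok <- records$converged > 0 & is.finite(records$est)
  B <- sum(ok)
  nc <- nrow(records) - B
  if (B < 2)
    return(data.frame(nsim_used = B, n_nonconverged = nc, bias = NA_real_,
                      mc_se_bias = NA_real_, emp_se = NA_real_,
                      rmse = NA_real_, mc_se_rmse = NA_real_,
                      coverage = NA_real_, mc_se_coverage = NA_real_,
                      power = NA_real_, mc_se_power = NA_real_,
                      mean_df = NA_real_))
  est <- records$est[ok]
  lo <- records$lower[ok]; hi <- records$upper[ok]
  err <- est - true_beta1
  bias <- mean(err)
  emp_se <- sd(est)
  rmse <- sqrt(mean(err^2))
  cov <- mean(lo <= true_beta1 & true_beta1 <= hi)
  pow <- mean(lo > 0 | hi < 0)
  data.frame(
    nsim_used = B, n_nonconverged = nc,
    bias = bias, mc_se_bias = emp_se / sqrt(B),
    emp_se = emp_se, rmse = rmse,
    mc_se_rmse = sd(err^2) / (2 * rmse * sqrt(B)),
    coverage = cov, mc_se_coverage = sqrt(cov * (1 - cov) / B),
    power = pow, mc_se_power = sqrt(pow * (1 - pow) / B),
    mean_df = mean(records$df[ok]))
}

#' Run the Monte-Carlo simulation study
#'
#' For every (scenario, series length) cell of the configured grid,
#' simulates `nsim` interrupted time series from the segmented regression
#' model with MA(3) errors (mid-series intervention, trend slope
#' `-1/n`), fits every configured method to the same datasets, and
#' aggregates the intervention-effect estimates into a metrics table.
#' Fully reproducible from the master seed; a method failing on a
#' replicate is counted, never fatal.
#'
#' @param config An [its_study_config()] object.
#' @param verbose Print per-cell progress.
#' @return An object of class `"its_study"`: list with `metrics` (one row
#'   per scenario x n x method), `scenarios` and `config`.
#' @seealso [aggregate_metrics()], [power_experiment()]
#' @export
run_study <- function(config = its_study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "its_study_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  scen <- config$scenarios
  if (is.null(scen))
    scen <- sample_scenarios(config$n_scenarios, seed = config$seed)
  rows <- vector("list", nrow(scen) * length(config$n_grid) *
                   length(config$methods))
  ri <- 0L
  for (si in seq_len(nrow(scen))) {
    theta <- as.numeric(scen[si, c("theta1", "theta2", "theta3")])
    for (n in config$n_grid) {
      beta2 <- -1 / n
      set.seed(.cell_seed(config$seed, scen$scenario_id[si], n))
      design <- its_design(n, trend = TRUE)
      X <- model.matrix(design)
      mu <- drop(X %*% c(config$beta0, config$beta1, beta2))
      eps <- .sim_ma_errors(n, theta, nsim = config$nsim,
                            sd_innov = config$sd_innov)
      Y <- mu + eps
      j <- match("x", colnames(X))
      for (method in config$methods) {
        nm <- config$nsim_by_method[[method]]
        if (is.null(nm)) nm <- config$nsim
        rec <- .cell_fit(method, X, Y[, seq_len(nm), drop = FALSE], j,
                         config$level, theta, config$sd_innov)
        met <- compute_metrics(rec, true_beta1 = config$beta1)
        ri <- ri + 1L
        rows[[ri]] <- cbind(
          data.frame(scenario_id = scen$scenario_id[si],
                     rho1 = scen$rho1[si], label = scen$label[si],
                     n = n, method = method, stringsAsFactors = FALSE),
          met)
        if (verbose)
          message(sprintf("scenario %d  n = %3d  %-9s coverage = %.3f",
                          scen$scenario_id[si], n, method, met$coverage))
      }
    }
  }
  structure(list(metrics = do.call(rbind, rows[seq_len(ri)]),
                 scenarios = scen, config = config),
            class = "its_study")
}

#' @export
print.its_study <- function(x, ...) {
  cat(sprintf(
    "ITS simulation study: %d scenarios x %d lengths x %d methods, nsim = %d\n",
    nrow(x$scenarios), length(x$config$n_grid), length(x$config$methods),
    x$config$nsim))
  print(aggregate_metrics(x))
  invisible(x)
}

#' Aggregate simulation metrics over grid cells
#'
#' Unweighted means of bias, empirical SE, RMSE, coverage and power over
#' the (scenario, n) cells selected by the filters, separately per
#' method.  These means over all cells (or over autocorrelation strata)
#' are the headline summaries of the simulation study.
#'
#' @param x An `"its_study"` object or its `metrics` data frame (which
#'   must then contain `rho1` and `n` columns).
#' @param rho1_min,rho1_max Restrict to scenarios whose lag-1
#'   autocorrelation lies in `[rho1_min, rho1_max)` (closed on the right
#'   when `rho1_max = Inf`).
#' @param n_min,n_max Restrict to series lengths in `[n_min, n_max]`.
#' @return Data frame with one row per method: number of cells and the
#'   unweighted cell means.  An empty selection gives a zero-row result
#'   with a warning.
#' @export
aggregate_metrics <- function(x, rho1_min = -Inf, rho1_max = Inf,
                              n_min = 0, n_max = Inf) {
  m <- if (inherits(x, "its_study")) x$metrics else as.data.frame(x)
  keep <- m$rho1 >= rho1_min &
    (if (is.finite(rho1_max)) m$rho1 < rho1_max else TRUE) &
    m$n >= n_min & m$n <= n_max
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    warning("no cells match the requested stratum")
    return(data.frame(method = character(), n_cells = integer(),
                      bias = numeric(), emp_se = numeric(),
                      rmse = numeric(), coverage = numeric(),
                      power = numeric(), mean_df = numeric()))
  }
  out <- do.call(rbind, lapply(split(m, m$method), function(g) {
    data.frame(method = g$method[1], n_cells = nrow(g),
               bias = mean(g$bias), emp_se = mean(g$emp_se),
               rmse = mean(g$rmse), coverage = mean(g$coverage),
               power = mean(g$power), mean_df = mean(g$mean_df))
  }))
  rownames(out) <- NULL
  out[match(unique(m$method), out$method), , drop = FALSE]
}

#' Power and degrees of freedom under zero autocorrelation
#'
#' Simulates series with independent errors (`theta = c(0, 0, 0)`) at a
#' single length and compares methods on the power to detect the
#' intervention effect (fraction of replicates whose confidence interval
#' excludes zero) and the mean reference-distribution degrees of freedom.
#' With the default `n = 50` the OLS residual degrees of freedom are 47
#' in every replicate, while the Satterthwaite/Kenward-Roger degrees of
#' freedom of the MA(3) REML fit are estimated per replicate.
#'
#' @param n Series length (default 50).
#' @param nsim Replicates (default 2000).
#' @param methods Methods to compare (default OLS and MA(3) REML with
#'   Kenward-Roger adjustment).
#' @param seed Master seed.
#' @param theta Error-model coefficients of the data-generating process
#'   (default zero autocorrelation).
#' @param beta1 True intervention effect (default -1).
#' @param level Confidence level.
#' @return Data frame with one row per method: `power`, `mc_se_power`,
#'   `mean_df`, `coverage`, `nsim_used`, `n_nonconverged`.
#' @export
power_experiment <- function(n = 50, nsim = 2000,
                             methods = c("ols", "reml_kr"), seed = 1,
                             theta = c(0, 0, 0), beta1 = -1,
                             level = 0.95) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.cell_seed(seed, 0L, n))
  design <- its_design(n, trend = TRUE)
  X <- model.matrix(design)
  mu <- drop(X %*% c(4, beta1, -1 / n))
  Y <- mu + .sim_ma_errors(n, theta, nsim = nsim)
  j <- match("x", colnames(X))
  out <- lapply(methods, function(method) {
    rec <- .cell_fit(method, X, Y, j, level, theta, 1)
    met <- compute_metrics(rec, true_beta1 = beta1)
    data.frame(method = method, power = met$power,
               mc_se_power = met$mc_se_power, mean_df = met$mean_df,
               coverage = met$coverage, nsim_used = met$nsim_used,
               n_nonconverged = met$n_nonconverged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot coverage or RMSE against series length per scenario
#'
#' One panel per autocorrelation scenario (ordered by lag-1
#' autocorrelation), showing the chosen metric as a function of series
#' length for every method in the study.
#'
#' @param x An `"its_study"` object.
#' @param metric Column of the metrics table to plot (default
#'   `"coverage"`).
#' @param ... Unused.
#' @export
plot.its_study <- function(x, metric = "coverage", ...) {
  m <- x$metrics
  scen <- x$scenarios[order(x$scenarios$rho1), ]
  methods <- unique(m$method)
  ns <- nrow(scen)
  nc <- ceiling(sqrt(ns))
  nr <- ceiling(ns / nc)
  op <- par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(par(op))
  for (si in seq_len(ns)) {
    sid <- scen$scenario_id[si]
    g <- m[m$scenario_id == sid, ]
    tab <- sapply(methods, function(mm) {
      gg <- g[g$method == mm, ]
      gg[[metric]][order(gg$n)]
    })
    matplot(sort(unique(g$n)), tab, type = "b", pch = 1:length(methods),
            lty = 1, xlab = "n", ylab = metric, log = "x",
            main = sprintf("rho1 = %.2f", scen$rho1[si]), cex.main = 0.9)
    if (metric == "coverage") abline(h = 0.95, lty = 3)
    if (si == 1)
      legend("bottomright", legend = methods, pch = 1:length(methods),
             col = seq_along(methods), cex = 0.7, bty = "n")
  }
  invisible(x)
}
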