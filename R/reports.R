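#' Analyze an interrupted time series and compare methods
#'
#' Fits the segmented regression model to one ITS dataset with one or
#' more estimation methods and reports the intervention effect (and
#' optionally the trend) with confidence intervals in a single
#' comparison table.  When `transform = "log2"` the outcome is
#' log2-transformed before fitting and effects are additionally reported
#' as percent reductions, \eqn{100 (1 - 2^{\hat\beta})}, the natural
#' reporting scale for incidence-rate outcomes.
#'
#' @param data A data frame with columns `time`, `y`, `x` and optional
#'   covariates, or a path to a CSV file readable by [read_its()].
#' @param formula Model formula (default `y ~ x + time` plus any
#'   covariates you add).
#' @param methods Methods to compare (see [its_fit()]).
#' @param transform `"none"` or `"log2"`.
#' @param intervention Name of the intervention column (default `"x"`).
#' @param level Confidence level.
#' @param ... Further arguments passed to [its_fit()].
#' @return Data frame of class `"its_analysis"` with one row per method:
#'   `estimate`, `lower`, `upper`, `df`, and for log2 outcomes
#'   `pct_reduction`, `pct_lower`, `pct_upper`.
#' @examples
#' dat <- simulate_its(60, theta = c(0.6, 0.3, 0.1), seed = 7)
#' analyze_its(dat, methods = c("ols", "pw", "nw"))
#' @export
analyze_its <- function(data, formula = y ~ x + time,
                        methods = c("ols", "pw", "arma", "nw"),
                        transform = c("none", "log2"),
                        intervention = "x", level = 0.95, ...) {
  transform <- match.arg(transform)
  if (is.character(data) && length(data) == 1L)
    data <- read_its(data)
  data <- as.data.frame(data)
  if (transform == "log2") {
    if (any(data$y <= 0))
      stop("log2 transform requires strictly positive outcomes")
    data$y <- log2(data$y)
  }
  rows <- lapply(methods, function(m) {
    fit <- its_fit(formula, data, method = m, intervention = intervention,
                   level = level, ...)
    j <- fit$intervention_index
    out <- data.frame(method = m, estimate = fit$coefficients[j],
                      lower = fit$ci[j, 1], upper = fit$ci[j, 2],
                      df = fit$df, converged = fit$converged,
                      stringsAsFactors = FALSE)
    if (transform == "log2") {
      out$pct_reduction <- pct_reduction(out$estimate)
      # a more negative coefficient is a larger reduction
      out$pct_lower <- pct_reduction(out$upper)
      out$pct_upper <- pct_reduction(out$lower)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "transform") <- transform
  class(out) <- c("its_analysis", "data.frame")
  out
}

#' Percent reduction implied by a log2-scale coefficient
#'
#' For a model fitted to log2-transformed rates, a coefficient
#' \eqn{\beta} corresponds to a multiplicative change \eqn{2^{\beta}},
#' i.e. a percent reduction of \eqn{100 (1 - 2^{\beta})}.
#'
#' @param beta Coefficient on the log2 scale.
#' @return Percent reduction (positive when the rate decreases).
#' @examples
#' pct_reduction(-0.5)  # 29.3
#' @export
pct_reduction <- function(beta) 100 * (1 - 2^beta)

#' @export
print.its_analysis <- function(x, digits = 3, ...) {
  cat("ITS method comparison\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Run the simulation study end to end and write its outputs
#'
#' Convenience wrapper around [run_study()] that draws the scenario set,
#' runs the grid, writes the scenario table, per-cell metrics and
#' stratum summaries as CSV files into `out_dir`, together with a plain
#' text manifest recording the seed and configuration so any run can be
#' reproduced bit-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param scale `"reduced"` (500 replicates, fast methods only) or
#'   `"full"` (2000 replicates, all headline methods).
#' @param seed Master seed.
#' @param config Optional [its_study_config()] overriding `scale`.
#' @param verbose Print progress.
#' @return Invisibly, the `"its_study"` object.
#' @export
reproduce_study <- function(out_dir, scale = c("reduced", "full"),
                            seed = 1, config = NULL, verbose = FALSE) {
  scale <- match.arg(scale)
  if (is.null(config)) {
    config <- if (scale == "reduced")
      its_study_config(nsim = 500, methods = c("ols", "nw", "pw"),
                       seed = seed)
    else
      its_study_config(nsim = 2000,
                       methods = c("ols", "nw", "pw", "arma", "ma3"),
                       seed = seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- run_study(config, verbose = verbose)
  write.csv(study$scenarios, file.path(out_dir, "scenarios.csv"),
            row.names = FALSE)
  write.csv(study$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  summaries <- rbind(
    cbind(stratum = "all", aggregate_metrics(study)),
    cbind(stratum = "rho1_lt_0.6",
          aggregate_metrics(study, rho1_max = 0.6)),
    cbind(stratum = "rho1_ge_0.6",
          aggregate_metrics(study, rho1_min = 0.6)),
    cbind(stratum = "n_le_50", aggregate_metrics(study, n_max = 50)))
  write.csv(summaries, file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  manifest <- data.frame(
    package = "itsreg",
    version = as.character(utils::packageVersion("itsreg")),
    seed = config$seed,
    nsim = config$nsim,
    n_grid = paste(config$n_grid, collapse = " "),
    methods = paste(config$methods, collapse = " "),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  write.dcf(manifest, file.path(out_dir, "MANIFEST"))
  invisible(study)
}
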