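#' Construct a segmented-regression design for an interrupted time series
#'
#' Builds the design of the segmented regression model for a series of `n`
#' equally spaced observations interrupted at time index `tau`: an
#' intercept, a step indicator `x` (`x = 0` before the intervention,
#' `x = 1` from `tau` onwards), an optional linear trend in the 0-based
#' time index, optional extra covariate columns, and optionally the
#' step-by-trend interaction.
#'
#' Time is indexed `t = 0, ..., n - 1`.  By default the intervention is
#' placed at `tau = (n + 1) %/% 2`, which gives a 1:1 pre/post split for even
#' `n`; for odd `n` the extra observation falls in the pre-intervention
#' period.
#'
#' @param n Number of observations (at least 4).
#' @param tau Intervention time index: the first post-intervention time
#'   point, with `0 < tau < n`.
#' @param trend Include a linear trend column (default `TRUE`).
#' @param covariates Optional named list or data frame of additional
#'   covariate columns, each of length `n`.
#' @param interaction Include the step-by-trend interaction `x * t`
#'   (default `FALSE`).
#' @return An object of class `"its_design"`: a list with elements
#'   `frame` (data frame with columns `time` and `x` plus covariates),
#'   `n`, `tau`, `trend` and `interaction`.
#' @examples
#' d <- its_design(50)
#' head(model.matrix(d))
#' @seealso [model.matrix.its_design()], [simulate_its()], [its_fit()]
#' @export
its_design <- function(n, tau = (n + 1L) %/% 2L, trend = TRUE, covariates = NULL,
                       interaction = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L)
    stop("'n' must be an integer >= 4")
  tau <- as.integer(tau)
  if (is.na(tau) || tau <= 0L || tau >= n)
    stop(sprintf("'tau' must satisfy 0 < tau < n; got tau = %d, n = %d",
                 tau, n))
  time <- 0:(n - 1L)
  x <- as.numeric(time >= tau)
  frame <- data.frame(time = time, x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariate columns must have length n")
    bad <- intersect(names(covariates), c("time", "x", "y"))
    if (length(bad))
      stop("covariate names clash with reserved columns: ",
           paste(bad, collapse = ", "))
    frame <- cbind(frame, covariates)
  }
  out <- structure(
    list(frame = frame, n = n, tau = tau, trend = isTRUE(trend),
         interaction = isTRUE(interaction)),
    class = "its_design")
  # fail early on rank-deficient designs, naming the offending column
  invisible(model.matrix(out))
  out
}

#' Design matrix of an ITS design
#'
#' Expands an [its_design()] object into the numeric regression matrix:
#' intercept, intervention step, optional trend, covariates and optional
#' step-by-trend interaction.  Fails with an informative error, naming the
#' offending column(s), if the matrix is column-rank deficient.
#'
#' @param object An `"its_design"` object.
#' @param ... Unused.
#' @return Numeric matrix with `n` rows.
#' @export
model.matrix.its_design <- function(object, ...) {
  f <- object$frame
  X <- cbind("(Intercept)" = rep(1, object$n), x = f$x)
  if (object$trend)
    X <- cbind(X, time = f$time)
  extra <- setdiff(names(f), c("time", "x"))
  for (nm in extra) {
    v <- f[[nm]]
    if (!is.numeric(v))
      stop(sprintf("covariate '%s' is not numeric", nm))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nm
  }
  if (object$interaction)
    X <- cbind(X, "x:time" = f$x * f$time)
  .check_full_rank(X)
  X
}

# Rank check shared by design construction and the fitters.  Uses a pivoted
# QR so the columns that break full rank can be reported by name.
.check_full_rank <- function(X) {
  qrx <- qr(X, LAPACK = FALSE)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(drop, collapse = ", "))
  }
  invisible(X)
}

#' @export
print.its_design <- function(x, ...) {
  cat(sprintf(
    "ITS design: n = %d, intervention at tau = %d (%d pre, %d post)\n",
    x$n, x$tau, x$tau, x$n - x$tau))
  cols <- c("(Intercept)", "x", if (x$trend) "time",
            setdiff(names(x$frame), c("time", "x")),
            if (x$interaction) "x:time")
  cat("columns:", paste(cols, collapse = ", "), "\n")
  invisible(x)
}

#' Read an interrupted time series from a delimited text file
#'
#' Reads a CSV file (header required) with columns `time`, `y` and `x`
#' plus optional covariate columns, and validates it for use with
#' [its_fit()]: all columns numeric, no missing values, equally spaced
#' time points, and `x` a 0/1 step.
#'
#' @param file Path to a CSV file.
#' @param sep Field separator (default comma).
#' @return A validated data frame.
#' @export
read_its <- function(file, sep = ",") {
  dat <- read.csv(file, sep = sep, header = TRUE)
  need <- c("time", "y", "x")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("input is missing required column(s): ", paste(miss, collapse = ", "))
  for (nm in names(dat)) {
    if (!is.numeric(dat[[nm]]))
      stop(sprintf("column '%s' is not numeric", nm))
    if (anyNA(dat[[nm]]))
      stop(sprintf("column '%s' contains missing values", nm))
  }
  dt <- diff(dat$time)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-8)
    stop("'time' must be equally spaced")
  if (!all(dat$x %in% c(0, 1)))
    stop("'x' must be a 0/1 intervention indicator")
  dat
}
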