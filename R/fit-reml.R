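# REML estimation of regression with ARMA errors, Satterthwaite degrees of
# freedom, and the first-order Kenward-Roger variance adjustment.  The
# error covariance is built densely from the analytic ARMA autocovariance;
# this targets short series (the regime where REML matters), where a dense
# n x n Cholesky is cheap.

# Map unconstrained optimiser coordinates to ARMA coefficients.  AR
# coefficients go through the partial-autocorrelation (tanh) transform so
# any coordinate value yields a stationary model; MA coefficients are
# unconstrained because every real theta gives a valid (PSD) moving-average
# covariance.
.reml_pars <- function(par, p, q) {
  phi <- numeric(0)
  if (p > 0) {
    r <- tanh(par[seq_len(p)])
    a <- numeric(0)
    for (k in seq_len(p)) {      # Durbin-Levinson map from PACF to AR
      if (k > 1) a <- a - r[k] * rev(a)
      a <- c(a, r[k])
    }
    phi <- a
  }
  theta <- if (q > 0) par[p + seq_len(q)] else numeric(0)
  list(phi = phi, theta = theta)
}

# Flip MA roots inside the unit circle to their invertible mirror.  The
# autocorrelation (and hence the REML objective) is unchanged up to the
# innovation-variance scale, which is re-profiled afterwards.
.ma_invert <- function(theta) {
  q <- length(theta)
  if (q == 0 || all(theta == 0)) return(theta)
  r <- polyroot(c(1, theta))
  flip <- Mod(r) < 1
  if (!any(flip)) return(theta)
  r[flip] <- 1 / Conj(r[flip])
  co <- 1
  for (z in r) co <- c(co, 0) - c(0, co) / z
  Re(co[-1])
}

# GLS pieces at a given unit-variance error correlation matrix V0:
# whitened design/response, beta-hat, profiled sigma2 and the two
# log-determinants entering the restricted likelihood.
.reml_gls <- function(X, y, V0) {
  L <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  qrx <- qr(Xs)
  beta <- qr.coef(qrx, ys)
  rs <- ys - drop(Xs %*% beta)
  XtX <- crossprod(Xs)
  Lx <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(Lx)) return(NULL)
  list(beta = beta, rq = sum(rs^2), ldV0 = 2 * sum(log(diag(L))),
       ldX = 2 * sum(log(diag(Lx))), XtVXinv = chol2inv(Lx), L = L)
}

.reml_V0 <- function(par, p, q, n) {
  pr <- .reml_pars(par, p, q)
  g <- tryCatch(arma_autocov(pr$phi, pr$theta, sigma2 = 1, lag_max = n - 1L),
                error = function(e) NULL)
  if (is.null(g)) return(NULL)
  toeplitz(g)
}

# Negative profiled restricted log-likelihood (sigma2 profiled out).
.reml_nll_profiled <- function(par, X, y, p, q) {
  n <- nrow(X); k <- ncol(X)
  V0 <- .reml_V0(par, p, q, n)
  if (is.null(V0)) return(1e10)
  gls <- .reml_gls(X, y, V0)
  if (is.null(gls) || gls$rq <= 0) return(1e10)
  sigma2 <- gls$rq / (n - k)
  0.5 * ((n - k) * (log(2 * pi) + log(sigma2) + 1) + gls$ldV0 + gls$ldX)
}

# var(beta_hat_j) as a function of the full parameter vector psi.
.reml_phi_fun <- function(psi, X, y, p, q, j) {
  sigma2 <- psi[length(psi)]
  V0 <- .reml_V0(psi[-length(psi)], p, q, nrow(X))
  if (is.null(V0)) return(NA_real_)
  gls <- .reml_gls(X, y, V0)
  if (is.null(gls)) return(NA_real_)
  sigma2 * gls$XtVXinv[j, j]
}

# Central-difference gradient with relative step.
.num_grad <- function(f, x, h = 1e-4 * (1 + abs(x))) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

# REML fit of the regression with an ARMA(p,q) error model.  Returns the
# internal state needed for Satterthwaite/Kenward-Roger computations.
.reml_state <- function(X, y, p = 0L, q = 3L) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k + p + q)
    stop("series too short for the requested error model")
  npar <- p + q
  converged <- TRUE
  if (npar == 0L) {
    par <- numeric(0)
  } else {
    nll <- function(u) .reml_nll_profiled(u, X, y, p, q)
    if (npar == 1L) {
      opt <- optim(0, nll, method = "Brent", lower = -6, upper = 6)
    } else {
      opt <- optim(rep(0, npar), nll, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10))
    }
    converged <- opt$convergence == 0 && opt$value < 1e9
    par <- opt$par
  }
  pr <- .reml_pars(par, p, q)
  # report the invertible MA representation; objective value is unchanged
  if (q > 0) {
    th_inv <- .ma_invert(pr$theta)
    par[p + seq_len(q)] <- th_inv
    pr$theta <- th_inv
  }
  V0 <- .reml_V0(par, p, q, n)
  gls <- if (!is.null(V0)) .reml_gls(X, y, V0) else NULL
  if (is.null(gls)) {
    return(list(ok = FALSE, converged = FALSE, p = p, q = q, n = n, k = k))
  }
  sigma2 <- gls$rq / (n - k)
  Phi <- sigma2 * gls$XtVXinv
  dimnames(Phi) <- list(colnames(X), colnames(X))
  list(ok = TRUE, converged = converged, p = p, q = q, n = n, k = k,
       par = par, phi = pr$phi, theta = pr$theta, sigma2 = sigma2,
       beta = setNames(gls$beta, colnames(X)), Phi = Phi, V0 = V0,
       X = X, y = y, psi = c(par, sigma2))
}

# Small-sample inference pieces shared by Satterthwaite and Kenward-Roger:
# derivative matrices dV/dpsi_i (numeric central differences for the error
# parameters, analytic for sigma2), the expected (Fisher) REML information
# I_ab = tr(P V_a P V_b) / 2 with P = V^{-1} - V^{-1}X Phi X'V^{-1}, and
# the KR building blocks P_i, Q_ij.
.reml_inference <- function(state, j = 2L, kr = TRUE) {
  n <- state$n; k <- state$k
  phi_hat <- state$Phi[j, j]
  if (state$p + state$q == 0L) {
    # iid error model: phi-hat is proportional to a chi-square with n - k
    # degrees of freedom, so d = n - k exactly and KR changes nothing
    return(list(phi = phi_hat, var_phi = 2 * phi_hat^2 / (n - k),
                d = n - k, vcov = state$Phi))
  }
  X <- state$X
  psi <- state$psi
  npsi <- length(psi)
  V <- state$sigma2 * state$V0
  Vinv <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(Vinv))
    return(list(phi = phi_hat, var_phi = NA_real_, d = NA_real_,
                vcov = state$Phi))
  Xv <- Vinv %*% X
  Pmat <- Vinv - Xv %*% state$Phi %*% t(Xv)
  par <- state$par
  h <- 1e-4 * (1 + abs(par))
  dV <- vector("list", npsi)
  for (i in seq_len(npsi - 1L)) {
    e <- numeric(npsi - 1L); e[i] <- h[i]
    Vp <- .reml_V0(par + e, state$p, state$q, n)
    Vm <- .reml_V0(par - e, state$p, state$q, n)
    if (is.null(Vp) || is.null(Vm))
      return(list(phi = phi_hat, var_phi = NA_real_, d = NA_real_,
                  vcov = state$Phi))
    dV[[i]] <- state$sigma2 * (Vp - Vm) / (2 * h[i])
  }
  dV[[npsi]] <- state$V0
  PV <- lapply(dV, function(Vi) Pmat %*% Vi)
  I_E <- matrix(0, npsi, npsi)
  for (a in seq_len(npsi)) for (b in a:npsi)
    I_E[a, b] <- I_E[b, a] <- 0.5 * sum(PV[[a]] * t(PV[[b]]))
  W <- tryCatch(solve(I_E), error = function(e) NULL)
  if (is.null(W) || any(!is.finite(W)))
    return(list(phi = phi_hat, var_phi = NA_real_, d = NA_real_,
                vcov = state$Phi))
  g <- .num_grad(function(ps)
    .reml_phi_fun(ps, X, state$y, state$p, state$q, j), psi)
  var_phi <- drop(t(g) %*% W %*% g)
  d <- if (is.finite(var_phi) && var_phi > 0) 2 * phi_hat^2 / var_phi
       else NA_real_
  vcov <- state$Phi
  if (kr) {
    # first-order Kenward-Roger bias adjustment:
    # Phi_A = Phi + 2 Phi [ sum_ab W_ab (Q_ab - P_a Phi P_b) ] Phi
    Pmx <- lapply(dV, function(Vi) crossprod(Xv, Vi %*% Xv))
    VvX <- lapply(dV, function(Vi) Vinv %*% (Vi %*% Xv))
    M <- 0
    for (a in seq_len(npsi)) for (b in seq_len(npsi)) {
      Qab <- crossprod(Xv, dV[[a]] %*% VvX[[b]])
      M <- M + W[a, b] * (Qab - Pmx[[a]] %*% state$Phi %*% Pmx[[b]])
    }
    PhiA <- state$Phi + 2 * state$Phi %*% M %*% state$Phi
    PhiA <- (PhiA + t(PhiA)) / 2
    dimnames(PhiA) <- dimnames(state$Phi)
    vcov <- PhiA
  }
  list(phi = phi_hat, var_phi = var_phi, d = d, vcov = vcov)
}

# Lean fit record: REML estimation, Satterthwaite df, optional KR SE.
.fit_reml <- function(X, y, p = 0L, q = 3L, kr = TRUE, level = 0.95,
                      intervention = 2L) {
  state <- .reml_state(X, y, p = p, q = q)
  cn <- colnames(X)
  k_reg <- ncol(X)
  if (!isTRUE(state$ok)) {
    beta <- setNames(rep(NA_real_, k_reg), cn)
    return(.fit_record("reml", beta, matrix(NA_real_, k_reg, k_reg),
                       df = Inf, level = level, converged = FALSE,
                       extras = list(p = p, q = q, kr = kr)))
  }
  sat <- .reml_inference(state, j = intervention, kr = kr)
  vcov <- sat$vcov
  df <- if (is.finite(sat$d) && sat$d > 0) sat$d else state$n - state$k
  resid <- y - drop(X %*% state$beta)
  .fit_record("reml", state$beta, vcov, df = df, level = level,
              resid = resid, sigma2 = state$sigma2,
              converged = state$converged && is.finite(sat$d),
              extras = list(p = p, q = q, kr = kr, phi_ar = state$phi,
                            theta = state$theta, d = sat$d,
                            var_phi = sat$var_phi,
                            se_unadj = sqrt(state$Phi[intervention,
                                                      intervention]),
                            state = state))
}

#' Satterthwaite degrees of freedom of a REML fit
#'
#' For a fit produced by [its_fit()] with `method = "reml"`, returns the
#' variance of the intervention-effect estimate
#' \eqn{\hat\phi = \widehat{var}(\hat\beta_1)}, the estimated variance of
#' \eqn{\hat\phi} obtained by the delta method from the inverse expected
#' (Fisher) REML information, and the matched degrees of freedom
#' \eqn{d = 2\hat\phi^2 / \widehat{var}(\hat\phi)}.  Under the iid error
#' model \eqn{d = n - k} exactly.
#'
#' @param fit An `"its_fit"` object with method `"reml"`.
#' @return List with elements `phi`, `var_phi`, `d`.
#' @export
satterthwaite_df <- function(fit) {
  if (!inherits(fit, "its_fit") || fit$method != "reml")
    stop("'fit' must be an its_fit object with method = \"reml\"")
  ex <- fit$extras
  list(phi = ex$state$Phi[fit$intervention_index, fit$intervention_index],
       var_phi = ex$var_phi, d = ex$d)
}
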