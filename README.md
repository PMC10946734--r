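# itsreg

Segmented regression for interrupted time series (ITS) with
autocorrelated errors.

An ITS is a sequence of equally spaced population-level measurements
interrupted by an event — a vaccine introduction, a policy change, a
pandemic — whose effect is estimated as the level change `β₁` in the
segmented regression model

```
y_t = β0 + β1·x_t + β2·t + ε_t,    x_t = 1{t ≥ τ}.
```

The errors `ε_t` of such series are almost always positively
autocorrelated, which leaves OLS point estimates unbiased but makes the
classical standard error of `β̂₁` too small, so confidence intervals
under-cover.  `itsreg` provides, behind one modelling interface, the
estimators epidemiologists and biostatisticians actually use for this
problem, plus small-sample corrections:

* **OLS** with classical t(n−k) intervals (the uncorrected baseline);
* **Newey-West**: OLS estimates with Bartlett-kernel HAC standard errors,
  lag chosen by the automatic plug-in rule or by the deterministic rules
  ⌊n^1/4⌋, ⌊0.75·n^1/3⌋, ⌊1.3·n^1/2⌋;
* **Prais-Winsten / Cochrane-Orcutt** feasible GLS under AR(1) errors
  (iterated quasi-differencing, first observation retained and rescaled
  by √(1−φ₁²) in the Prais-Winsten variant);
* **ARMA-error regression** by exact maximum likelihood, with stepwise
  AICc order selection under the constraint p, q ≤ 5;
* **REML** estimation of the error model with **Satterthwaite** degrees
  of freedom d = 2φ²/var(φ̂) (φ = var(β̂₁)) and the first-order
  **Kenward-Roger** variance adjustment, for trustworthy intervals on
  short series.

A Monte-Carlo engine (`run_study()`, `power_experiment()`) evaluates the
estimators on synthetic ITS data with MA(3) errors whose coefficients are
drawn from nested uniforms — positive, decreasing autocorrelation up to
lag 3 — reporting bias, RMSE, coverage and power with Monte-Carlo errors.

## Worked example

```r
library(itsreg)
dat <- simulate_its(50, theta = c(0.8, 0.5, 0.2), seed = 1)   # strong autocorrelation
fit <- its_fit(y ~ x + time, dat, method = "pw")
summary(fit)
#> ITS segmented regression (method: pw, n = 50)
#>             Estimate Std. Error t value Pr(>|t|)
#> (Intercept)  4.50441    0.60740   7.416 1.92e-09 ***
#> x           -1.19884    0.82171  -1.459    0.151
#> time        -0.02388    0.03085  -0.774    0.443
#> reference distribution: t with 47.00 df
#> AR(1) coefficient: 0.6263 (3 iterations)
```

The intervention effect is estimated at −1.20 (true value −1) with an
AR(1) autocorrelation estimate of 0.63.  Comparing methods on the same
series:

```r
analyze_its(dat, methods = c("ols", "pw", "arma", "nw"))
#> ITS method comparison
#>  method estimate lower  upper  df converged
#>     ols    -1.19 -2.43  0.058  47      TRUE
#>      pw    -1.20 -2.85  0.454  47      TRUE
#>    arma    -1.61 -2.63 -0.590 Inf      TRUE
#>      nw    -1.19 -2.79  0.418  47      TRUE
```

The OLS interval is the narrowest — deceptively so under this much
autocorrelation; the autocorrelation-aware methods widen it.  For
incidence rates analysed on the log₂ scale,
`analyze_its(..., transform = "log2")` also reports effects as percent
reductions `100·(1 − 2^β̂)`.

A small simulation study:

```r
study <- run_study(its_study_config(n_scenarios = 5, nsim = 200,
                                    methods = c("ols", "pw", "nw"), seed = 1))
aggregate_metrics(study)                  # grid means: bias, RMSE, coverage, power
aggregate_metrics(study, rho1_min = 0.6)  # high-autocorrelation stratum
```

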