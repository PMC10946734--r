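test_that("metrics reproduce hand-computed values", {
  r <- data.frame(est = c(0, 2), lower = c(-10, -10), upper = c(10, 10))
  m <- compute_metrics(r, true_beta1 = 1)
  expect_equal(m$bias, 0)
  expect_equal(m$rmse, 1)
  expect_equal(m$emp_se, sqrt(2))
  expect_equal(m$coverage, 1)
  expect_equal(m$power, 0)

  # binomial Monte-Carlo SE at B = 2000, coverage 0.95
  B <- 2000
  r2 <- data.frame(est = rep(0, B), lower = rep(-1, B), upper = rep(1, B))
  r2$lower[1:100] <- 0.5   # exactly 100 non-covering intervals for truth 0
  m2 <- compute_metrics(r2, true_beta1 = 0)
  expect_equal(m2$coverage, 0.95)
  expect_equal(m2$mc_se_coverage, sqrt(0.95 * 0.05 / 2000))
  expect_equal(round(m2$mc_se_coverage, 5), 0.00487)
})

test_that("rmse, bias and empirical SE satisfy the decomposition identity", {
  set.seed(71)
  for (i in 1:5) {
    B <- sample(50:500, 1)
    r <- data.frame(est = rnorm(B, -1, 0.7), lower = -2, upper = 0)
    m <- compute_metrics(r, true_beta1 = -1)
    expect_equal(m$rmse^2, m$bias^2 + (B - 1) / B * m$emp_se^2,
                 tolerance = 1e-12)
  }
})

test_that("non-converged replicates are excluded and counted", {
  r <- data.frame(est = c(1, 2, NA, 4), lower = -10, upper = 10,
                  converged = c(1, 1, 0, 0))
  m <- compute_metrics(r, true_beta1 = 2)
  expect_equal(m$nsim_used, 2)
  expect_equal(m$n_nonconverged, 2)
  # all failed: metrics missing, full count
  m0 <- compute_metrics(data.frame(est = c(NA, NA), lower = NA, upper = NA,
                                   converged = c(0, 0)), 0)
  expect_equal(m0$nsim_used, 0)
  expect_equal(m0$n_nonconverged, 2)
  expect_true(is.na(m0$bias))
})

test_that("the study grid is deterministic and substreams are stable under
           method and replicate subsetting", {
  sc <- sample_scenarios(2, seed = 5)
  cfg <- its_study_config(scenarios = sc, n_grid = 20, nsim = 40,
                          methods = c("ols", "pw"), seed = 9)
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(s1$metrics, s2$metrics)

  # dropping a method does not change the other method's results
  cfg_ols <- its_study_config(scenarios = sc, n_grid = 20, nsim = 40,
                              methods = "ols", seed = 9)
  s3 <- run_study(cfg_ols)
  expect_equal(s3$metrics, s1$metrics[s1$metrics$method == "ols", ],
               ignore_attr = TRUE)

  # a per-method replicate cap sees the leading datasets of the same stream
  cfg_half <- its_study_config(scenarios = sc, n_grid = 20, nsim = 40,
                               methods = c("ols", "pw"),
                               nsim_by_method = list(pw = 20), seed = 9)
  cfg_20 <- its_study_config(scenarios = sc, n_grid = 20, nsim = 20,
                             methods = "pw", seed = 9)
  s4 <- run_study(cfg_half)
  s5 <- run_study(cfg_20)
  expect_equal(s5$metrics, s4$metrics[s4$metrics$method == "pw", ],
               ignore_attr = TRUE)
})

test_that("OLS and Newey-West share point estimates within every cell", {
  sc <- sample_scenarios(2, seed = 6)
  cfg <- its_study_config(scenarios = sc, n_grid = c(20, 50), nsim = 60,
                          methods = c("ols", "nw"), seed = 10)
  s <- run_study(cfg)
  m <- s$metrics
  for (cell in split(m, list(m$scenario_id, m$n))) {
    expect_equal(cell$bias[cell$method == "ols"],
                 cell$bias[cell$method == "nw"])
    expect_equal(cell$emp_se[cell$method == "ols"],
                 cell$emp_se[cell$method == "nw"])
    expect_equal(cell$rmse[cell$method == "ols"],
                 cell$rmse[cell$method == "nw"])
  }
})

test_that("aggregation returns unweighted cell means and flags empty
           strata", {
  sc <- sample_scenarios(3, seed = 8)
  cfg <- its_study_config(scenarios = sc, n_grid = c(20, 50), nsim = 30,
                          methods = "ols", seed = 2)
  s <- run_study(cfg)
  agg <- aggregate_metrics(s)
  expect_equal(agg$coverage, mean(s$metrics$coverage))
  # single-cell stratum equals that cell's value
  one <- s$metrics[s$metrics$scenario_id == 1 & s$metrics$n == 20, ]
  agg1 <- aggregate_metrics(s, rho1_min = one$rho1, rho1_max = one$rho1 + 1e-9,
                            n_max = 20)
  expect_equal(agg1$coverage, one$coverage)
  expect_warning(aggregate_metrics(s, rho1_min = 2), "no cells")
})

test_that("known-parameter GLS attains nominal coverage", {
  sc <- sample_scenarios(1, seed = 12)
  cfg <- its_study_config(scenarios = sc, n_grid = 20, nsim = 600,
                          methods = "known_gls", seed = 3)
  m <- run_study(cfg)$metrics
  expect_lt(abs(m$coverage - 0.95), 3 * m$mc_se_coverage + 1e-12)
})

test_that("the power experiment reports OLS df = 47 in every replicate", {
  pe <- power_experiment(n = 50, nsim = 100, methods = "ols", seed = 4)
  expect_equal(pe$mean_df, 47)
  expect_equal(pe$nsim_used, 100)
  expect_true(pe$power > 0 && pe$power < 1)
})

test_that("study configuration is validated", {
  expect_error(its_study_config(methods = "magic"), "unknown method")
  expect_error(its_study_config(nsim = 1), "nsim")
  expect_error(its_study_config(n_grid = c(8, 20)), "at least 12")
  expect_error(its_study_config(nsim = 100,
                                nsim_by_method = list(ols = 200)),
               "cannot exceed")
})
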