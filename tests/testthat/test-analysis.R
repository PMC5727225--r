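test_that("Shannon diversity matches hand-computed values", {
  expect_equal(shannon(5), 0)
  expect_equal(shannon(c(10, 10)), log(2))
  expect_equal(shannon(c(3, 1)), -0.75 * log(0.75) - 0.25 * log(0.25))
  expect_equal(shannon(c(3, 1)), 0.562335, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "positive")
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("Shannon diversity is maximal iff equi-abundant and label-invariant", {
  set.seed(31)
  for (n in c(2, 5, 9)) {
    expect_equal(shannon(rep(7, n)), log(n))
    x <- rpois(n, 40) + 1
    expect_lte(shannon(x), log(n) + 1e-12)
    expect_equal(shannon(x), shannon(sample(x)))  # relabeling
    if (var(x) > 0) expect_lt(shannon(x), log(n))
  }
})

test_that("richness counts extant types above the threshold", {
  tr <- coevo_sim(lv_config(t_max = 100, seed = 8))
  expect_equal(richness(tr), c(prey = 1, predator = 1))
  # a threshold above every abundance leaves nothing to count
  expect_equal(unname(richness(tr, min_count = 1e6)), c(0, 0))
  # with min_count = 1 richness equals the extant-type count at each sample
  cfg <- sim_config(fast_params(mu_x = 2e-3), t_max = 200, seed = 15)
  tr2 <- coevo_sim(cfg)
  expect_equal(richness(tr2)[["prey"]], mean(rowSums(tr2$prey >= 1)))
  expect_error(richness(tr2, t_window = c(500, 600)), "window")
})

test_that("outcomes are classified from extant totals at the horizon", {
  tr <- coevo_sim(lv_config(t_max = 100, seed = 8))
  expect_identical(classify_outcome(tr), "coexistence")
  expect_error(classify_outcome(tr, t_horizon = 1e4), "beyond")
  # predator-only start decays to prey_extinct or both_extinct
  cfg <- sim_config(fast_params(), init_prey_count = 0L, init_pred_count = 50L,
                    t_max = 200, seed = 4)
  tr2 <- coevo_sim(cfg)
  expect_true(classify_outcome(tr2) %in% c("prey_extinct", "both_extinct"))
  # classification at the final horizon always agrees with the engine status
  for (seed in 1:6) {
    cfg3 <- sim_config(coevo_params(m = 0.5), t_max = 400, seed = seed)
    tr3 <- coevo_sim(cfg3)
    expect_identical(classify_outcome(tr3), tr3$status)
  }
})

test_that("phase lag recovers constructed lags and refuses aperiodic series", {
  t <- seq(0, 20 * pi, by = 0.1)  # lag resolution dt / period ~ 0.016
  period <- 2 * pi
  prey <- sin(t)
  set.seed(66)
  expect_equal(phase_lag(prey, sin(t - period / 4), sample_dt = 0.1), 0.25,
               tolerance = 0.02)
  expect_equal(phase_lag(prey, -sin(t), sample_dt = 0.1), 0.5,
               tolerance = 0.05)  # finite-series edge bias of the ccf
  # white noise: no significant spectral peak
  expect_true(is.na(phase_lag(rnorm(500), rnorm(500))))
  # constant series are undefined
  expect_true(is.na(phase_lag(rep(3, 100), rnorm(100))))
})

test_that("ensemble summaries partition outcomes and condition on coexistence", {
  cfg <- lv_config(t_max = 60, seed = 0)
  trs <- lapply(1:5, function(i) { c2 <- cfg; c2$seed <- i; coevo_sim(c2) })
  es <- ensemble_summary(trs)
  expect_equal(sum(es$fractions), 1)
  expect_equal(es$n_runs, 5)
  # mutation-free: coexistence-conditional richness is exactly (1, 1)
  expect_equal(es$mean_richness, c(prey = 1, predator = 1))
  expect_equal(es$mean_shannon, c(prey = 0, predator = 0))
  # mixed horizons are rejected
  cfg2 <- lv_config(t_max = 90, seed = 1)
  expect_error(ensemble_summary(c(trs, list(coevo_sim(cfg2)))), "mixed|horizon")
})

test_that("run_ensemble seeds are deterministic and restartable", {
  cfg <- lv_config(t_max = 50, seed = 0)
  a <- run_ensemble(cfg, 4, base_seed = 10)
  b <- run_ensemble(cfg, 4, base_seed = 10)
  expect_identical(a$runs, b$runs)
  expect_identical(a$runs$seed, 11:14)
})

test_that("run_sweep tabulates per-m ensembles deterministically", {
  cfg <- lv_config(t_max = 50, seed = 0)
  sw <- run_sweep(c(0.5, 3), runs_per_m = 3, config = cfg, base_seed = 100)
  expect_identical(nrow(sw), 2L)
  expect_equal(sw$coexistence + sw$predator_extinct + sw$prey_extinct +
                 sw$both_extinct, c(1, 1))
  # mutation-free sweep: richness columns are exactly 1
  expect_equal(sw$prey_richness, c(1, 1))
  expect_equal(sw$predator_richness, c(1, 1))
  sw2 <- run_sweep(c(0.5, 3), runs_per_m = 3, config = cfg, base_seed = 100)
  expect_identical(sw, sw2)
  runs <- attr(sw, "runs")
  expect_identical(nrow(runs), 6L)
})
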