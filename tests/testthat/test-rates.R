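test_that("predation rate evaluates the power-law trade-off", {
  p <- coevo_params(p = 0.005, m = 3, k_max = 0.3)
  expect_equal(predation_rate(1.0, 0.3, p), 0.005)
  expect_equal(predation_rate(0.5, 0.3, p), 6.25e-4)   # 0.005 * 0.5^3
  expect_equal(predation_rate(0.5, 0.1, p), 2.5e-3)    # exponent m*k/kmax = 1
  # an undefended prey is consumed at the full rate p under any predator
  for (k in seq(0.05, 0.3, by = 0.05))
    expect_equal(predation_rate(1, k, p), 0.005)
  expect_error(predation_rate(0, 0.3, p), "g")
  expect_error(predation_rate(1.2, 0.3, p), "g")
  expect_error(predation_rate(0.5, 0.31, p), "k")
  expect_error(predation_rate(0.5, 0, p), "k")
})

test_that("predation rate is increasing in g, decreasing in k, bounded by p", {
  p <- coevo_params()
  gs <- seq(0.1, 0.9, by = 0.1)
  ks <- seq(0.05, p$k_max, by = 0.05)
  f <- outer(gs, ks, predation_rate, params = p)
  expect_true(all(f > 0 & f <= p$p))
  expect_true(all(apply(f, 2, diff) > 0))  # finite differences in g
  expect_true(all(apply(f, 1, diff) < 0))  # finite differences in k (g < 1)
})

test_that("trade-off curve shape is classified by the effective exponent", {
  p <- coevo_params(m = 3, k_max = 0.3)
  naive <- tradeoff_shape(p$k_max, p)
  expect_equal(naive$exponent, 3)
  expect_identical(naive$shape, "concave_cheap")
  lin <- tradeoff_shape(p$k_max, coevo_params(m = 1))
  expect_equal(lin$exponent, 1)
  expect_identical(lin$shape, "linear")
  # an evolved predator at k = kmax/3 makes an m = 3 trade-off linear
  evolved <- tradeoff_shape(p$k_max / 3, p)
  expect_equal(evolved$exponent, 1)
  expect_identical(evolved$shape, "linear")
  expect_identical(tradeoff_shape(p$k_max / 30, p)$shape, "convex_costly")
  expect_error(tradeoff_shape(0.4, p), "k")
})

test_that("carrying capacity matches the logistic fixed point", {
  p <- coevo_params(b_x = 1, d_x = 0.1, r_c = 5e-5)
  expect_equal(carrying_capacity(1, p), 18000)
  expect_error(carrying_capacity(0.1, p), "not viable")  # growth = death
  p2 <- coevo_params(r_c = 1e-4)
  expect_equal(carrying_capacity(1, p2), carrying_capacity(1, p) / 2)
})

test_that("mean-field fixed point has the closed form and flags non-coexistence", {
  p <- coevo_params(b_x = 1, d_x = 0.1, r_c = 5e-5, p = 0.005, m = 3,
                    k_max = 0.3, d_y = 0.5)
  fp <- meanfield_fixed_point(1, 0.3, p)
  expect_equal(fp$prey, 1000 / 3, tolerance = 1e-12)
  expect_equal(fp$predator, 176.6667, tolerance = 1e-6)
  expect_true(fp$coexists)
  # X* scales with the predator death rate: a near-immortal predator
  # suppresses the prey towards zero in the mean field
  fp_small <- meanfield_fixed_point(1, 0.3, coevo_params(d_y = 1e-6))
  expect_lt(fp_small$prey, 1e-3)
  # when X* would exceed the prey carrying capacity the predator starves
  p_starve <- coevo_params(d_y = 50)
  fp2 <- meanfield_fixed_point(1, 0.3, p_starve)
  expect_false(fp2$coexists)
  expect_gte(fp2$prey, carrying_capacity(1, p_starve))
})

test_that("closed-form equilibria agree with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  p <- coevo_params(r_c = 5e-4)
  g <- 0.8; k <- 0.2
  f <- predation_rate(g, k, p)
  rhs <- function(t, s, parms) {
    list(c(X = (p$b_x * g - p$d_x - p$r_c * s[1] - f * s[2]) * s[1],
           Y = (k * f * s[1] - p$d_y) * s[2]))
  }
  out <- deSolve::ode(c(X = 500, Y = 50), seq(0, 4000, by = 100), rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  fin <- out[nrow(out), c("X", "Y")]
  fp <- meanfield_fixed_point(g, k, p)
  expect_equal(unname(fin[["X"]]), fp$prey, tolerance = 1e-6)
  expect_equal(unname(fin[["Y"]]), fp$predator, tolerance = 1e-6)

  # prey alone relaxes to the carrying capacity
  rhs0 <- function(t, s, parms)
    list((p$b_x * g - p$d_x - p$r_c * s[1]) * s[1])
  out0 <- deSolve::ode(c(X = 10), seq(0, 500, by = 10), rhs0, NULL,
                       rtol = 1e-12, atol = 1e-12)
  expect_equal(unname(out0[nrow(out0), "X"]), carrying_capacity(g, p),
               tolerance = 1e-6)
})

test_that("parameter validation names the offending key", {
  expect_error(coevo_params(m = -1), "'m'")
  expect_error(coevo_params(k_max = 1), "'k_max'")
  expect_error(coevo_params(mu_x = 1), "'mu_x'")
  expect_error(coevo_params(d_y = -0.1), "'d_y'")
  expect_error(coevo_params(mutation_kernel = "normal", sigma_g = 0), "'sigma_g'")
})
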