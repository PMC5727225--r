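test_that("identical seed and configuration give bit-identical trajectories", {
  cfg <- sim_config(fast_params(), t_max = 100, seed = 42)
  a <- coevo_sim(cfg)
  b <- coevo_sim(cfg)
  expect_identical(a$prey, b$prey)
  expect_identical(a$predator, b$predator)
  expect_identical(a$genealogy, b$genealogy)
  expect_identical(a$tallies, b$tallies)
  expect_identical(a$status, b$status)
  # a different seed gives a different realisation
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(coevo_sim(cfg2)$tallies, a$tallies))
})

test_that("without mutation the type sets never grow", {
  tr <- coevo_sim(lv_config(t_max = 200, seed = 5))
  expect_identical(ncol(tr$prey), 1L)
  expect_identical(ncol(tr$predator), 1L)
  expect_identical(nrow(tr$genealogy), 2L)
  expect_equal(tr$tallies[["prey_birth_mutant"]], 0)
  expect_equal(tr$tallies[["predation_reproduction_mutant"]], 0)
  expect_equal(unname(richness(tr)), c(1, 1))
})

test_that("event tallies balance the population book-keeping", {
  cfg <- sim_config(fast_params(mu_x = 1e-3, mu_y = 1e-3), t_max = 150, seed = 9)
  tr <- coevo_sim(cfg)
  tl <- tr$tallies
  n_end <- nrow(tr$prey)
  prey_final <- sum(tr$prey[n_end, ])
  pred_final <- sum(tr$predator[n_end, ])
  prey_in <- sum(cfg$init_prey_count) + tl[["prey_birth"]] + tl[["prey_birth_mutant"]]
  prey_out <- tl[["prey_competition_death"]] + tl[["prey_intrinsic_death"]] +
    tl[["predation"]] + tl[["predation_reproduction"]] +
    tl[["predation_reproduction_mutant"]]
  expect_equal(prey_in - prey_out, prey_final)
  pred_in <- sum(cfg$init_pred_count) + tl[["predation_reproduction"]] +
    tl[["predation_reproduction_mutant"]]
  expect_equal(pred_in - tl[["predator_death"]], pred_final)
  # abundances are non-negative integers throughout
  expect_true(all(tr$prey >= 0) && all(tr$predator >= 0))
  expect_true(is.integer(tr$prey) && is.integer(tr$predator))
})

test_that("the genealogy is consistent: unique ids, parents precede children", {
  cfg <- sim_config(fast_params(mu_x = 2e-3, mu_y = 5e-3), t_max = 300, seed = 21)
  tr <- coevo_sim(cfg)
  for (sp in c("prey", "predator")) {
    gen <- tr$genealogy[tr$genealogy$species == sp, ]
    expect_false(any(duplicated(gen$id)))
    kids <- gen[!is.na(gen$parent_id), ]
    if (nrow(kids)) {
      t_parent <- gen$t_origin[match(kids$parent_id, gen$id)]
      expect_true(all(t_parent <= kids$t_origin))
    }
    ext <- gen[!is.na(gen$t_extinct), ]
    if (nrow(ext)) expect_true(all(ext$t_extinct >= ext$t_origin))
    # extant columns at the horizon are exactly the types without t_extinct
    mat <- tr[[sp]]
    extant_ids <- as.integer(colnames(mat))[mat[nrow(mat), ] > 0]
    expect_setequal(extant_ids, gen$id[is.na(gen$t_extinct)])
  }
})

test_that("prey-only populations fluctuate around the carrying capacity", {
  # stationary mean within 3 standard errors of (b_x g - d_x)/r_c,
  # estimated across independent runs for three growth traits
  p <- coevo_params(mu_x = 0, mu_y = 0, r_c = 5e-3)
  for (g in c(0.3, 0.6, 1.0)) {
    K <- carrying_capacity(g, p)
    means <- vapply(1:8, function(i) {
      cfg <- sim_config(p, init_prey_g = g, init_prey_count = round(K),
                        init_pred_count = 0L, t_max = 400, seed = 300 + i)
      time_avg_totals(coevo_sim(cfg), t_from = 100)[["prey"]]
    }, numeric(1))
    se <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - K), 3 * se + 1)  # +1 covers the O(1) bias
  }
})

test_that("the mutation-free system tracks the mean-field cycle centre", {
  tr <- coevo_sim(lv_config(t_max = 500, seed = 77))
  fp <- meanfield_fixed_point(1, 0.3, fast_params())
  avg <- time_avg_totals(tr, t_from = 100)
  expect_equal(avg[["prey"]], fp$prey, tolerance = 0.15)
  expect_equal(avg[["predator"]], fp$predator, tolerance = 0.15)
})

test_that("after prey extinction predators only decay", {
  # start with predators alone: pure death process, prey never reappears
  cfg <- sim_config(fast_params(), init_prey_g = 1, init_prey_count = 0L,
                    init_pred_k = 0.3, init_pred_count = 200L,
                    t_max = 100, seed = 3)
  tr <- coevo_sim(cfg)
  tot <- rowSums(tr$predator)
  expect_true(all(diff(tot) <= 0))
  expect_true(all(rowSums(tr$prey) == 0))
  expect_identical(tr$status, if (tot[length(tot)] > 0) "prey_extinct" else "both_extinct")
  expect_equal(sum(tr$tallies) , tr$tallies[["predator_death"]])
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(coevo_params(), t_max = 0), "t_max")
  expect_error(sim_config(coevo_params(), sample_dt = -1), "sample_dt")
  expect_error(sim_config(coevo_params(), init_prey_count = -5), "non-negative")
  expect_error(sim_config(coevo_params(), init_pred_k = 0.5), "init_pred_k")
  expect_error(sim_config(coevo_params(), init_prey_g = 1.2), "init_prey_g")
})
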