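test_that("prey propensities follow the per-type rate laws", {
  p <- coevo_params(b_x = 1, d_x = 0.1, r_c = 5e-5, mu_x = 0)
  # a lone individual has nobody to compete with
  s1 <- population_state(prey_g = 1, prey_count = 1, pred_count = 0)
  expect_equal(prey_propensities(s1, p)$competition, 0)
  # mu_x = 0: all births are faithful
  s2 <- population_state(prey_g = 1, prey_count = 1000, pred_count = 0)
  pp <- prey_propensities(s2, p)
  expect_equal(pp$birth, 1000)
  expect_equal(pp$birth_mut, 0)
  expect_equal(pp$death, 100)
  # two types: each individual competes with every other, within and
  # between types alike
  s3 <- population_state(prey_g = c(0.5, 1), prey_count = c(100, 200),
                         pred_count = 0)
  pp3 <- prey_propensities(s3, p)
  expect_equal(pp3$competition, c(100 * 299 * 5e-5, 200 * 299 * 5e-5))
  expect_equal(pp3$competition[1], 1.495)
  # mutation splits the birth rate by mu_x
  p4 <- coevo_params(mu_x = 0.01)
  pp4 <- prey_propensities(s2, p4)
  expect_equal(pp4$birth_mut / (pp4$birth + pp4$birth_mut), 0.01)
  expect_equal(pp4$total, sum(pp4$birth, pp4$birth_mut, pp4$competition, pp4$death))
})

test_that("predation propensities are mass-action with exact branch probabilities", {
  p <- coevo_params(p = 0.005, m = 3, k_max = 0.3, mu_y = 1e-3)
  s <- population_state(prey_g = 1, prey_count = 1000,
                        pred_k = 0.3, pred_count = 100)
  q <- predation_propensities(s, p)
  expect_equal(as.numeric(q$pair_rate), 0.005 * 1000 * 100)  # = 500
  expect_equal(q$predator_death, 0.5 * 100)
  # branch probabilities partition every predation event
  for (k in c(0.05, 0.17, 0.3)) {
    s2 <- population_state(prey_g = 0.7, prey_count = 10, pred_k = k,
                           pred_count = 5)
    q2 <- predation_propensities(s2, p)
    expect_equal(colSums(q2$branch_prob), setNames(1, NULL), tolerance = 1e-15)
    expect_equal(unname(q2$branch_prob["prey_death_only", 1]), 1 - k)
    expect_equal(unname(q2$branch_prob["reproduction_mutant", 1]), k * 1e-3)
  }
  # empty species: zero-count types are dropped, mass action gives zero
  s0 <- population_state(prey_g = 1, prey_count = 100, pred_k = 0.3,
                         pred_count = 0)
  expect_equal(predation_propensities(s0, p)$total, 0)
  # prey-only evolution scenario: the mutant branch is switched off
  pfix <- coevo_params(mu_y = 1e-3, predator_evolves = FALSE)
  qfix <- predation_propensities(s, pfix)
  expect_equal(unname(qfix$branch_prob["reproduction_mutant", 1]), 0)
  expect_equal(unname(qfix$branch_prob["reproduction", 1]), 0.3)
})

test_that("single steps realise the stoichiometry of their channel", {
  # pure-birth configuration: counts can only increase
  p <- coevo_params(b_x = 1, d_x = 0, r_c = 0, mu_x = 0)
  s <- population_state(prey_g = 0.5, prey_count = 10, pred_count = 0)
  set.seed(11)
  for (i in 1:25) {
    st <- ssa_step(s, p)
    expect_identical(st$event$class, "prey_birth")
    expect_identical(sum(st$state$prey$count), sum(s$prey$count) + 1L)
    expect_gt(st$dt, 0)
    s <- st$state
  }

  # pure-predation configuration: prey decreases by exactly 1 per event,
  # predators change by 0 or +1
  p2 <- coevo_params(b_x = 0, d_x = 0, r_c = 0, d_y = 0, mu_y = 0.2)
  s2 <- population_state(prey_g = 1, prey_count = 500, pred_k = 0.3,
                         pred_count = 50)
  set.seed(12)
  for (i in 1:40) {
    st <- ssa_step(s2, p2)
    expect_true(st$event$class %in%
      c("predation", "predation_reproduction", "predation_reproduction_mutant"))
    expect_identical(sum(st$state$prey$count), sum(s2$prey$count) - 1L)
    expect_true((sum(st$state$predator$count) - sum(s2$predator$count)) %in% 0:1)
    s2 <- st$state
  }
  # mutant predators were registered with genealogy
  reg <- s2$registry
  muts <- reg[reg$species == "predator" & !is.na(reg$parent_id), ]
  if (nrow(muts) > 0) {
    expect_true(all(muts$trait > 0 & muts$trait <= 0.3))
    expect_true(all(muts$t_origin > 0))
  }
})

test_that("an empty system is absorbing", {
  p <- coevo_params()
  s <- population_state(prey_g = 1, prey_count = 0, pred_count = 0)
  st <- ssa_step(s, p)
  expect_identical(st$event$class, "absorbed")
  expect_identical(st$dt, Inf)
})

test_that("waiting times at frozen propensities are exponential", {
  # repeated draws from one fixed state: the direct method's waiting time
  # is Exponential(R) with R the total propensity
  p <- coevo_params(mu_x = 0, mu_y = 0)
  s <- population_state(prey_g = 0.8, prey_count = 300, pred_k = 0.2,
                        pred_count = 40)
  R <- prey_propensities(s, p)$total + predation_propensities(s, p)$total
  set.seed(99)
  n <- 3000
  dts <- vapply(seq_len(n), function(i) ssa_step(s, p)$dt, numeric(1))
  expect_equal(mean(dts), 1 / R, tolerance = 3 / sqrt(n))  # 3 SE, CV of exp = 1
  expect_equal(sd(dts) / mean(dts), 1, tolerance = 0.06)   # exponential CV
})
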