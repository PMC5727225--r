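# shared fixtures: small, fast parameterisations used across test files

# baseline rates with competition scaled up 10x (smaller, faster populations)
fast_params <- function(...) {
  do.call(coevo_params, modifyList(list(r_c = 5e-4), list(...)))
}

# a no-mutation one-prey one-predator configuration (stochastic
# Lotka-Volterra with logistic competition)
lv_config <- function(t_max = 300, seed = 1, ...) {
  sim_config(fast_params(mu_x = 0, mu_y = 0, ...), t_max = t_max, seed = seed)
}

# time average of total abundance over [t_from, horizon]
time_avg_totals <- function(traj, t_from) {
  sel <- traj$times >= t_from
  c(prey = mean(rowSums(traj$prey[sel, , drop = FALSE])),
    predator = mean(rowSums(traj$predator[sel, , drop = FALSE])))
}
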