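#' Classify the outcome of a realisation at a time horizon
#'
#' Reads the total abundances at the sample time closest from below to
#' `t_horizon` and classifies: both positive is coexistence; only prey is
#' predator extinction; only predators is prey extinction; neither is
#' joint extinction.
#'
#' @param traj a [coevo_sim()] trajectory.
#' @param t_horizon evaluation time; defaults to the trajectory horizon.
#' @return One of `"coexistence"`, `"predator_extinct"`, `"prey_extinct"`,
#'   `"both_extinct"`.
#' @export
classify_outcome <- function(traj, t_horizon = NULL) {
  stopifnot(inherits(traj, "coevo_trajectory"))
  if (is.null(t_horizon)) t_horizon <- max(traj$times)
  if (t_horizon > max(traj$times) + 1e-9)
    stop("'t_horizon' lies beyond the recorded trajectory", call. = FALSE)
  i <- max(which(traj$times <= t_horizon + 1e-9))
  nx <- sum(traj$prey[i, ]); ny <- sum(traj$predator[i, ])
  if (nx > 0 && ny > 0) "coexistence"
  else if (nx > 0) "predator_extinct"
  else if (ny > 0) "prey_extinct"
  else "both_extinct"
}

#' Time-averaged type richness of a trajectory
#'
#' At every sample time inside the window, counts the types of each species
#' with abundance at least `min_count`, then averages over the window. With
#' the default `min_count = 1` this is the number of extant lineages; a
#' larger threshold discounts transient single-copy mutants.
#'
#' @param traj a [coevo_sim()] trajectory.
#' @param t_window numeric length-2 window `c(from, to)`; defaults to the
#'   full trajectory.
#' @param min_count abundance threshold for a type to count.
#' @return Named numeric vector `c(prey = ..., predator = ...)`.
#' @export
richness <- function(traj, t_window = NULL, min_count = 1L) {
  stopifnot(inherits(traj, "coevo_trajectory"))
  if (is.null(t_window)) t_window <- range(traj$times)
  sel <- traj$times >= t_window[1] - 1e-9 & traj$times <= t_window[2] + 1e-9
  if (!any(sel)) stop("empty time window", call. = FALSE)
  c(prey = mean(rowSums(traj$prey[sel, , drop = FALSE] >= min_count)),
    predator = mean(rowSums(traj$predator[sel, , drop = FALSE] >= min_count)))
}

#' Shannon diversity of a set of type abundances
#'
#' \eqn{H = -\sum_i q_i \ln q_i} over the frequencies \eqn{q_i} of types
#' with positive counts. Zero for a monomorphic population, maximal at
#' \eqn{\ln n} when all `n` types are equi-abundant.
#'
#' @param abundances non-negative per-type counts with at least one
#'   positive entry.
#' @return The Shannon index (natural log).
#' @examples
#' shannon(c(1, 1))       # ln 2
#' shannon(c(3, 1))
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  tot <- sum(abundances)
  if (tot <= 0) stop("at least one abundance must be positive", call. = FALSE)
  q <- abundances[abundances > 0] / tot
  -sum(q * log(q))
}

#' Time-averaged Shannon diversity per species
#'
#' Convenience companion to [richness()]: the Shannon index of each
#' species' type-abundance distribution at every sample time inside the
#' window where the species is extant, averaged over those times.
#'
#' @inheritParams richness
#' @return Named numeric vector `c(prey = ..., predator = ...)`; `NA` for a
#'   species extinct throughout the window.
#' @export
shannon_diversity <- function(traj, t_window = NULL) {
  stopifnot(inherits(traj, "coevo_trajectory"))
  if (is.null(t_window)) t_window <- range(traj$times)
  sel <- traj$times >= t_window[1] - 1e-9 & traj$times <= t_window[2] + 1e-9
  if (!any(sel)) stop("empty time window", call. = FALSE)
  one <- function(m) {
    m <- m[sel, , drop = FALSE]
    tot <- rowSums(m)
    live <- tot > 0
    if (!any(live)) return(NA_real_)
    mean(apply(m[live, , drop = FALSE], 1, shannon))
  }
  c(prey = one(traj$prey), predator = one(traj$predator))
}

#' Phase lag between prey and predator cycles
#'
#' Estimates the dominant cycle period of the (mean-removed) total-prey
#' series from its periodogram and the time shift of the predator series
#' that maximises the cross-correlation, and reports the lag as a fraction
#' of the period in \[0, 1). Classical predator-prey cycles show a
#' quarter-period lag (0.25); rapid prey evolution can push cycles towards
#' antiphase (0.5). When no significant periodicity is present (the
#' periodogram peak does not exceed a permutation-based threshold), the
#' lag is undefined and `NA` is returned.
#'
#' @param prey_totals,predator_totals equal-length numeric series of total
#'   abundances on a regular grid.
#' @param sample_dt grid spacing.
#' @param n_perm number of permutations for the significance threshold of
#'   the spectral peak.
#' @param conf confidence level of the permutation threshold.
#' @return Lag/period in \[0, 1), or `NA_real_` when undefined.
#' @export
phase_lag <- function(prey_totals, predator_totals, sample_dt = 1,
                      n_perm = 199, conf = 0.95) {
  stopifnot(length(prey_totals) == length(predator_totals))
  n <- length(prey_totals)
  if (n < 8) stop("series too short for a phase estimate", call. = FALSE)
  if (sd(prey_totals) == 0 || sd(predator_totals) == 0) return(NA_real_)
  x <- prey_totals - mean(prey_totals)
  y <- predator_totals - mean(predator_totals)
  sp <- spec.pgram(x, plot = FALSE, detrend = TRUE, taper = 0)
  peak <- which.max(sp$spec)
  # null: max periodogram ordinate of the shuffled (aperiodic) series
  null_max <- replicate(n_perm, {
    max(spec.pgram(sample(x), plot = FALSE, detrend = TRUE, taper = 0)$spec)
  })
  if (sp$spec[peak] <= quantile(null_max, conf, names = FALSE)) return(NA_real_)
  period <- sample_dt / sp$freq[peak]
  max_h <- min(n - 3L, ceiling(period / sample_dt))
  cors <- vapply(0:max_h, function(h) {
    if (h == 0) cor(x, y) else cor(x[1:(n - h)], y[(1 + h):n])
  }, numeric(1))
  lag <- (which.max(cors) - 1L) * sample_dt
  (lag / period) %% 1
}

# per-run statistics used by ensemble aggregation
run_stats <- function(traj, t_horizon = NULL, min_count = 1L) {
  if (is.null(t_horizon)) t_horizon <- max(traj$times)
  rich <- richness(traj, c(0, t_horizon), min_count)
  div <- shannon_diversity(traj, c(0, t_horizon))
  data.frame(seed = traj$seed,
             outcome = classify_outcome(traj, t_horizon),
             prey_richness = rich[["prey"]],
             predator_richness = rich[["predator"]],
             prey_shannon = div[["prey"]],
             predator_shannon = div[["predator"]],
             prey_final = sum(traj$prey[length(traj$times), ]),
             predator_final = sum(traj$predator[length(traj$times), ]))
}

#' Summarise an ensemble of realisations
#'
#' Aggregates outcome classification, richness and Shannon diversity over
#' independent realisations of one configuration. Outcome fractions
#' partition the ensemble; richness and diversity means are conditional on
#' coexistence at the horizon, because diversity of an extinct species is
#' not meaningful and this is the standard conditioning for
#' coexistence-ensemble summaries.
#'
#' @param trajectories a list of [coevo_sim()] trajectories sharing one
#'   configuration, or a per-run data frame as produced by [run_ensemble()].
#' @param t_horizon classification time; defaults to the common horizon.
#' @param min_count richness threshold, see [richness()].
#' @return An object of class `"coevo_ensemble"`: a list with `n_runs`,
#'   `fractions` (named, summing to 1), conditional means
#'   `mean_richness` and `mean_shannon` (each `c(prey, predator)`),
#'   `n_coexisting` and the per-run data frame `runs`.
#' @export
ensemble_summary <- function(trajectories, t_horizon = NULL, min_count = 1L) {
  if (is.data.frame(trajectories)) {
    runs <- trajectories
  } else {
    stopifnot(length(trajectories) >= 1,
              all(vapply(trajectories, inherits, logical(1), "coevo_trajectory")))
    horizons <- vapply(trajectories, function(tr) max(tr$times), numeric(1))
    if (length(unique(horizons)) != 1)
      stop("trajectories have mixed horizons; ensembles must share one configuration",
           call. = FALSE)
    runs <- do.call(rbind, lapply(trajectories, run_stats,
                                  t_horizon = t_horizon, min_count = min_count))
  }
  outcomes <- c("coexistence", "predator_extinct", "prey_extinct", "both_extinct")
  fr <- vapply(outcomes, function(o) mean(runs$outcome == o), numeric(1))
  co <- runs$outcome == "coexistence"
  cond_mean <- function(col) if (any(co)) mean(runs[[col]][co]) else NA_real_
  structure(list(
    n_runs = nrow(runs),
    fractions = fr,
    n_coexisting = sum(co),
    mean_richness = c(prey = cond_mean("prey_richness"),
                      predator = cond_mean("predator_richness")),
    mean_shannon = c(prey = cond_mean("prey_shannon"),
                     predator = cond_mean("predator_shannon")),
    runs = runs), class = "coevo_ensemble")
}

#' @export
print.coevo_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d runs (%d coexisting at horizon)\n",
              x$n_runs, x$n_coexisting))
  cat("  outcome fractions:\n")
  for (nm in names(x$fractions))
    cat(sprintf("    %-18s %.3f\n", nm, x$fractions[[nm]]))
  cat(sprintf("  mean richness | coexistence: prey %.3f, predator %.3f\n",
              x$mean_richness[["prey"]], x$mean_richness[["predator"]]))
  cat(sprintf("  mean Shannon  | coexistence: prey %.3f, predator %.3f\n",
              x$mean_shannon[["prey"]], x$mean_shannon[["predator"]]))
  invisible(x)
}

#' Run an ensemble of independent realisations
#'
#' Runs `n_runs` realisations of one configuration with seeds
#' `base_seed + 1, ..., base_seed + n_runs` (restartable, order-independent)
#' and aggregates them with [ensemble_summary()]. Trajectories are
#' summarised on the fly and discarded unless `keep_trajectories = TRUE`.
#'
#' @param config a [sim_config()].
#' @param n_runs number of realisations.
#' @param base_seed seed offset; run `i` uses seed `base_seed + i`.
#' @param t_horizon,min_count passed to the per-run summaries.
#' @param keep_trajectories retain the full trajectory objects (memory!).
#' @return A `"coevo_ensemble"` (see [ensemble_summary()]); with
#'   `keep_trajectories = TRUE` the list gains a `trajectories` element.
#' @export
run_ensemble <- function(config, n_runs, base_seed = config$seed,
                         t_horizon = NULL, min_count = 1L,
                         keep_trajectories = FALSE) {
  stopifnot(inherits(config, "coevo_config"), n_runs >= 1)
  trajs <- if (keep_trajectories) vector("list", n_runs) else NULL
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i)
    tr <- coevo_sim(cfg)
    rows[[i]] <- run_stats(tr, t_horizon, min_count)
    if (keep_trajectories) trajs[[i]] <- tr
  }
  out <- ensemble_summary(do.call(rbind, rows))
  out$config <- config
  out$base_seed <- as.integer(base_seed)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Sweep the trade-off shape parameter m over ensembles
#'
#' Runs an ensemble for every value of `m` and tabulates coexistence
#' fractions and coexistence-conditional mean richness and Shannon
#' diversity per species — the standard diversity-versus-trade-off-shape
#' summary. Seeds are `base_seed + (j - 1) * runs_per_m + i` for run `i`
#' of the `j`-th `m` value, so sweeps over the same `base_seed` and run
#' count are paired across scenarios (e.g. coevolution versus prey-only
#' evolution).
#'
#' @param m_values trade-off shape values to sweep.
#' @param runs_per_m ensemble size per value.
#' @param config a [sim_config()] whose `m` is overridden per ensemble.
#' @param base_seed seed offset.
#' @param t_horizon,min_count passed to the per-run summaries.
#' @return A data frame with one row per `m`: outcome fractions,
#'   conditional mean richness/Shannon per species and `n_coexisting`;
#'   the per-run records are attached as attribute `"runs"`.
#' @export
run_sweep <- function(m_values, runs_per_m, config = sim_config(),
                      base_seed = config$seed, t_horizon = NULL,
                      min_count = 1L) {
  stopifnot(inherits(config, "coevo_config"), runs_per_m >= 1)
  rows <- vector("list", length(m_values))
  run_records <- vector("list", length(m_values))
  for (j in seq_along(m_values)) {
    cfg <- config
    cfg$params$m <- as.numeric(m_values[j])
    validate_params(cfg$params)
    es <- run_ensemble(cfg, runs_per_m,
                       base_seed = base_seed + (j - 1L) * runs_per_m,
                       t_horizon = t_horizon, min_count = min_count)
    rows[[j]] <- data.frame(
      m = m_values[j], n_runs = es$n_runs,
      coexistence = es$fractions[["coexistence"]],
      predator_extinct = es$fractions[["predator_extinct"]],
      prey_extinct = es$fractions[["prey_extinct"]],
      both_extinct = es$fractions[["both_extinct"]],
      n_coexisting = es$n_coexisting,
      prey_richness = es$mean_richness[["prey"]],
      predator_richness = es$mean_richness[["predator"]],
      prey_shannon = es$mean_shannon[["prey"]],
      predator_shannon = es$mean_shannon[["predator"]])
    run_records[[j]] <- cbind(m = m_values[j], es$runs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "runs") <- do.call(rbind, run_records)
  out
}
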