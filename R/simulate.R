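#' Simulation configuration
#'
#' Bundles model parameters, initial condition, horizon and seed for one
#' stochastic realisation. The default initial condition is the standard
#' naive starting point: a single undefended ancestor prey type
#' (\eqn{g_1 = 1}) with 1000 individuals and a single naive ancestor
#' predator type (\eqn{k_1 = k_{max}}) with 100 individuals.
#'
#' @param params a [coevo_params()] object.
#' @param init_prey_g,init_prey_count trait values and abundances of the
#'   initial prey types.
#' @param init_pred_k,init_pred_count trait values and abundances of the
#'   initial predator types; the default puts the ancestor at `k_max`.
#' @param t_max simulation horizon (time units).
#' @param sample_dt recording interval for the trajectory grid.
#' @param seed integer RNG seed; identical seed and configuration give a
#'   bit-identical trajectory.
#' @param stop_on_total_extinction stop as soon as both species are
#'   extinct. Since the fully extinct state is absorbing, this only affects
#'   whether the engine keeps formally advancing the clock; recorded
#'   trajectories are identical either way.
#' @param max_events hard cap on the number of events (guards against
#'   runaway parameterisations).
#' @return An object of class `"coevo_config"`.
#' @export
sim_config <- function(params = coevo_params(),
                       init_prey_g = 1.0, init_prey_count = 1000L,
                       init_pred_k = params$k_max, init_pred_count = 100L,
                       t_max = 2000, sample_dt = 1.0, seed = 1L,
                       stop_on_total_extinction = TRUE,
                       max_events = 1e9) {
  stopifnot(inherits(params, "coevo_params"))
  validate_params(params)
  if (!is.numeric(t_max) || length(t_max) != 1 || t_max <= 0)
    stop("invalid 't_max': must be a positive number", call. = FALSE)
  if (!is.numeric(sample_dt) || length(sample_dt) != 1 || sample_dt <= 0)
    stop("invalid 'sample_dt': must be a positive number", call. = FALSE)
  if (length(init_prey_g) != length(init_prey_count) ||
      length(init_pred_k) != length(init_pred_count))
    stop("initial traits and counts must have equal lengths", call. = FALSE)
  if (any(init_prey_count < 0) || any(init_pred_count < 0))
    stop("invalid initial counts: must be non-negative", call. = FALSE)
  if (length(init_prey_g) && (any(init_prey_g <= 0) || any(init_prey_g > 1)))
    stop("invalid 'init_prey_g': must lie in (0, 1]", call. = FALSE)
  if (length(init_pred_k) && (any(init_pred_k <= 0) || any(init_pred_k > params$k_max)))
    stop("invalid 'init_pred_k': must lie in (0, k_max]", call. = FALSE)
  structure(list(params = params,
                 init_prey_g = as.numeric(init_prey_g),
                 init_prey_count = as.integer(init_prey_count),
                 init_pred_k = as.numeric(init_pred_k),
                 init_pred_count = as.integer(init_pred_count),
                 t_max = as.numeric(t_max), sample_dt = as.numeric(sample_dt),
                 seed = as.integer(seed),
                 stop_on_total_extinction = isTRUE(stop_on_total_extinction),
                 max_events = as.numeric(max_events)),
            class = "coevo_config")
}

#' @export
print.coevo_config <- function(x, ...) {
  cat(sprintf("Simulation configuration: t_max = %g, sample_dt = %g, seed = %d\n",
              x$t_max, x$sample_dt, x$seed))
  cat(sprintf("  initial prey: %s individuals at g = %s\n",
              paste(x$init_prey_count, collapse = ", "),
              paste(signif(x$init_prey_g, 4), collapse = ", ")))
  cat(sprintf("  initial predators: %s individuals at k = %s\n",
              paste(x$init_pred_count, collapse = ", "),
              paste(signif(x$init_pred_k, 4), collapse = ", ")))
  print(x$params)
  invisible(x)
}

#' Run one stochastic realisation of the coevolution model
#'
#' Simulates the full reaction system exactly (direct-method SSA) from the
#' configured initial state until `t_max` or absorption, recording per-type
#' abundances on a fixed time grid (the state is held constant between
#' events). New types created by mutation are tracked with their parent,
#' trait and origin time; extinct types keep their extinction time.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `"coevo_trajectory"`: a list with
#'   \describe{
#'     \item{times}{sample-time grid.}
#'     \item{prey, predator}{integer abundance matrices, one row per sample
#'       time, one column per type ever created (column names are type ids;
#'       extinct or not-yet-born types have zero counts).}
#'     \item{genealogy}{data frame `species`, `id`, `parent_id`, `trait`,
#'       `t_origin`, `t_extinct` (`NA` while extant).}
#'     \item{tallies}{named event counts per reaction class.}
#'     \item{status}{terminal status at the horizon: `"coexistence"`,
#'       `"predator_extinct"`, `"prey_extinct"` or `"both_extinct"`.}
#'     \item{config, seed}{the full configuration echo.}
#'   }
#' @examples
#' cfg <- sim_config(coevo_params(mu_x = 0, mu_y = 0, r_c = 5e-3),
#'                   init_prey_count = 200, init_pred_count = 0,
#'                   t_max = 50, seed = 42)
#' traj <- coevo_sim(cfg)
#' summary(traj)
#' @export
coevo_sim <- function(config) {
  stopifnot(inherits(config, "coevo_config"))
  set.seed(config$seed)
  raw <- ssa_run_cpp(unclass(config$params),
                     config$init_prey_g, config$init_prey_count,
                     config$init_pred_k, config$init_pred_count,
                     config$t_max, config$sample_dt, config$max_events)
  times <- seq(0, by = raw$sample_dt, length.out = raw$n_samples)

  densify <- function(idx, type, cnt, n_types) {
    m <- matrix(0L, nrow = raw$n_samples, ncol = n_types)
    if (n_types) colnames(m) <- seq_len(n_types)
    if (length(idx)) m[cbind(idx, type)] <- as.integer(cnt)
    m
  }
  nx <- length(raw$prey_registry$trait)
  ny <- length(raw$pred_registry$trait)
  prey <- densify(raw$prey_sample, raw$prey_type, raw$prey_count, nx)
  pred <- densify(raw$pred_sample, raw$pred_type, raw$pred_count, ny)

  gen <- rbind(
    if (nx) data.frame(species = "prey", id = seq_len(nx),
                       parent_id = ifelse(raw$prey_registry$parent == 0,
                                          NA_integer_, raw$prey_registry$parent),
                       trait = raw$prey_registry$trait,
                       t_origin = raw$prey_registry$t_origin,
                       t_extinct = raw$prey_registry$t_extinct),
    if (ny) data.frame(species = "predator", id = seq_len(ny),
                       parent_id = ifelse(raw$pred_registry$parent == 0,
                                          NA_integer_, raw$pred_registry$parent),
                       trait = raw$pred_registry$trait,
                       t_origin = raw$pred_registry$t_origin,
                       t_extinct = raw$pred_registry$t_extinct))

  structure(list(times = times, prey = prey, predator = pred,
                 genealogy = gen,
                 tallies = setNames(as.numeric(raw$tallies), names(raw$tallies)),
                 status = raw$status, n_events = raw$n_events,
                 config = config, seed = config$seed),
            class = "coevo_trajectory")
}

#' @export
print.coevo_trajectory <- function(x, ...) {
  cat(sprintf("Coevolution trajectory: t in [0, %g], %d samples, seed %d\n",
              max(x$times), length(x$times), x$seed))
  cat(sprintf("  types ever created: %d prey, %d predator\n",
              sum(x$genealogy$species == "prey"),
              sum(x$genealogy$species == "predator")))
  cat(sprintf("  terminal status: %s\n", x$status))
  invisible(x)
}

#' @export
summary.coevo_trajectory <- function(object, ...) {
  nxt <- rowSums(object$prey); nyt <- rowSums(object$predator)
  out <- list(status = object$status,
              horizon = max(object$times),
              n_events = object$n_events,
              final_totals = c(prey = nxt[length(nxt)],
                               predator = nyt[length(nyt)]),
              mean_totals = c(prey = mean(nxt), predator = mean(nyt)),
              types_created = c(prey = sum(object$genealogy$species == "prey"),
                                predator = sum(object$genealogy$species == "predator")),
              tallies = object$tallies)
  class(out) <- "summary.coevo_trajectory"
  out
}

#' @export
print.summary.coevo_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory over [0, %g] (%s; %.0f events)\n",
              x$horizon, x$status, x$n_events))
  cat(sprintf("  final totals: %d prey, %d predators\n",
              x$final_totals[["prey"]], x$final_totals[["predator"]]))
  cat(sprintf("  time-mean totals: %.1f prey, %.1f predators\n",
              x$mean_totals[["prey"]], x$mean_totals[["predator"]]))
  cat(sprintf("  types created: %d prey, %d predator\n",
              x$types_created[["prey"]], x$types_created[["predator"]]))
  cat("  event tallies:\n")
  for (nm in names(x$tallies))
    cat(sprintf("    %-32s %.0f\n", nm, x$tallies[[nm]]))
  invisible(x)
}

#' Plot a coevolution trajectory
#'
#' `which = "totals"` draws total prey and predator abundances over time;
#' `which = "types"` draws the per-type abundances of one species, one line
#' per type, which makes invasion and extinction of mutant lineages
#' visible.
#'
#' @param x a `coevo_trajectory`.
#' @param which `"totals"` or `"types"`.
#' @param species species shown when `which = "types"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.coevo_trajectory <- function(x, which = c("totals", "types"),
                                  species = c("prey", "predator"), ...) {
  which <- match.arg(which)
  if (which == "totals") {
    m <- cbind(prey = rowSums(x$prey), predator = rowSums(x$predator))
    matplot(x$times, m, type = "l", lty = 1, col = c("black", "firebrick"),
            xlab = "time", ylab = "abundance", ...)
    legend("topright", legend = colnames(m), lty = 1,
           col = c("black", "firebrick"), bty = "n")
  } else {
    species <- match.arg(species)
    m <- x[[species]]
    cols <- hcl.colors(max(2L, ncol(m)), "Dark 3")
    matplot(x$times, m, type = "l", lty = 1, col = cols,
            xlab = "time", ylab = paste(species, "abundance per type"), ...)
  }
  invisible(x)
}
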