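#' Advance the population by one stochastic event
#'
#' One iteration of the direct-method stochastic simulation algorithm: the
#' waiting time to the next event is exponential with rate equal to the
#' total propensity \eqn{R}, and the event channel is chosen with
#' probability proportional to its propensity. The state is updated by the
#' channel's stoichiometry, mutant types are registered with their
#' genealogy, and types whose count reaches zero are pruned (their
#' extinction time recorded).
#'
#' This R-level stepper is the readable reference for the reaction system
#' and is convenient for fine-grained inspection and distributional tests;
#' whole trajectories are produced by the compiled engine behind
#' [coevo_sim()], which implements the same scheme.
#'
#' @param state a [population_state()].
#' @param params a [coevo_params()].
#' @return A list with `state` (the updated state, time advanced by `dt`),
#'   `dt` (the exponential waiting time) and `event` (a list describing the
#'   realised channel). When the total propensity is zero the state is
#'   absorbing: `dt` is `Inf` and the event class is `"absorbed"`.
#' @export
ssa_step <- function(state, params) {
  pp <- prey_propensities(state, params)
  qq <- predation_propensities(state, params)
  R <- pp$total + qq$total
  if (R <= 0) {
    return(list(state = state, dt = Inf, event = list(class = "absorbed")))
  }
  dt <- rexp(1, R)
  nx <- nrow(state$prey); ny <- nrow(state$predator)

  # one flat weight vector over all channels, in a fixed order
  w <- c(pp$birth + pp$birth_mut,      # prey birth per type (mutation decided after)
         pp$competition,               # competition death per type
         pp$death,                     # intrinsic death per type
         as.vector(qq$pair_rate),      # predation per (prey, predator) pair
         qq$predator_death)            # predator death per type
  ch <- sample.int(length(w), 1L, prob = w)
  state$t <- state$t + dt

  prune <- function(st, species, row) {
    df <- st[[species]]
    st$registry$t_extinct[st$registry$species == species &
                            st$registry$id == df$id[row]] <- st$t
    st[[species]] <- df[-row, , drop = FALSE]
    st
  }

  if (ch <= nx) {                                   # prey birth
    i <- ch
    if (params$mu_x > 0 && runif(1) < params$mu_x) {
      gnew <- draw_mutant_g(state$prey$trait[i], params)
      id <- state$next_prey_id
      state$next_prey_id <- id + 1L
      state$prey <- rbind(state$prey,
                          data.frame(id = id, trait = gnew, count = 1L))
      state$registry <- rbind(state$registry,
        data.frame(species = "prey", id = id, parent_id = state$prey$id[i],
                   trait = gnew, t_origin = state$t, t_extinct = NA_real_))
      event <- list(class = "prey_birth_mutant", parent_id = state$prey$id[i],
                    id = id, trait = gnew)
    } else {
      state$prey$count[i] <- state$prey$count[i] + 1L
      event <- list(class = "prey_birth", id = state$prey$id[i])
    }
  } else if (ch <= 2 * nx) {                        # competition death
    i <- ch - nx
    state$prey$count[i] <- state$prey$count[i] - 1L
    event <- list(class = "prey_competition_death", id = state$prey$id[i])
    if (state$prey$count[i] == 0L) state <- prune(state, "prey", i)
  } else if (ch <= 3 * nx) {                        # intrinsic death
    i <- ch - 2 * nx
    state$prey$count[i] <- state$prey$count[i] - 1L
    event <- list(class = "prey_intrinsic_death", id = state$prey$id[i])
    if (state$prey$count[i] == 0L) state <- prune(state, "prey", i)
  } else if (ch <= 3 * nx + nx * ny) {              # predation on pair (i, l)
    pair <- ch - 3 * nx
    i <- (pair - 1) %% nx + 1
    l <- (pair - 1) %/% nx + 1
    branch <- sample.int(3L, 1L, prob = qq$branch_prob[, l])
    if (branch == 1L) {
      event <- list(class = "predation", prey_id = state$prey$id[i],
                    predator_id = state$predator$id[l])
    } else if (branch == 2L) {
      state$predator$count[l] <- state$predator$count[l] + 1L
      event <- list(class = "predation_reproduction",
                    prey_id = state$prey$id[i],
                    predator_id = state$predator$id[l])
    } else {
      knew <- draw_mutant_k(state$predator$trait[l], params)
      id <- state$next_pred_id
      state$next_pred_id <- id + 1L
      state$predator <- rbind(state$predator,
                              data.frame(id = id, trait = knew, count = 1L))
      state$registry <- rbind(state$registry,
        data.frame(species = "predator", id = id,
                   parent_id = state$predator$id[l], trait = knew,
                   t_origin = state$t, t_extinct = NA_real_))
      event <- list(class = "predation_reproduction_mutant",
                    prey_id = state$prey$id[i], parent_id = state$predator$id[l],
                    id = id, trait = knew)
    }
    state$prey$count[i] <- state$prey$count[i] - 1L
    if (state$prey$count[i] == 0L) state <- prune(state, "prey", i)
  } else {                                          # predator death
    l <- ch - 3 * nx - nx * ny
    state$predator$count[l] <- state$predator$count[l] - 1L
    event <- list(class = "predator_death", id = state$predator$id[l])
    if (state$predator$count[l] == 0L) state <- prune(state, "predator", l)
  }

  list(state = state, dt = dt, event = event)
}
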