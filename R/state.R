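#' Construct a population state
#'
#' A snapshot of the individual-based model: the extant prey and predator
#' types with their trait values and integer abundances, plus a registry of
#' every type ever created (the genealogy). Propensity functions and the
#' single-step sampler [ssa_step()] operate on this representation.
#'
#' @param prey_g,prey_count trait values in (0, 1] and abundances of the
#'   extant prey types.
#' @param pred_k,pred_count reproduction efficacies in (0, k_max] and
#'   abundances of the extant predator types (`k_max` is checked against
#'   `params` when the state is used).
#' @param t current simulation time.
#' @return An object of class `"coevo_state"`: a list with `t`, data frames
#'   `prey` and `predator` (columns `id`, `trait`, `count`), a `registry`
#'   data frame (`species`, `id`, `parent_id`, `trait`, `t_origin`,
#'   `t_extinct`) and id counters for new types.
#' @export
population_state <- function(prey_g = 1.0, prey_count = 1000L,
                             pred_k = 0.3, pred_count = 100L, t = 0) {
  stopifnot(length(prey_g) == length(prey_count),
            length(pred_k) == length(pred_count))
  prey_count <- as.integer(prey_count); pred_count <- as.integer(pred_count)
  if (any(prey_count < 0) || any(pred_count < 0))
    stop("abundances must be non-negative", call. = FALSE)
  keepx <- prey_count > 0; keepy <- pred_count > 0
  prey <- data.frame(id = seq_len(sum(keepx)), trait = prey_g[keepx],
                     count = prey_count[keepx])
  pred <- data.frame(id = seq_len(sum(keepy)), trait = pred_k[keepy],
                     count = pred_count[keepy])
  registry <- rbind(
    if (nrow(prey)) data.frame(species = "prey", id = prey$id,
                               parent_id = NA_integer_, trait = prey$trait,
                               t_origin = t, t_extinct = NA_real_),
    if (nrow(pred)) data.frame(species = "predator", id = pred$id,
                               parent_id = NA_integer_, trait = pred$trait,
                               t_origin = t, t_extinct = NA_real_))
  structure(list(t = t, prey = prey, predator = pred, registry = registry,
                 next_prey_id = nrow(prey) + 1L,
                 next_pred_id = nrow(pred) + 1L),
            class = "coevo_state")
}

#' @export
print.coevo_state <- function(x, ...) {
  cat(sprintf("Population state at t = %g: %d prey (%d types), %d predators (%d types)\n",
              x$t, sum(x$prey$count), nrow(x$prey),
              sum(x$predator$count), nrow(x$predator)))
  invisible(x)
}

#' Prey reaction propensities
#'
#' Per extant prey type `i` with abundance \eqn{x_i} and trait \eqn{g_i}:
#' \itemize{
#'   \item birth without mutation at rate \eqn{b_x g_i (1 - \mu_x) x_i},
#'   \item birth with mutation at rate \eqn{b_x g_i \mu_x x_i},
#'   \item competition death at rate \eqn{r_c x_i (N_x - 1)} where
#'     \eqn{N_x} is total prey abundance (within- and between-type
#'     competition are identical; an individual does not compete with
#'     itself),
#'   \item intrinsic death at rate \eqn{d_x x_i}.
#' }
#'
#' @param state a [population_state()].
#' @param params a [coevo_params()].
#' @return A list of per-type numeric vectors `birth`, `birth_mut`,
#'   `competition`, `death` and the scalar `total`.
#' @export
prey_propensities <- function(state, params) {
  stopifnot(inherits(state, "coevo_state"), inherits(params, "coevo_params"))
  g <- state$prey$trait; x <- state$prey$count
  Nx <- sum(x)
  birth <- params$b_x * g * (1 - params$mu_x) * x
  birth_mut <- params$b_x * g * params$mu_x * x
  competition <- if (Nx > 1) params$r_c * x * (Nx - 1) else numeric(length(x)) * 0
  death <- params$d_x * x
  list(birth = birth, birth_mut = birth_mut, competition = competition,
       death = death,
       total = sum(birth) + sum(birth_mut) + sum(competition) + sum(death))
}

#' Predation and predator reaction propensities
#'
#' Each (prey type i, predator type l) pair is one predation channel with
#' total propensity \eqn{f(g_i, k_l) x_i y_l}. Conditional on a predation
#' event on the pair, the outcome branches: with probability \eqn{1 - k_l}
#' the prey dies and nothing else happens; with probability
#' \eqn{k_l (1 - \mu_y)} the prey dies and predator l reproduces; with
#' probability \eqn{k_l \mu_y} the prey dies and a mutant predator type is
#' born. The three branch rates are exactly the separate reaction rates of
#' the model, so collapsing them into one channel with post-draw branching
#' is mathematically identical. Predator death is a per-type channel at
#' rate \eqn{d_y y_l}. With `predator_evolves = FALSE` the mutant branch
#' has probability zero.
#'
#' @inheritParams prey_propensities
#' @return A list with `pair_rate` (matrix, prey types x predator types),
#'   `branch_prob` (3 x predator-types matrix with rows `prey_death_only`,
#'   `reproduction`, `reproduction_mutant`, each column summing to 1),
#'   `predator_death` (per-type vector) and the scalar `total`.
#' @export
predation_propensities <- function(state, params) {
  stopifnot(inherits(state, "coevo_state"), inherits(params, "coevo_params"))
  g <- state$prey$trait; x <- state$prey$count
  k <- state$predator$trait; y <- state$predator$count
  if (length(k) && any(k > params$k_max))
    stop("predator trait exceeds k_max", call. = FALSE)
  fmat <- outer(g, k, function(gi, kl) params$p * gi^(params$m * kl / params$k_max))
  pair_rate <- fmat * outer(x, y)
  mu_y <- if (params$predator_evolves) params$mu_y else 0
  branch_prob <- rbind(prey_death_only = 1 - k,
                       reproduction = k * (1 - mu_y),
                       reproduction_mutant = k * mu_y)
  predator_death <- params$d_y * y
  list(pair_rate = pair_rate, branch_prob = branch_prob,
       predator_death = predator_death,
       total = sum(pair_rate) + sum(predator_death))
}
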