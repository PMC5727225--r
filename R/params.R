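#' Model parameters for the coevolution model
#'
#' Bundles all global rates and trade-off constants of the individual-based
#' predator-prey model. Prey types carry a growth/defense trait
#' \eqn{g \in (0, 1]} (large \eqn{g}: fast growth, weak defense); predator
#' types carry a reproduction efficacy \eqn{k \in (0, k_{max}]}, the
#' probability that a predation event also produces a predator offspring.
#' Predation follows the power-law trade-off
#' \eqn{f(g, k) = p \, g^{m k / k_{max}}}, so the exponent \eqn{m} sets the
#' initial shape of the growth-defense trade-off under a naive predator
#' (\eqn{k = k_{max}}): concave and cheap for \eqn{m > 1}, linear at
#' \eqn{m = 1}, convex and costly for \eqn{m < 1}.
#'
#' Defaults are the baseline parameterisation used throughout: a prey
#' carrying capacity of 18000 at \eqn{g = 1}, weak mutation supply, and a
#' naive ancestor predator bounded at \eqn{k_{max} = 0.3}.
#'
#' @param b_x prey background birth rate (per individual per unit time);
#'   the realised birth rate of type \eqn{i} is \code{b_x * g_i}.
#' @param d_x prey intrinsic death rate.
#' @param r_c pairwise resource-competition rate; each prey individual dies
#'   from competition at rate \code{r_c * (N_x - 1)}, identical within and
#'   between types.
#' @param mu_x probability that a prey birth is a mutant birth, in \[0, 1).
#' @param d_y predator death rate.
#' @param mu_y probability that a predator reproduction event creates a
#'   mutant type, in \[0, 1).
#' @param p predation time-scale constant; \eqn{f(1, k) = p} for every k.
#' @param m initial trade-off shape parameter, > 0.
#' @param k_max upper limit of the predator reproduction efficacy, in (0, 1).
#' @param mutation_kernel \code{"uniform"} (mutant traits drawn uniformly on
#'   the trait range, independent of the parent) or \code{"normal"}
#'   (parent-centred Gaussian, resampled into the trait range).
#' @param sigma_g,sigma_k standard deviations of the normal kernel for the
#'   prey and predator trait (ignored by the uniform kernel).
#' @param predator_evolves if \code{FALSE}, predator mutation is switched
#'   off (the "evolution of only prey" scenario); the ancestor predator
#'   type is the only one ever present.
#'
#' @return An object of class \code{"coevo_params"} (a validated named list).
#' @examples
#' p <- coevo_params(m = 3)
#' predation_rate(0.5, 0.3, p)
#' carrying_capacity(1, p)
#' @export
coevo_params <- function(b_x = 1.0, d_x = 0.1, r_c = 5e-5, mu_x = 1e-4,
                         d_y = 0.5, mu_y = 1e-3, p = 0.005, m = 3,
                         k_max = 0.3,
                         mutation_kernel = c("uniform", "normal"),
                         sigma_g = 0.05, sigma_k = 0.015,
                         predator_evolves = TRUE) {
  mutation_kernel <- match.arg(mutation_kernel)
  obj <- structure(list(
    b_x = as.numeric(b_x), d_x = as.numeric(d_x), r_c = as.numeric(r_c),
    mu_x = as.numeric(mu_x), d_y = as.numeric(d_y), mu_y = as.numeric(mu_y),
    p = as.numeric(p), m = as.numeric(m), k_max = as.numeric(k_max),
    mutation_kernel = mutation_kernel,
    sigma_g = as.numeric(sigma_g), sigma_k = as.numeric(sigma_k),
    predator_evolves = isTRUE(predator_evolves)),
    class = "coevo_params")
  validate_params(obj)
  obj
}

validate_params <- function(p) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) stop("invalid parameter '", key, "': ", what, call. = FALSE)
  }
  for (key in c("b_x", "d_x", "r_c", "mu_x", "d_y", "mu_y", "p", "m",
                "k_max", "sigma_g", "sigma_k")) {
    chk(is.numeric(p[[key]]) && length(p[[key]]) == 1 && is.finite(p[[key]]),
        key, "must be a single finite number")
  }
  for (key in c("b_x", "d_x", "r_c", "d_y", "p")) {
    chk(p[[key]] >= 0, key, "rates must be non-negative")
  }
  chk(p$mu_x >= 0 && p$mu_x < 1, "mu_x", "must lie in [0, 1)")
  chk(p$mu_y >= 0 && p$mu_y < 1, "mu_y", "must lie in [0, 1)")
  chk(p$m > 0, "m", "must be > 0")
  chk(p$k_max > 0 && p$k_max < 1, "k_max", "must lie in (0, 1)")
  if (identical(p$mutation_kernel, "normal")) {
    chk(p$sigma_g > 0, "sigma_g", "must be > 0 for the normal kernel")
    chk(p$sigma_k > 0, "sigma_k", "must be > 0 for the normal kernel")
  }
  invisible(p)
}

#' @export
print.coevo_params <- function(x, ...) {
  cat("Coevolution model parameters\n")
  cat(sprintf("  prey:     b_x = %g, d_x = %g, r_c = %g, mu_x = %g\n",
              x$b_x, x$d_x, x$r_c, x$mu_x))
  cat(sprintf("  predator: d_y = %g, mu_y = %g, k_max = %g%s\n",
              x$d_y, x$mu_y, x$k_max,
              if (x$predator_evolves) "" else "  [predator does not evolve]"))
  cat(sprintf("  predation: f(g, k) = %g * g^(%g * k / %g)\n", x$p, x$m, x$k_max))
  cat(sprintf("  mutation kernel: %s", x$mutation_kernel))
  if (identical(x$mutation_kernel, "normal"))
    cat(sprintf(" (sigma_g = %g, sigma_k = %g)", x$sigma_g, x$sigma_k))
  cat("\n")
  invisible(x)
}
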