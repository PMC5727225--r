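#' Predation rate under the growth-defense trade-off
#'
#' Evaluates \eqn{f(g, k) = p \, g^{m k / k_{max}}}, the per prey-predator
#' pair predation rate. It increases with the prey growth trait \eqn{g}
#' (faster growth buys less defense) and decreases with the predator
#' reproduction efficacy \eqn{k} (investment in reproduction costs
#' predation ability). At \eqn{g = 1} (no defense) it equals \eqn{p}
#' regardless of the predator.
#'
#' @param g prey growth/defense trait(s), in (0, 1].
#' @param k predator reproduction efficacy(ies), in (0, k_max].
#' @param params a [coevo_params()] object.
#' @return Numeric vector of per-pair rates (recycled over `g` and `k`).
#' @export
predation_rate <- function(g, k, params) {
  stopifnot(inherits(params, "coevo_params"))
  if (any(!is.finite(g)) || any(g <= 0) || any(g > 1))
    stop("'g' must lie in (0, 1]", call. = FALSE)
  if (any(!is.finite(k)) || any(k <= 0) || any(k > params$k_max))
    stop("'k' must lie in (0, k_max]", call. = FALSE)
  params$p * g^(params$m * k / params$k_max)
}

#' Shape of the growth-defense trade-off curve for a given predator
#'
#' The trade-off curve plots prey growth \eqn{g} against the predation rate
#' \eqn{f(g, k)} for a fixed predator background \eqn{k}. Its curvature is
#' governed by the effective exponent \eqn{e = m k / k_{max}}: when
#' \eqn{e > 1} the curve is concave and defense is cheap (a small growth
#' cost buys a large defense gain); when \eqn{e < 1} it is convex and
#' defense is costly; \eqn{e = 1} is linear. As the predator evolves
#' towards smaller \eqn{k}, the same prey trade-off becomes more convex:
#' the trade-off is dynamical.
#'
#' @inheritParams predation_rate
#' @param tol half-width of the band around \eqn{e = 1} reported as linear;
#'   exact \eqn{e = 1} arises for rational parameter choices, so the
#'   boundary is classified with a small numeric tolerance.
#' @return A list with `exponent` (\eqn{e}) and `shape` (one of
#'   `"concave_cheap"`, `"linear"`, `"convex_costly"`).
#' @export
tradeoff_shape <- function(k, params, tol = 1e-9) {
  stopifnot(inherits(params, "coevo_params"), length(k) == 1)
  if (!is.finite(k) || k <= 0 || k > params$k_max)
    stop("'k' must lie in (0, k_max]", call. = FALSE)
  e <- params$m * k / params$k_max
  shape <- if (abs(e - 1) < tol) "linear"
           else if (e > 1) "concave_cheap"
           else "convex_costly"
  list(exponent = e, shape = shape)
}

#' Mean-field prey carrying capacity
#'
#' Deterministic equilibrium of a homogeneous prey population in isolation.
#' Without predation the prey grows logistically,
#' \eqn{dX/dt = (b_x g - d_x - r_c X) X}, with positive fixed point
#' \eqn{K = (b_x g - d_x) / r_c}. Used as an independent oracle for the
#' stochastic engine.
#'
#' @inheritParams predation_rate
#' @return The carrying capacity (scalar).
#' @export
carrying_capacity <- function(g, params) {
  stopifnot(inherits(params, "coevo_params"), length(g) == 1)
  if (!is.finite(g) || g <= 0 || g > 1) stop("'g' must lie in (0, 1]", call. = FALSE)
  net <- params$b_x * g - params$d_x
  if (net <= 0)
    stop("population not viable: b_x * g <= d_x", call. = FALSE)
  net / params$r_c
}

#' Mean-field coexistence fixed point of the one-prey one-predator system
#'
#' The reaction scheme with a single prey type (trait `g`) and a single
#' predator type (efficacy `k`) induces the mean-field system
#' \deqn{dX/dt = (b_x g - d_x - r_c X - f Y) X, \quad
#'       dY/dt = (k f X - d_y) Y,}
#' with \eqn{f = f(g, k)}. Its interior fixed point is
#' \eqn{X^* = d_y / (k f)} and \eqn{Y^* = (b_x g - d_x - r_c X^*) / f}.
#' Stochastic realisations cycle around this point; the time-averaged
#' abundances of long runs land near it, which makes it the main oracle for
#' validating the simulation engine.
#'
#' @inheritParams predation_rate
#' @return A list with `prey` (\eqn{X^*}), `predator` (\eqn{Y^*}) and
#'   `coexists` (`FALSE` when \eqn{Y^* \le 0}, i.e. the predator cannot be
#'   sustained and \eqn{X^*} exceeds the prey carrying capacity).
#' @export
meanfield_fixed_point <- function(g, k, params) {
  stopifnot(inherits(params, "coevo_params"), length(g) == 1, length(k) == 1)
  f <- predation_rate(g, k, params)
  if (f <= 0) stop("predation rate is zero; no predator fixed point", call. = FALSE)
  X <- params$d_y / (k * f)
  Y <- (params$b_x * g - params$d_x - params$r_c * X) / f
  list(prey = X, predator = Y, coexists = Y > 0)
}
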