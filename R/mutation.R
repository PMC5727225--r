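#' Draw mutant trait values
#'
#' Mutant traits are drawn either from a uniform distribution over the full
#' trait range, independent of the parent (the default kernel), or from a
#' parent-centred normal distribution resampled until it falls inside the
#' range. Prey traits live on (0, 1]; predator reproduction efficacies on
#' (0, k_max]. Draws of exactly 0 are impossible (open lower bound);
#' resampling of the normal kernel is capped at 1000 attempts, after which
#' an error is thrown.
#'
#' @param parent_g,parent_k parental trait (used only by the normal kernel).
#' @param params a [coevo_params()]; `mutation_kernel`, `sigma_g`,
#'   `sigma_k` and `k_max` are read from it.
#' @param n number of draws.
#' @return Numeric vector of `n` mutant trait values.
#' @examples
#' p <- coevo_params()
#' draw_mutant_g(0.8, p, n = 5)
#' @export
draw_mutant_g <- function(parent_g, params, n = 1L) {
  stopifnot(inherits(params, "coevo_params"),
            is.finite(parent_g), parent_g > 0, parent_g <= 1)
  if (identical(params$mutation_kernel, "normal"))
    draw_trait_normal_cpp(n, parent_g, params$sigma_g, 1.0)
  else
    draw_trait_uniform_cpp(n, 1.0)
}

#' @rdname draw_mutant_g
#' @export
draw_mutant_k <- function(parent_k, params, n = 1L) {
  stopifnot(inherits(params, "coevo_params"),
            is.finite(parent_k), parent_k > 0, parent_k <= params$k_max)
  if (identical(params$mutation_kernel, "normal"))
    draw_trait_normal_cpp(n, parent_k, params$sigma_k, params$k_max)
  else
    draw_trait_uniform_cpp(n, params$k_max)
}
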