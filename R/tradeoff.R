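#' Fit a power-law trade-off curve to growth-assay data
#'
#' Fits \eqn{y = a z^c} by nonlinear least squares on the original scale,
#' where the predictor \eqn{z} is prey (bacteria) growth and the response
#' \eqn{y} is the mean predator (ciliate) growth on that prey — the proxy
#' for how poorly the prey is defended. The fitted exponent \eqn{c}
#' classifies the trade-off shape: \eqn{c > 1} concave (defense is cheap),
#' \eqn{c < 1} convex (defense is costly). Starting values come from an
#' ordinary linear regression on the log-log scale; the log-log fit is used
#' only for initialisation, never as the estimate, because least squares on
#' the original scale and on the log scale weight the observations
#' differently.
#'
#' @param formula a two-sided formula `response ~ predictor`, e.g.
#'   `predator_growth ~ prey_growth`.
#' @param data a data frame containing the formula variables, typically one
#'   row per prey population with the response already averaged over
#'   technical replicates (see [assay_means()]).
#' @param tol classification tolerance around \eqn{c = 1}, see
#'   [classify_tradeoff()].
#' @param normalize divide predictor and response by their values at the
#'   largest predictor (the ancestral, fastest-growing population) before
#'   fitting. Off by default: the exponent is scale-free, so normalisation
#'   only rescales \eqn{a}.
#' @return An object of class `"tradeoff_fit"` with components `a`, `c`,
#'   `r_squared`, `shape`, `n`, `fitted`, `residuals`, `data`, `converged`
#'   and the underlying `nls`-type fit, supporting `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()`, `fitted()`, `plot()` and
#'   `simulate()`.
#' @examples
#' d <- data.frame(z = c(0.2, 0.5, 0.9, 1.0))
#' d$y <- 3 * d$z^0.5
#' fit <- tradeoff_fit(y ~ z, d)
#' coef(fit)
#' @export
tradeoff_fit <- function(formula, data, tol = 0, normalize = FALSE) {
  mf <- stats::model.frame(formula, data)
  y <- mf[[1L]]
  z <- mf[[2L]]
  fit_power_law(z, y, tol = tol, normalize = normalize,
                call = match.call(), formula = formula)
}

#' @rdname tradeoff_fit
#' @param z,y predictor (prey growth) and response (mean predator growth)
#'   vectors for the plain-vector interface.
#' @param call,formula internal, used to label the returned object.
#' @export
fit_power_law <- function(z, y, tol = 0, normalize = FALSE,
                          call = NULL, formula = NULL) {
  if (length(z) != length(y)) stop("'z' and 'y' lengths differ", call. = FALSE)
  ok <- is.finite(z) & is.finite(y)
  z <- z[ok]; y <- y[ok]
  n <- length(z)
  if (n < 3) stop("need at least 3 points to fit a power law", call. = FALSE)
  if (any(z <= 0) || any(y <= 0))
    stop("growth rates must be strictly positive", call. = FALSE)
  if (isTRUE(normalize)) {
    ref <- which.max(z)
    y <- y / y[ref]
    z <- z / z[ref]
  }
  # log-log linear regression for starting values only
  ll <- lm(log(y) ~ log(z))
  start <- list(a = exp(unname(coef(ll)[1])), c = unname(coef(ll)[2]))
  d <- data.frame(z = z, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * z^c, data = d, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  converged <- !is.null(fit) && isTRUE(fit$convInfo$isConv)
  if (is.null(fit)) {
    a_hat <- start$a; c_hat <- start$c
    fitted_y <- a_hat * z^c_hat
    vc <- NULL
  } else {
    cf <- coef(fit)
    a_hat <- unname(cf[["a"]]); c_hat <- unname(cf[["c"]])
    fitted_y <- as.numeric(fitted(fit))
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  }
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(a = a_hat, c = c_hat, r_squared = r2,
                 shape = classify_tradeoff(c_hat, tol), n = n,
                 fitted = fitted_y, residuals = y - fitted_y,
                 data = d, start = start, converged = converged,
                 vcov = vc, normalize = isTRUE(normalize),
                 call = call, formula = formula, nls = fit),
            class = "tradeoff_fit")
}

#' Classify a trade-off exponent as cheap, costly or linear
#'
#' The exponent of the fitted power law \eqn{y = a z^c} (or the effective
#' exponent \eqn{e = m k / k_{max}} of the model's predation function)
#' determines the curvature of the growth-defense trade-off: `c > 1 + tol`
#' is concave — a small growth cost buys a large defense gain, defense is
#' cheap; `c < 1 - tol` is convex — defense is costly; the band around 1
#' is linear. The default `tol = 0` applies the strict inequalities.
#'
#' @param c fitted exponent(s).
#' @param tol half-width of the linear band.
#' @return Character vector: `"concave_cheap"`, `"convex_costly"` or
#'   `"linear"`.
#' @export
classify_tradeoff <- function(c, tol = 0) {
  stopifnot(is.numeric(c), all(is.finite(c)), tol >= 0)
  ifelse(c > 1 + tol, "concave_cheap",
         ifelse(c < 1 - tol, "convex_costly", "linear"))
}

#' @export
print.tradeoff_fit <- function(x, ...) {
  cat("Power-law trade-off fit: y = a * z^c\n")
  cat(sprintf("  a = %.6g, c = %.6g  (n = %d, R^2 = %.4f)\n",
              x$a, x$c, x$n, x$r_squared))
  cat(sprintf("  shape: %s%s\n", x$shape,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' @export
summary.tradeoff_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else c(a = NA, c = NA)
  out <- list(coefficients = cbind(Estimate = c(a = object$a, c = object$c),
                                   `Std. Error` = se),
              r_squared = object$r_squared, shape = object$shape,
              n = object$n, converged = object$converged,
              residuals = object$residuals)
  class(out) <- "summary.tradeoff_fit"
  out
}

#' @export
print.summary.tradeoff_fit <- function(x, ...) {
  cat("Power-law trade-off fit y = a * z^c\n\nCoefficients:\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("\nR-squared: %.5f on %d points; shape: %s\n",
              x$r_squared, x$n, x$shape))
  if (!x$converged) cat("Warning: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
coef.tradeoff_fit <- function(object, ...) c(a = object$a, c = object$c)

#' @export
residuals.tradeoff_fit <- function(object, ...) object$residuals

#' @export
fitted.tradeoff_fit <- function(object, ...) object$fitted

#' @export
predict.tradeoff_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  z <- if (is.data.frame(newdata)) {
    nm <- if (!is.null(object$formula)) all.vars(object$formula)[2] else "z"
    if (!nm %in% names(newdata)) nm <- names(newdata)[1]
    newdata[[nm]]
  } else as.numeric(newdata)
  object$a * z^object$c
}

#' @export
plot.tradeoff_fit <- function(x, ...) {
  plot(x$data$z, x$data$y, xlab = "prey growth z",
       ylab = "mean predator growth y", pch = 19, ...)
  zz <- seq(min(x$data$z), max(x$data$z), length.out = 200)
  lines(zz, x$a * zz^x$c, col = "firebrick", lwd = 2)
  mtext(sprintf("c = %.3f (%s), R^2 = %.3f", x$c, x$shape, x$r_squared),
        side = 3, line = 0.3, cex = 0.9)
  invisible(x)
}

#' @export
simulate.tradeoff_fit <- function(object, nsim = 1, seed = NULL, noise_cv = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_cv)) {
    # residual coefficient of variation around the fitted curve
    noise_cv <- sd(object$residuals / object$fitted)
  }
  mu <- object$fitted
  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- replicate(nsim, mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog))
  as.data.frame(out)
}

#' Generate a synthetic growth assay with power-law structure
#'
#' Emulates a small growth-assay design against one predator background:
#' `n_populations` prey populations with growth rates spread over
#' (0.2, 1.0] (the first, fastest-growing one playing the ancestor; the
#' default of 4 matches one ancestral plus three coevolved populations),
#' each measured in `replicates` technical replicates. Replicate responses
#' are \eqn{a z^c} times mean-one lognormal noise with coefficient of
#' variation `noise_cv`. With `noise_cv = 0` the replicate means reproduce
#' \eqn{a z^c} exactly, so [tradeoff_fit()] recovers `(a, c)` to machine
#' precision.
#'
#' @param a,c power-law parameters (> 0).
#' @param n_populations number of prey populations (>= 3).
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param replicates technical replicates per population.
#' @param seed optional integer seed for reproducibility.
#' @param prey_labels,pred_label population labels.
#' @return A `growth_assay` data frame with columns `prey_pop`, `pred_pop`,
#'   `prey_growth` and `rep1 ... repR`.
#' @export
synthetic_assay <- function(a = 1, c = 1, n_populations = 4,
                            noise_cv = 0.01, replicates = 3,
                            seed = NULL, prey_labels = NULL,
                            pred_label = "predator1") {
  if (!is.numeric(a) || a <= 0 || !is.numeric(c) || c <= 0)
    stop("'a' and 'c' must be positive", call. = FALSE)
  if (n_populations < 3)
    stop("'n_populations' must be at least 3", call. = FALSE)
  if (noise_cv < 0 || replicates < 1)
    stop("invalid 'noise_cv' or 'replicates'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- seq(1.0, 0.2, length.out = n_populations)
  if (is.null(prey_labels))
    prey_labels <- c("ancestor", paste0("coevolved", seq_len(n_populations - 1)))
  mu <- a * z^c
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  reps <- sapply(seq_len(replicates), function(r) {
    if (sdlog > 0) mu * rlnorm(n_populations, -sdlog^2 / 2, sdlog) else mu
  })
  reps <- matrix(reps, nrow = n_populations,
                 dimnames = list(NULL, paste0("rep", seq_len(replicates))))
  out <- data.frame(prey_pop = prey_labels, pred_pop = pred_label,
                    prey_growth = z)
  out <- cbind(out, as.data.frame(reps))
  class(out) <- c("growth_assay", "data.frame")
  out
}

#' Mean predator growth per (prey population, predator background)
#'
#' Collapses the technical replicates of a growth-assay table to their
#' mean, the response used for trade-off fitting.
#'
#' @param assay a `growth_assay` data frame ([synthetic_assay()] or
#'   [read_assay()]).
#' @return Data frame `prey_pop`, `pred_pop`, `prey_growth`,
#'   `predator_growth` (replicate mean).
#' @export
assay_means <- function(assay) {
  repcols <- grep("^rep[0-9]+$", names(assay), value = TRUE)
  if (!length(repcols)) stop("no replicate columns (rep1, rep2, ...)", call. = FALSE)
  data.frame(prey_pop = assay$prey_pop, pred_pop = assay$pred_pop,
             prey_growth = assay$prey_growth,
             predator_growth = rowMeans(assay[repcols]))
}

#' Fit trade-off curves for every predator background in an assay
#'
#' Splits the assay by predator background, averages technical replicates
#' and fits one power law per background.
#'
#' @inheritParams assay_means
#' @param tol classification tolerance, see [classify_tradeoff()].
#' @return A data frame with one row per background (`pred_pop`, `a`, `c`,
#'   `r_squared`, `shape`, `n_points`); the underlying `tradeoff_fit`
#'   objects are attached as attribute `"fits"`.
#' @export
fit_tradeoffs <- function(assay, tol = 0) {
  m <- assay_means(assay)
  backgrounds <- unique(m$pred_pop)
  fits <- lapply(backgrounds, function(b) {
    d <- m[m$pred_pop == b, ]
    if (nrow(d) < 3)
      stop("predator background '", b, "' has fewer than 3 points", call. = FALSE)
    fit_power_law(d$prey_growth, d$predator_growth, tol = tol)
  })
  names(fits) <- backgrounds
  out <- data.frame(pred_pop = backgrounds,
                    a = vapply(fits, `[[`, numeric(1), "a"),
                    c = vapply(fits, `[[`, numeric(1), "c"),
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                    shape = vapply(fits, `[[`, character(1), "shape"),
                    n_points = vapply(fits, `[[`, integer(1), "n"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
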