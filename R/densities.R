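## Likelihood kernels for the hierarchical models.

#' Normal log density
#'
#' Exact Gaussian log density with domain checks; the observation model of
#' the recovery-trajectory regressions.
#'
#' @param y observation(s).
#' @param mu mean.
#' @param sigma standard deviation (> 0).
#' @return log density, vectorised.
#' @export
log_density_normal <- function(y, mu, sigma) {
  if (any(!(sigma > 0))) stop("sigma must be > 0", call. = FALSE)
  stats::dnorm(y, mu, sigma, log = TRUE)
}

#' Gamma log density in mean-shape form
#'
#' Gamma distribution parameterised by its mean `mu` and shape `k`
#' (shape `k`, rate `k / mu`, so `E[y] = mu` and `Var[y] = mu^2 / k`); the
#' observation model of the carnivore/herbivore biomass regressions. With
#' `k = 1` it reduces to the Exponential distribution with mean `mu`.
#'
#' @param y observation(s), > 0.
#' @param mu mean (> 0).
#' @param k shape (> 0).
#' @return log density, vectorised.
#' @export
log_density_gamma_mean_shape <- function(y, mu, k) {
  if (any(!(y > 0))) stop("y must be > 0", call. = FALSE)
  if (any(!(mu > 0))) stop("mu must be > 0", call. = FALSE)
  if (any(!(k > 0))) stop("k must be > 0", call. = FALSE)
  stats::dgamma(y, shape = k, rate = k / mu, log = TRUE)
}

#' @rdname log_density_gamma_mean_shape
#' @param n number of draws.
#' @export
rgamma_mean_shape <- function(n, mu, k) {
  stats::rgamma(n, shape = k, rate = k / mu)
}

# half-Cauchy(0, scale) log density on x > 0
log_density_half_cauchy <- function(x, scale) {
  log(2) - log(pi) - log(scale) - log1p((x / scale)^2)
}
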