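## Generic MCMC: componentwise adaptive random-walk Metropolis over an
## arbitrary log-posterior closure, plus the posterior container class.
##
## Each parameter gets its own Gaussian proposal whose log step size is
## adapted during warmup toward a 44% acceptance rate (the optimum for
## one-dimensional random-walk proposals) and frozen afterwards, so the
## post-warmup chain is a fixed Markov kernel.

#' Sample a posterior with componentwise adaptive Metropolis
#'
#' General-purpose MCMC over any log-posterior function of a flat parameter
#' vector. One Metropolis update per parameter per iteration; per-parameter
#' step sizes adapt during warmup and are frozen afterwards. Runs are fully
#' reproducible given `seed` (chain `c` uses `seed + c - 1`).
#'
#' For the built-in hierarchical models prefer [fit_hier_model()], which
#' runs the same algorithm in compiled code with sparse updates.
#'
#' @param log_posterior function taking a parameter vector, returning the
#'   (unnormalised) scalar log posterior; must be finite at `init`.
#' @param init initial parameter vector (names are kept as parameter names).
#' @param n_iter iterations per chain, including warmup.
#' @param warmup adaptation iterations discarded from summaries.
#' @param n_chains number of independent chains.
#' @param seed integer seed.
#' @param step_init initial proposal SD.
#' @return a `posterior_samples` object: draws indexed (chain, iteration,
#'   parameter) with the warmup length recorded.
#' @export
sample_posterior <- function(log_posterior, init, n_iter = 7000, warmup = 1500,
                             n_chains = 3, seed = 1, step_init = 0.5) {
  stopifnot(warmup < n_iter, n_chains >= 1)
  n_par <- length(init)
  par_names <- if (!is.null(names(init))) names(init) else paste0("par", seq_len(n_par))
  lp0 <- log_posterior(init)
  if (!is.finite(lp0)) stop("log posterior not finite at init", call. = FALSE)

  draws <- array(NA_real_, c(n_chains, n_iter, n_par),
    dimnames = list(NULL, NULL, par_names)
  )
  lp_draws <- matrix(NA_real_, n_chains, n_iter)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    theta <- as.numeric(init)
    lp <- log_posterior(theta)
    ls <- rep(log(step_init), n_par)
    for (it in seq_len(n_iter)) {
      for (j in seq_len(n_par)) {
        prop <- theta
        prop[j] <- theta[j] + exp(ls[j]) * stats::rnorm(1)
        lp_prop <- log_posterior(prop)
        if (!is.finite(lp_prop) && is.nan(lp_prop)) {
          stop(sprintf("log posterior returned NaN at parameter %s", par_names[j]), call. = FALSE)
        }
        alpha <- min(1, exp(lp_prop - lp))
        if (stats::runif(1) < alpha) {
          theta <- prop
          lp <- lp_prop
        }
        if (it <= warmup) {
          ls[j] <- ls[j] + min(0.25, 1 / sqrt(it)) * (alpha - 0.44)
        }
      }
      draws[ch, it, ] <- theta
      lp_draws[ch, it] <- lp
    }
  }
  posterior_samples(draws, warmup = warmup, seed = seed, lp = lp_draws)
}

#' Posterior draws container
#'
#' Draws are indexed (chain, iteration, parameter); the warmup portion is
#' retained but excluded from [as.matrix()] and all summaries.
#'
#' @param draws numeric array, dim (chains, iterations, parameters), with
#'   parameter dimnames.
#' @param warmup number of leading warmup iterations per chain.
#' @param seed seed the run used.
#' @param lp optional (chains x iterations) log-posterior trace.
#' @return object of class `"posterior_samples"`.
#' @export
posterior_samples <- function(draws, warmup, seed = NA_integer_, lp = NULL) {
  stopifnot(length(dim(draws)) == 3, warmup < dim(draws)[2])
  structure(
    list(
      draws = draws, parameters = dimnames(draws)[[3]],
      n_chains = dim(draws)[1], n_iter = dim(draws)[2],
      warmup = as.integer(warmup), seed = seed, lp = lp
    ),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(
    "Posterior samples: %d chains x %d iterations (%d warmup), %d parameters\n",
    x$n_chains, x$n_iter, x$warmup, length(x$parameters)
  ))
  invisible(x)
}

#' @describeIn posterior_samples post-warmup draws as a (draws x parameters)
#'   matrix, chains stacked.
#' @param x a `posterior_samples` object.
#' @param ... unused.
#' @export
as.matrix.posterior_samples <- function(x, ...) {
  keep <- (x$warmup + 1L):x$n_iter
  np <- length(x$parameters)
  out <- do.call(rbind, lapply(seq_len(x$n_chains), function(ch) {
    matrix(x$draws[ch, keep, ], ncol = np)
  }))
  colnames(out) <- x$parameters
  out
}

#' @export
summary.posterior_samples <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  m <- as.matrix(object)
  q <- t(apply(m, 2, stats::quantile, probs = probs))
  data.frame(
    parameter = object$parameters,
    mean = colMeans(m), sd = apply(m, 2, stats::sd), q,
    check.names = FALSE, row.names = NULL
  )
}
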