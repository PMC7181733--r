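test_that("the sampler recovers the conjugate Normal-mean posterior", {
  # y in {1, 2, 3}, sigma = 1 known, mu ~ N(0, 10):
  # posterior mean = 6 / (3 + 1/100), sd = 1 / sqrt(3.01)
  lp <- function(th) {
    sum(dnorm(c(1, 2, 3), th, 1, log = TRUE)) + dnorm(th, 0, 10, log = TRUE)
  }
  s <- sample_posterior(lp, c(mu = 0), n_iter = 4000, warmup = 1000, n_chains = 3, seed = 7)
  m <- as.matrix(s)
  d <- diagnostics(s)
  mcse <- sd(m) / sqrt(d$ess)
  expect_lt(abs(mean(m) - 6 / 3.01), 3 * mcse)
  expect_lt(abs(sd(m) - 1 / sqrt(3.01)), 0.02)
  expect_true(attr(d, "pass"))
})

test_that("the sampler recovers the conjugate Gamma-rate posterior", {
  # y ~ Gamma(shape 3, rate r), r ~ Gamma(2, 1):
  # posterior r ~ Gamma(2 + 3n, 1 + sum(y))
  set.seed(2)
  y <- rgamma(20, shape = 3, rate = 0.5)
  a_post <- 2 + 3 * length(y)
  b_post <- 1 + sum(y)
  lp <- function(r) {
    if (r <= 0) return(-Inf)
    sum(dgamma(y, shape = 3, rate = r, log = TRUE)) + dgamma(r, 2, 1, log = TRUE)
  }
  s <- sample_posterior(lp, c(rate = 0.5), n_iter = 4000, warmup = 1000, n_chains = 3, seed = 5)
  m <- as.matrix(s)
  d <- diagnostics(s)
  mcse <- sd(m) / sqrt(d$ess)
  expect_lt(abs(mean(m) - a_post / b_post), 3 * mcse)
  expect_true(attr(d, "pass"))
})

test_that("same seed gives identical draws, different seeds differ", {
  lp <- function(th) dnorm(th, 2, 1, log = TRUE)
  a <- sample_posterior(lp, 0, n_iter = 500, warmup = 100, n_chains = 2, seed = 3)
  b <- sample_posterior(lp, 0, n_iter = 500, warmup = 100, n_chains = 2, seed = 3)
  expect_identical(a$draws, b$draws)
  c_ <- sample_posterior(lp, 0, n_iter = 500, warmup = 100, n_chains = 2, seed = 4)
  expect_false(identical(a$draws, c_$draws))
})

test_that("a non-finite log posterior at the start is an error", {
  expect_error(
    sample_posterior(function(th) -Inf, 0, n_iter = 100, warmup = 10),
    "not finite"
  )
})

test_that("split R-hat is near 1 for iid chains and large for separated chains", {
  set.seed(9)
  iid <- array(rnorm(4 * 1000), c(4, 1000, 1), dimnames = list(NULL, NULL, "x"))
  d <- diagnostics(posterior_samples(iid, warmup = 0))
  expect_lt(abs(d$rhat - 1), 0.01)
  # chains centred at 0 and 10
  sep <- array(rbind(rnorm(500, 0, 1), rnorm(500, 10, 1)), c(2, 500, 1))
  dimnames(sep) <- list(NULL, NULL, "x")
  d2 <- diagnostics(posterior_samples(sep, warmup = 0))
  expect_gt(d2$rhat, 2)
  expect_false(attr(d2, "pass"))
})

test_that("ESS of iid draws approaches the draw count", {
  set.seed(10)
  iid <- array(rnorm(3 * 2000), c(3, 2000, 1), dimnames = list(NULL, NULL, "x"))
  d <- diagnostics(posterior_samples(iid, warmup = 0))
  expect_gt(d$ess, 0.75 * 6000)
  expect_lte(d$ess, 6000)
})

test_that("diagnostics require at least two chains", {
  one <- array(rnorm(300), c(1, 300, 1), dimnames = list(NULL, NULL, "x"))
  expect_error(diagnostics(posterior_samples(one, warmup = 0)), "2 chains")
})

test_that("the compiled engine matches the generic R sampler on a small model", {
  # same posterior sampled by two independently coded routes
  set.seed(14)
  d <- data.frame(
    reef_id = rep(c("A", "B", "C", "D"), each = 4),
    year = rep(c(2005, 2008, 2011, 2014), 4),
    year_c = rep(c(-4.5, -1.5, 1.5, 4.5), 4),
    habitat = rep(c(0, 1, 0, 1), each = 4),
    management = rep(c(0, 0, 1, 1), each = 4),
    y = rnorm(16, rep(c(0, -2, 3, 1), each = 4), 1),
    pre_level = 10
  )
  m <- hier_model(d, "recovery")
  m$y_scale <- 1 # both routes must target the identical (unstandardised) posterior
  cpp <- fit_hier_model(m, n_iter = 6000, warmup = 1500, n_chains = 2, seed = 4)
  lp <- function(th) log_posterior(m, params = th)
  gen <- sample_posterior(lp, m$init, n_iter = 10000, warmup = 2000, n_chains = 2, seed = 9)
  d_cpp <- diagnostics(cpp)
  d_gen <- diagnostics(gen)
  for (p in c("(Intercept)", "year_c", "management_protected", "log_sigma")) {
    a <- as.matrix(cpp)[, p]
    b <- as.matrix(gen)[, p]
    mcse2 <- sd(a)^2 / d_cpp$ess[d_cpp$parameter == p] +
      sd(b)^2 / d_gen$ess[d_gen$parameter == p]
    expect_lt(abs(mean(a) - mean(b)), 4 * sqrt(mcse2) + 0.02, label = p)
  }
})

test_that("fit_hier_model runs are reproducible under a fixed seed", {
  d <- simulate_recovery_data(beta = c(50, -40, 20, 30, -15, -10), seed = 2)
  m <- hier_model(d, "recovery")
  a <- fit_hier_model(m, n_iter = 400, warmup = 100, n_chains = 2, seed = 11)
  b <- fit_hier_model(m, n_iter = 400, warmup = 100, n_chains = 2, seed = 11)
  expect_identical(a$draws, b$draws)
})
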