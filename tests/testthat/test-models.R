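make_summaries_sites <- function(seed = 3) {
  sim <- simulate_survey_data(seed = seed)
  s <- summarize_reef_years(sim$data)
  list(summaries = s, sites = sim$design)
}

test_that("recovery design centres years and differences against the 1994 baseline", {
  ss <- make_summaries_sites()
  d <- build_recovery_design(ss$summaries, ss$sites, "biomass")
  expect_setequal(unique(d$year_c), c(-4.5, -1.5, 1.5, 4.5))
  expect_equal(nrow(d), 21 * 4)
  # independent construction for one reef-year
  r <- d[d$reef_id == "RF03" & d$year == 2008, ]
  s <- ss$summaries
  expect_equal(
    r$y,
    s$total_biomass[s$reef_id == "RF03" & s$year == 2008] -
      s$total_biomass[s$reef_id == "RF03" & s$year == 1994]
  )
  expect_equal(r$pre_level, s$total_biomass[s$reef_id == "RF03" & s$year == 1994])
  expect_equal(r$habitat, as.integer(ss$sites$regime[3] == "regime_shifted"))
  # post value equal to the baseline gives y = 0
  s2 <- ss$summaries
  s2$total_biomass[s2$reef_id == "RF01" & s2$year == 2005] <-
    s2$total_biomass[s2$reef_id == "RF01" & s2$year == 1994]
  d2 <- build_recovery_design(s2, ss$sites, "biomass")
  expect_equal(d2$y[d2$reef_id == "RF01" & d2$year == 2005], 0)
})

test_that("a missing 1994 baseline is an error naming the reef", {
  ss <- make_summaries_sites()
  s <- ss$summaries[!(ss$summaries$reef_id == "RF05" & ss$summaries$year == 1994), ]
  expect_error(build_recovery_design(s, ss$sites), "RF05")
})

test_that("trophic designs carry positive FG biomass with the right covariates", {
  ss <- make_summaries_sites()
  pre <- build_trophic_design(ss$summaries, ss$sites, "pre")
  expect_equal(nrow(pre), 21 * 2)
  expect_true(all(pre$y > 0))
  expect_setequal(unique(pre$fg), c("carnivore", "herbivore"))
  post <- build_trophic_design(ss$summaries, ss$sites, "post")
  expect_equal(nrow(post), 21 * 4 * 2)
  expect_setequal(unique(post$year_c), c(-4.5, -1.5, 1.5, 4.5))
  # y columns agree with the summary table
  i <- which(post$reef_id == "RF02" & post$year == 2011 & post$fg == "herbivore")
  expect_equal(
    post$y[i],
    ss$summaries$herbivore_biomass[
      ss$summaries$reef_id == "RF02" & ss$summaries$year == 2011
    ]
  )
})

test_that("log posterior with zero observations is the log prior alone", {
  ss <- make_summaries_sites()
  d <- build_recovery_design(ss$summaries, ss$sites)[0, ]
  m <- hier_model(d, "recovery")
  expect_equal(length(m$group_levels), 0)
  theta <- setNames(rep(0.3, m$n_par), m$par_names)
  # by hand: 6 fixed-coefficient priors + half-Cauchy(0,2) on sigma + Jacobian
  by_hand <- sum(dnorm(rep(0.3, 6), 0, 10, log = TRUE)) +
    log(2 / (pi * 2 * (1 + (exp(0.3) / 2)^2))) + 0.3
  expect_equal(log_posterior(m, params = theta), by_hand, tolerance = 1e-12)
})

test_that("log posterior equals a term-by-term hand summation on a 5-observation toy", {
  d <- data.frame(
    reef_id = c("A", "A", "B", "B", "C"),
    year = c(2005, 2008, 2005, 2008, 2005),
    year_c = c(-1.5, 1.5, -1.5, 1.5, -1.5),
    habitat = c(0, 0, 1, 1, 0),
    management = c(1, 1, 0, 0, 1),
    y = c(10, 20, -5, 0, 12),
    pre_level = 100
  )
  m <- hier_model(d, "recovery")
  set.seed(42)
  theta <- setNames(rnorm(m$n_par, 0, 0.7), m$par_names)

  beta <- theta[1:6]
  u <- theta[paste0("u[", c("A", "B", "C"), "]")]
  v <- theta[paste0("v[", c("A", "B", "C"), "]")]
  tau_u <- exp(theta[["log_tau_u"]])
  tau_v <- exp(theta[["log_tau_v"]])
  sigma <- exp(theta[["log_sigma"]])
  r <- match(d$reef_id, c("A", "B", "C"))
  mu <- beta[1] + beta[2] * d$habitat + beta[3] * d$year_c + beta[4] * d$management +
    beta[5] * d$habitat * d$year_c + beta[6] * d$management * d$year_c +
    u[r] + v[r] * d$year_c
  hc <- function(x) log(2 / (pi * 2 * (1 + (x / 2)^2)))
  by_hand <- sum(dnorm(d$y, mu, sigma, log = TRUE)) +
    sum(dnorm(beta, 0, 10, log = TRUE)) +
    sum(dnorm(u, 0, tau_u, log = TRUE)) + sum(dnorm(v, 0, tau_v, log = TRUE)) +
    hc(tau_u) + log(tau_u) + hc(tau_v) + log(tau_v) +
    hc(sigma) + log(sigma)
  expect_equal(log_posterior(m, params = theta), by_hand, tolerance = 1e-8)

  # additivity: a single observation adds exactly one log-density term
  # on top of the prior (all parameters at zero, scales at one)
  m1 <- hier_model(d[1, ], "recovery")
  th1 <- setNames(numeric(m1$n_par), m1$par_names)
  prior_only <- sum(dnorm(numeric(6), 0, 10, log = TRUE)) +
    dnorm(0, 0, 1, log = TRUE) + dnorm(0, 0, 1, log = TRUE) + # u[A], v[A]
    3 * (hc(1) + log(1)) # tau_u, tau_v, sigma
  expect_equal(
    log_posterior(m1, params = th1),
    prior_only + dnorm(d$y[1], 0, 1, log = TRUE),
    tolerance = 1e-10
  )
})

test_that("gamma-model log posterior matches hand summation with the log link", {
  ss <- make_summaries_sites()
  d <- build_trophic_design(ss$summaries, ss$sites, "pre")[c(1, 2, 22, 23, 40), ]
  m <- hier_model(d, "trophic_pre")
  set.seed(9)
  theta <- setNames(rnorm(m$n_par, 0, 0.5), m$par_names)
  theta[grep("Intercept", m$par_names)] <- 5

  p <- ncol(m$X)
  beta <- theta[1:p]
  u <- theta[grep("^u\\[", m$par_names)]
  tau_u <- exp(theta[["log_tau_u"]])
  k <- exp(theta[["log_k"]])
  eta <- as.numeric(m$X %*% beta) + u[m$g1]
  hc <- function(x) log(2 / (pi * 2 * (1 + (x / 2)^2)))
  by_hand <- sum(dgamma(d$y, shape = k, rate = k / exp(eta), log = TRUE)) +
    sum(dnorm(beta, 0, 10, log = TRUE)) + sum(dnorm(u, 0, tau_u, log = TRUE)) +
    hc(tau_u) + log(tau_u) + dexp(k, 1, log = TRUE) + log(k)
  expect_equal(log_posterior(m, params = theta), by_hand, tolerance = 1e-8)
})

test_that("the compiled log posterior agrees with the R reference to 1e-10", {
  ss <- make_summaries_sites()
  set.seed(31)
  for (structure in c("recovery", "trophic_pre", "trophic_post")) {
    d <- if (structure == "recovery") {
      build_recovery_design(ss$summaries, ss$sites)
    } else {
      build_trophic_design(ss$summaries, ss$sites,
        if (structure == "trophic_pre") "pre" else "post"
      )
    }
    m <- hier_model(d, structure)
    for (i in 1:5) {
      theta <- m$init + rnorm(m$n_par, 0, 0.2)
      lp_r <- log_posterior(m, params = setNames(theta, m$par_names))
      lp_cpp <- reefmpa:::.lp_hier_cpp(reefmpa:::hier_data_list(m), theta)
      expect_equal(lp_cpp, lp_r, tolerance = 1e-10, label = structure)
    }
  }
})

test_that("parameter dimension mismatches are errors", {
  ss <- make_summaries_sites()
  d <- build_recovery_design(ss$summaries, ss$sites)
  m <- hier_model(d, "recovery")
  expect_error(log_posterior(m, params = numeric(3)))
})
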