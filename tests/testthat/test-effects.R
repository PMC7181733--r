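test_that("contrast estimators match direct arithmetic", {
  expect_equal(mean_difference(c(10, 20), c(10, 10, 10)), 5)
  expect_equal(mean_difference(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(response_ratio_pct(c(17, 18), c(10, 10)), 75)
  expect_equal(response_ratio_pct(c(7, 7), c(7, 7)), 0)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(9, 10, 500)
    f <- runif(12, 10, 500)
    expect_equal(mean_difference(p, f), mean(p) - mean(f), tolerance = 1e-12)
    expect_equal(
      exp(log_response_ratio(p, f)) - 1,
      response_ratio_pct(p, f) / 100,
      tolerance = 1e-12
    )
  }
  expect_error(mean_difference(numeric(0), 1), "non-empty")
  expect_error(response_ratio_pct(c(1, 2), c(0, 0)), "> 0")
})

test_that("jackknife enumerates the documented leave-one-out set", {
  lv <- labelled_values(c(10, 20), c(10, 10, 10))
  jk <- jackknife_bounds(lv$values, lv$management, "mean_difference")
  expect_equal(jk$estimate, 5)
  expect_equal(sort(unname(jk$loo)), sort(c(10, 0, 5, 5, 5)))
  expect_equal(jk$jackknife_min, 0)
  expect_equal(jk$jackknife_max, 10)
  expect_equal(jk$n_protected + jk$n_fished, length(jk$loo))
})

test_that("jackknife equals exhaustive leave-one-out enumeration on random 21-site tables", {
  set.seed(11)
  for (rep in 1:10) {
    values <- rlnorm(21, log(200), 0.6)
    management <- sample(rep(c("protected", "fished"), c(9, 12)))
    for (est in c("mean_difference", "response_ratio_pct")) {
      jk <- jackknife_bounds(values, management, est)
      oracle <- sapply(1:21, function(i) {
        p <- values[-i][management[-i] == "protected"]
        f <- values[-i][management[-i] == "fished"]
        if (est == "mean_difference") mean(p) - mean(f) else (mean(p) / mean(f) - 1) * 100
      })
      expect_equal(unname(jk$loo), oracle, tolerance = 1e-12)
      expect_equal(jk$jackknife_min, min(oracle))
      expect_equal(jk$jackknife_max, max(oracle))
      expect_length(jk$loo, 21)
      # the full-sample mean difference always lies inside the bounds
      if (est == "mean_difference") {
        expect_gte(jk$estimate, jk$jackknife_min)
        expect_lte(jk$estimate, jk$jackknife_max)
      }
    }
  }
})

test_that("degenerate and invalid jackknife inputs behave", {
  lv <- labelled_values(rep(4, 3), rep(4, 4))
  jk <- jackknife_bounds(lv$values, lv$management)
  expect_equal(jk$jackknife_min, jk$estimate)
  expect_equal(jk$jackknife_max, jk$estimate)
  expect_error(
    jackknife_bounds(c(1, 2, 3), c("protected", "fished", "fished")),
    ">= 2 sites"
  )
})

test_that("estimators are invariant to site ordering", {
  set.seed(4)
  values <- rlnorm(21, log(100), 0.5)
  management <- rep(c("protected", "fished"), c(9, 12))
  jk <- jackknife_bounds(values, management)
  ord <- sample(21)
  jk2 <- jackknife_bounds(values[ord], management[ord])
  expect_equal(jk2$estimate, jk$estimate)
  expect_equal(jk2$jackknife_min, jk$jackknife_min)
  expect_equal(jk2$jackknife_max, jk$jackknife_max)
  expect_equal(jk2$jackknife_se, jk$jackknife_se)
})

test_that("trophic-group mean differences sum to the total mean difference", {
  sim <- simulate_survey_data(seed = 21, years = 1994)
  s <- summarize_reef_years(sim$data)
  sites <- sim$design
  tot <- effects_by_group(s, sites, grouping = "total")
  grp <- effects_by_group(s, sites, grouping = "trophic_group")
  expect_equal(sum(grp$estimate), tot$estimate, tolerance = 1e-9)
  ch <- effects_by_group(s, sites, grouping = "carnivore_herbivore")
  expect_equal(nrow(ch), 2)
})

test_that("post-disturbance effects stratify by regime with correct group sizes", {
  sim <- simulate_survey_data(seed = 13, years = c(1994, 2008))
  s <- summarize_reef_years(sim$data)
  eff <- effects_by_group(s, sim$design, grouping = "total")
  expect_equal(eff$stratum[eff$year == 1994], "all")
  post <- eff[eff$year == 2008, ]
  expect_setequal(post$stratum, c("recovering", "regime_shifted"))
  expect_equal(post$n_protected[post$stratum == "recovering"], 5)
  expect_equal(post$n_fished[post$stratum == "recovering"], 7)
  expect_equal(post$n_protected[post$stratum == "regime_shifted"], 4)
  expect_equal(post$n_fished[post$stratum == "regime_shifted"], 5)
})

test_that("a generated 1.75x reserve world shows a ~75% response ratio", {
  # single-seed check with generous sampling slack; the multi-seed
  # calibration lives in the acceptance suite
  sim <- simulate_survey_data(seed = 1, years = 1994)
  s <- summarize_reef_years(sim$data)
  eff <- effects_by_group(s, sim$design,
    grouping = "total", estimator = "response_ratio_pct"
  )
  expect_gt(eff$estimate, 25)
  expect_lt(eff$estimate, 125)
})

test_that("null and strong-effect worlds differ in how often the range spans zero", {
  # the min/max drop-one band is a site-influence range, not a calibrated
  # interval: under a null it spans zero well above chance-at-strong-effect
  # levels but far below 1; under a strong effect it should essentially
  # never span zero
  set.seed(8)
  spans <- function(mult) {
    mean(replicate(40, {
      v <- c(rlnorm(9, log(100 * mult), 0.4), rlnorm(12, log(100), 0.4))
      m <- rep(c("protected", "fished"), c(9, 12))
      jk <- jackknife_bounds(v, m)
      jk$jackknife_min < 0 && jk$jackknife_max > 0
    }))
  }
  expect_gt(spans(1), 0.15)
  expect_lt(spans(2.5), 0.05)
})
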