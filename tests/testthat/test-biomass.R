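test_that("length-weight mass follows the power law", {
  expect_equal(length_weight_mass(10, 0.01, 3), 10)
  # L = 1 returns the coefficient for any exponent
  for (b in c(2.5, 3, 3.4)) expect_equal(length_weight_mass(1, 0.037, b), 0.037)
  # independent power-law evaluation: a * exp(b * log(L))
  set.seed(1)
  for (i in 1:20) {
    L <- runif(1, 1, 80)
    a <- runif(1, 0.005, 0.05)
    b <- runif(1, 2.8, 3.2)
    expect_equal(length_weight_mass(L, a, b), a * exp(b * log(L)), tolerance = 1e-12)
  }
  expect_error(length_weight_mass(-1, 0.01, 3), "length_cm")
  expect_error(length_weight_mass(10, 0, 3), "lw_a")
})

test_that("mass is strictly increasing in length", {
  L <- seq(1, 100, by = 0.5)
  m <- length_weight_mass(L, 0.0137, 3.04)
  expect_true(all(diff(m) > 0))
})

test_that("areal conversion: 1 g m^-2 in one count equals 10 kg ha^-1", {
  traits <- data.frame(
    species_id = "s", family = "f", trophic_group = "grazer",
    # one fish weighing exactly pi * 49 g (the 7 m count area in m^2)
    lw_a = pi * 49, lw_b = 3, stringsAsFactors = FALSE
  )
  fish <- data.frame(
    reef_id = "R", year = 1994, replicate = 1L, species_id = "s",
    count = 1L, length_cm = 1, stringsAsFactors = FALSE
  )
  b <- replicate_biomass(fish, traits)
  expect_equal(unname(b["total"]), 10)
  expect_equal(unname(b["grazer"]), 10)
})

test_that("empty replicates give zero biomass everywhere and zero richness", {
  x <- tiny_survey()
  empty <- x$fish[0, ]
  b <- replicate_biomass(empty, x$traits)
  expect_equal(unname(b), rep(0, 8))
  expect_equal(replicate_richness(empty), 0L)
})

test_that("replicate biomass is linear: doubling counts doubles all outputs", {
  x <- tiny_survey()
  fish <- x$fish[x$fish$replicate == 1 & x$fish$reef_id == "R1", ]
  b1 <- replicate_biomass(fish, x$traits)
  fish2 <- fish
  fish2$count <- fish2$count * 2L
  expect_equal(replicate_biomass(fish2, x$traits), 2 * b1)
})

test_that("richness counts distinct species", {
  f <- data.frame(
    species_id = c("A", "B", "A"), count = c(2L, 1L, 3L)
  )
  expect_equal(replicate_richness(f), 2L)
  many <- data.frame(
    species_id = sprintf("sp%03d", 1:134), count = 1L
  )
  expect_equal(replicate_richness(many), 134L)
})

test_that("group biomasses partition the total and carnivore/herbivore sums hold", {
  sim <- simulate_survey_data(seed = 7, years = c(1994, 2008))
  s <- summarize_reef_years(sim$data)
  grp <- as.matrix(s[, paste0("biomass_", trophic_groups)])
  expect_equal(rowSums(grp), s$total_biomass, tolerance = 1e-9)
  expect_equal(
    s$carnivore_biomass,
    rowSums(s[, paste0("biomass_", carnivore_groups)]),
    tolerance = 1e-12
  )
  expect_equal(
    s$herbivore_biomass,
    rowSums(s[, paste0("biomass_", herbivore_groups)]),
    tolerance = 1e-12
  )
  expect_true(all(grp >= 0))
})

test_that("reef-year summaries equal a brute-force per-replicate aggregation", {
  x <- tiny_survey()
  s <- summarize_reef_years(x)
  # independent oracle: replicate-level biomass via replicate_biomass, then mean
  for (reef in c("R1", "R2")) {
    reps <- sort(unique(x$benthic$replicate[x$benthic$reef_id == reef]))
    totals <- sapply(reps, function(r) {
      f <- x$fish[x$fish$reef_id == reef & x$fish$replicate == r, ]
      unname(replicate_biomass(f, x$traits)["total"])
    })
    expect_equal(
      s$total_biomass[s$reef_id == reef], mean(totals),
      tolerance = 1e-12, label = reef
    )
  }
  # simple means: benthic (40, 60) -> 50; two replicate totals average
  expect_equal(s$hard_coral[s$reef_id == "R1"], 50)
  expect_equal(s$richness[s$reef_id == "R1"], mean(c(2, 1)))
})

test_that("summaries are invariant to row order and record splitting", {
  x <- tiny_survey()
  s0 <- summarize_reef_years(x)

  perm <- x
  set.seed(3)
  perm$fish <- perm$fish[sample(nrow(perm$fish)), ]
  perm$benthic <- perm$benthic[sample(nrow(perm$benthic)), ]
  expect_equal(summarize_reef_years(perm), s0)

  # split (spA, count 2) into two count-1 records
  split <- x
  i <- which(split$fish$count == 2L)[1]
  row <- split$fish[i, ]
  row$count <- 1L
  split$fish$count[i] <- 1L
  split$fish <- rbind(split$fish, row)
  expect_equal(summarize_reef_years(split), s0)
})

test_that("fish recorded outside the benthic replicate registry are rejected", {
  x <- tiny_survey()
  x$benthic <- x$benthic[x$benthic$reef_id != "R2", ]
  expect_error(summarize_reef_years(x), "registry")
})
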