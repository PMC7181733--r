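# Small in-code fixtures shared across test files.

# two reefs (one protected, one fished), one year, two replicates each,
# three species with simple length-weight coefficients
tiny_survey <- function() {
  sites <- data.frame(
    reef_id = c("R1", "R2"),
    management = c("protected", "fished"),
    stringsAsFactors = FALSE
  )
  traits <- data.frame(
    species_id = c("spA", "spB", "spC"),
    family = c("f1", "f1", "f2"),
    trophic_group = c("piscivore", "grazer", "planktivore"),
    lw_a = c(0.01, 0.02, 0.01),
    lw_b = c(3, 3, 3),
    stringsAsFactors = FALSE
  )
  fish <- data.frame(
    reef_id = c("R1", "R1", "R1", "R2"),
    year = 1994,
    replicate = c(1L, 1L, 2L, 1L),
    species_id = c("spA", "spB", "spA", "spC"),
    count = c(2L, 1L, 3L, 5L),
    length_cm = c(30, 20, 25, 10),
    stringsAsFactors = FALSE
  )
  benthic <- data.frame(
    reef_id = rep(c("R1", "R2"), each = 2),
    year = 1994,
    replicate = c(1L, 2L, 1L, 2L),
    hard_coral = c(40, 60, 20, 30),
    soft_coral = 5,
    macroalgae = c(2, 1, 30, 25),
    sand = 10,
    rubble = 10,
    rock = 10,
    complexity = c(4L, 3L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  survey_data(sites, fish, benthic, traits)
}

# reef-level values with a known protected/fished split
labelled_values <- function(protected, fished) {
  list(
    values = c(protected, fished),
    management = c(
      rep("protected", length(protected)),
      rep("fished", length(fished))
    )
  )
}

# direct simulation from the recovery-model data-generating process
# (21-reef study design, 4 post-disturbance years)
simulate_recovery_data <- function(beta, tau_u = 40, tau_v = 8, sigma = 30,
                                   seed = 1) {
  set.seed(seed)
  design <- generate_design()
  years <- c(2005, 2008, 2011, 2014)
  d <- expand.grid(reef_id = design$reef_id, year = years,
    stringsAsFactors = FALSE
  )
  d <- merge(d, design, by = "reef_id")
  d$year_c <- d$year - mean(years)
  d$habitat <- as.integer(d$regime == "regime_shifted")
  d$management <- as.integer(d$management == "protected")
  u <- rnorm(21, 0, tau_u)
  v <- rnorm(21, 0, tau_v)
  r <- match(d$reef_id, design$reef_id)
  eta <- beta[1] + beta[2] * d$habitat + beta[3] * d$year_c +
    beta[4] * d$management + beta[5] * d$habitat * d$year_c +
    beta[6] * d$management * d$year_c + u[r] + v[r] * d$year_c
  d$y <- rnorm(nrow(d), eta, sigma)
  d$pre_level <- 300
  d[order(d$reef_id, d$year), c(
    "reef_id", "year", "year_c", "habitat", "management", "y", "pre_level"
  )]
}
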