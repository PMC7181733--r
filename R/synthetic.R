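## Synthetic UVC survey generator: the study design (21 reefs, 9 protected /
## 12 fished, 2x2 management x regime layout, survey years 1994-2014, 8-16
## replicate 7 m point counts) with known ground-truth effect sizes, so every
## pipeline stage can be checked against truth.

#' Ground-truth parameters for the synthetic survey generator
#'
#' Defaults reproduce the study conditions: a uniform 1.75 pre-disturbance
#' reserve multiplier on fish biomass (a +75% response ratio), biomass
#' recovery slopes of 7 / 4 / 2 / 0 % year^-1 for fished-recovering /
#' protected-recovering / fished-shifted / protected-shifted strata
#' (percent of the stratum's pre-disturbance level), trophic composition
#' shifting from carnivore-rich pre-disturbance to herbivore-dominated
#' post-disturbance, and benthic cover trajectories that separate recovering
#' (coral regrowth) from regime-shifted (macroalgal takeover) reefs.
#'
#' @param scenario `"paper"` for the study-calibrated defaults, `"null"` for
#'   a no-reserve-effect world (multiplier 1, all slopes and offsets 0, no
#'   protected coral bonus) used for calibration checks.
#' @return a list of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(scenario = c("paper", "null")) {
  scenario <- match.arg(scenario)
  truth <- list(
    scenario = scenario,
    # fished pre-disturbance biomass by trophic group, kg ha^-1
    baseline_biomass = c(
      piscivore = 60, mixed_diet = 85, scraper_excavator = 70, grazer = 55,
      browser = 20, planktivore = 40, corallivore = 10
    ),
    reserve_multiplier = 1.75,
    # percent-of-pre-level trajectory of expected total biomass:
    # f(t) = 1 + (pct2005 + slope * (year - 2005)) / 100, per stratum
    biomass_pct2005 = c(
      recovering_fished = 16, recovering_protected = 16,
      regime_shifted_fished = 20, regime_shifted_protected = 0
    ),
    biomass_slope = c(
      recovering_fished = 7, recovering_protected = 4,
      regime_shifted_fished = 2, regime_shifted_protected = 0
    ),
    # post-disturbance trophic composition (shares of total biomass)
    post_shares = list(
      recovering = c(
        piscivore = 0.08, mixed_diet = 0.27, scraper_excavator = 0.32,
        grazer = 0.15, browser = 0.05, planktivore = 0.10, corallivore = 0.03
      ),
      regime_shifted = c(
        piscivore = 0.06, mixed_diet = 0.22, scraper_excavator = 0.22,
        grazer = 0.18, browser = 0.25, planktivore = 0.05, corallivore = 0.02
      )
    ),
    # benthic means; covers in %, complexity on the 0-5 scale
    pre_coral = 28, pre_coral_bonus = 15, # protected reefs pre-disturbance
    pre_macroalgae = 1.2,
    coral_post = list(recovering = c(8, 35), regime_shifted = c(6, 6)), # 2005 -> 2014
    macroalgae_post = list(recovering = c(3, 3), regime_shifted = c(25, 45)),
    soft_coral = 6, sand = 15, rubble = 12, rock = 18,
    complexity = c(pre = 3.5, recovering = 3.2, regime_shifted = 2.0),
    cover_sd = 6, complexity_sd = 0.6,
    # sampling process
    replicate_range = c(8L, 16L),
    nb_size = 4, # gamma-mixed (negative binomial) count overdispersion
    reef_sd = 0.25, # lognormal reef-quality SD (mean-corrected)
    length_sdlog = 0.15, # individual length spread around species length
    species_length_sdlog = 0.25, # species length spread around group typical
    typical_length = c(
      piscivore = 45, mixed_diet = 30, scraper_excavator = 30, grazer = 22,
      browser = 28, planktivore = 12, corallivore = 14
    )
  )
  if (scenario == "null") {
    truth$reserve_multiplier <- 1
    truth$biomass_pct2005[] <- 0
    truth$biomass_slope[] <- 0
    truth$pre_coral_bonus <- 0
  }
  class(truth) <- "synthetic_truth"
  truth
}

#' Generate a synthetic species trait table
#'
#' 134 species in 16 families by default, every trophic group represented,
#' length-weight coefficients in plausible ranges (a in \[0.005, 0.05\],
#' b in \[2.8, 3.2\]).
#'
#' @param n_species,n_families pool sizes.
#' @param seed integer seed (same seed, identical table).
#' @return a trait data frame matching the `traits.csv` schema.
#' @export
generate_traits <- function(n_species = 134, n_families = 16, seed = 1) {
  stopifnot(n_species >= n_families, n_species >= length(trophic_groups))
  set.seed(seed)
  group_weights <- c(
    piscivore = 0.10, mixed_diet = 0.20, scraper_excavator = 0.15,
    grazer = 0.15, browser = 0.08, planktivore = 0.22, corallivore = 0.10
  )[trophic_groups]
  grp <- c(
    trophic_groups,
    sample(trophic_groups, n_species - length(trophic_groups), TRUE, group_weights)
  )
  fam <- c(
    sprintf("fam%02d", seq_len(n_families)),
    sprintf("fam%02d", sample.int(n_families, n_species - n_families, TRUE))
  )
  data.frame(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    family = fam,
    trophic_group = grp,
    lw_a = round(runif(n_species, 0.005, 0.05), 5),
    lw_b = round(runif(n_species, 2.8, 3.2), 3),
    stringsAsFactors = FALSE
  )
}

#' Generate the reef-site design
#'
#' The study layout: 21 reefs in a 2x2 management x regime design with 7
#' fished-recovering, 5 protected-recovering, 5 fished-shifted and 4
#' protected-shifted sites (9 protected, 12 fished in total). The returned
#' `regime` column is the generating ground truth; blank it to
#' `"unassigned"` before exercising the classifier.
#'
#' @param counts named design counts (fished_recovering, protected_recovering,
#'   fished_shifted, protected_shifted).
#' @return site data frame with ground-truth `regime`.
#' @export
generate_design <- function(counts = c(
                              fished_recovering = 7, protected_recovering = 5,
                              fished_shifted = 5, protected_shifted = 4
                            )) {
  management <- rep(
    c("fished", "protected", "fished", "protected"),
    counts
  )
  regime <- rep(
    c("recovering", "recovering", "regime_shifted", "regime_shifted"),
    counts
  )
  data.frame(
    reef_id = sprintf("RF%02d", seq_along(management)),
    management = management,
    regime = regime,
    stringsAsFactors = FALSE
  )
}

# expected-biomass trajectory factor per stratum and year
trajectory_factor <- function(truth, regime, management, year) {
  if (year <= BLEACHING_YEAR) return(1)
  cell <- paste(regime, management, sep = "_")
  f <- 1 + (truth$biomass_pct2005[[cell]] + truth$biomass_slope[[cell]] * (year - 2005)) / 100
  if (f <= 0) {
    stop(sprintf("infeasible parameters: expected biomass <= 0 in %s, %d", cell, year), call. = FALSE)
  }
  f
}

benthic_means <- function(truth, regime, management, year) {
  if (year <= BLEACHING_YEAR) {
    coral <- truth$pre_coral + if (management == "protected") truth$pre_coral_bonus else 0
    ma <- truth$pre_macroalgae
    cx <- truth$complexity[["pre"]]
  } else {
    w <- (year - 2005) / 9
    cr <- truth$coral_post[[regime]]
    mr <- truth$macroalgae_post[[regime]]
    coral <- cr[1] + (cr[2] - cr[1]) * w
    ma <- mr[1] + (mr[2] - mr[1]) * w
    cx <- truth$complexity[[regime]]
  }
  list(
    cover = c(
      hard_coral = coral, soft_coral = truth$soft_coral, macroalgae = ma,
      sand = truth$sand, rubble = truth$rubble, rock = truth$rock
    ),
    complexity = cx
  )
}

# g per point count per kg ha^-1 of areal density
g_per_count_per_kgha <- function() area_m2(POINT_COUNT_RADIUS_M) / G_M2_TO_KG_HA

#' Generate full synthetic survey tables
#'
#' Draws fish counts from a gamma-mixed (negative binomial) process whose
#' expected reef-year biomass follows the ground truth exactly: baseline
#' trophic composition times the reserve multiplier pre-disturbance, and
#' stratum-specific linear percent-of-pre trajectories post-disturbance,
#' modulated by mean-corrected lognormal reef quality. Individual lengths
#' are lognormal around species-typical sizes (group-typical length with
#' per-species spread) and recorded to the nearest cm; expected masses use
#' the exact lognormal moment so biomass is unbiased. Benthic cover follows
#' the regime trajectories with replicate-level noise. All outputs pass
#' [validate_survey_data()].
#'
#' @param truth a [synthetic_truth()] list.
#' @param design site design from [generate_design()] (with ground-truth
#'   regime labels).
#' @param traits trait table from [generate_traits()].
#' @param years survey years.
#' @param seed integer seed; identical seeds give identical tables.
#' @return a [survey_data()] object; the site table's `regime` column is
#'   reset to `"unassigned"` so classification can be exercised.
#' @export
generate_surveys <- function(truth, design, traits,
                             years = c(1994, 2005, 2008, 2011, 2014), seed = 1) {
  set.seed(seed)
  S <- nrow(traits)
  grp <- factor(traits$trophic_group, levels = trophic_groups)

  # species-typical lengths and within-group abundance weights
  L_s <- truth$typical_length[traits$trophic_group] *
    exp(rnorm(S, 0, truth$species_length_sdlog))
  L_s <- pmin(pmax(L_s, 4), 120)
  rank_in_group <- stats::ave(seq_len(S), grp, FUN = seq_along)
  w_s <- 0.85^(rank_in_group - 1)
  w_s <- w_s / stats::ave(w_s, grp, FUN = sum)
  # expected mass per recorded individual (lognormal length moment)
  e_mass <- traits$lw_a * L_s^traits$lw_b *
    exp(traits$lw_b^2 * truth$length_sdlog^2 / 2)

  base_shares <- truth$baseline_biomass / sum(truth$baseline_biomass)
  total_base <- sum(truth$baseline_biomass)
  q_reef <- setNames(
    exp(rnorm(nrow(design), 0, truth$reef_sd) - truth$reef_sd^2 / 2),
    design$reef_id
  )

  fish_rows <- list()
  benthic_rows <- list()
  for (r in seq_len(nrow(design))) {
    reef <- design$reef_id[r]
    regime <- design$regime[r]
    mgmt <- design$management[r]
    for (yr in years) {
      n_rep <- sample(truth$replicate_range[1]:truth$replicate_range[2], 1)
      f <- trajectory_factor(truth, regime, mgmt, yr)
      total <- total_base * f * q_reef[[reef]] *
        (if (mgmt == "protected") truth$reserve_multiplier else 1)
      shares <- if (yr <= BLEACHING_YEAR) base_shares else truth$post_shares[[regime]]
      lambda <- total * shares[traits$trophic_group] * g_per_count_per_kgha() *
        w_s / e_mass
      cnt <- matrix(
        rnbinom(n_rep * S, mu = rep(lambda, each = n_rep), size = truth$nb_size),
        n_rep, S
      )
      nz <- which(cnt > 0, arr.ind = TRUE)
      if (nrow(nz) > 0) {
        n_ind <- cnt[nz]
        rep_i <- rep(nz[, 1], n_ind)
        sp_i <- rep(nz[, 2], n_ind)
        len <- pmax(1, round(L_s[sp_i] * exp(rnorm(length(sp_i), 0, truth$length_sdlog))))
        agg <- aggregate(
          list(count = rep(1L, length(sp_i))),
          list(replicate = rep_i, species = sp_i, length_cm = len), sum
        )
        fish_rows[[length(fish_rows) + 1L]] <- data.frame(
          reef_id = reef, year = yr, replicate = agg$replicate,
          species_id = traits$species_id[agg$species],
          count = agg$count, length_cm = agg$length_cm,
          stringsAsFactors = FALSE
        )
      }
      bm <- benthic_means(truth, regime, mgmt, yr)
      cov <- matrix(
        rnorm(n_rep * length(benthic_categories), rep(bm$cover, each = n_rep), truth$cover_sd),
        n_rep,
        dimnames = list(NULL, benthic_categories)
      )
      cov <- pmin(pmax(cov, 0), 100)
      over <- rowSums(cov) > 100
      if (any(over)) cov[over, ] <- cov[over, ] * (100 / rowSums(cov)[over])
      benthic_rows[[length(benthic_rows) + 1L]] <- data.frame(
        reef_id = reef, year = yr, replicate = seq_len(n_rep),
        round(cov, 1),
        complexity = pmin(5L, pmax(0L, as.integer(round(
          rnorm(n_rep, bm$complexity, truth$complexity_sd)
        )))),
        stringsAsFactors = FALSE
      )
    }
  }

  fish <- do.call(rbind, fish_rows)
  fish <- fish[order(fish$reef_id, fish$year, fish$replicate, fish$species_id, fish$length_cm), ]
  rownames(fish) <- NULL
  benthic <- do.call(rbind, benthic_rows)
  rownames(benthic) <- NULL
  sites <- design
  sites$regime <- "unassigned"
  survey_data(sites, fish, benthic, traits)
}

#' One-call synthetic dataset with truth metadata
#'
#' Convenience wrapper: builds the default design and trait pool, generates
#' surveys for the requested scenario, and returns the data together with
#' the generating truth and the true site regimes.
#'
#' @param seed integer seed.
#' @param scenario `"paper"` or `"null"` (see [synthetic_truth()]).
#' @param years survey years.
#' @return list with `data` (a [survey_data()] with unassigned regimes),
#'   `truth`, and `design` (sites with ground-truth regime).
#' @export
simulate_survey_data <- function(seed = 1, scenario = "paper",
                                 years = c(1994, 2005, 2008, 2011, 2014)) {
  truth <- synthetic_truth(scenario)
  design <- generate_design()
  traits <- generate_traits(seed = seed)
  data <- generate_surveys(truth, design, traits, years = years, seed = seed)
  list(data = data, truth = truth, design = design)
}
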