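## Biomass construction: length-weight allometry, areal conversion from
## 7 m-radius point counts, and reef-year aggregation.

#' Length-weight allometry
#'
#' Converts fish total length to body mass with the standard power law
#' \eqn{W = a L^b} (W in grams, L in cm).
#'
#' @param length_cm fish length in cm (> 0).
#' @param lw_a allometric coefficient (g cm^-b, > 0).
#' @param lw_b allometric exponent (dimensionless).
#' @return mass in grams; vectorised over all arguments.
#' @examples
#' length_weight_mass(10, 0.01, 3) # 10 g
#' @export
length_weight_mass <- function(length_cm, lw_a, lw_b) {
  if (any(!(length_cm > 0))) stop("length_cm must be > 0", call. = FALSE)
  if (any(!(lw_a > 0))) stop("lw_a must be > 0", call. = FALSE)
  lw_a * length_cm^lw_b
}

# g per point count -> kg per hectare:
# divide by the count area (pi r^2 m^2) to get g m^-2, then multiply by 10
area_m2 <- function(radius_m) pi * radius_m^2
G_M2_TO_KG_HA <- 10

#' Areal biomass of one replicate point count
#'
#' Sums count x mass over a replicate's fish observations and converts to
#' kg per hectare using the point-count area (default 7 m radius, ~153.9
#' m^2). Returns the total and the per-trophic-group partition.
#'
#' @param fish fish observation rows of a single replicate (may be empty).
#' @param traits species trait table covering all observed species.
#' @param radius_m point count radius in metres.
#' @return named numeric vector: `total` followed by one element per trophic
#'   group (kg ha^-1). Groups always sum to the total.
#' @export
replicate_biomass <- function(fish, traits, radius_m = POINT_COUNT_RADIUS_M) {
  out <- setNames(numeric(length(trophic_groups) + 1L), c("total", trophic_groups))
  if (nrow(fish) == 0) return(out)
  idx <- match(fish$species_id, traits$species_id)
  if (anyNA(idx)) {
    stop(sprintf(
      "species without trait rows: %s",
      paste(unique(fish$species_id[is.na(idx)]), collapse = ", ")
    ), call. = FALSE)
  }
  mass_g <- fish$count * length_weight_mass(fish$length_cm, traits$lw_a[idx], traits$lw_b[idx])
  conv <- G_M2_TO_KG_HA / area_m2(radius_m)
  grp <- factor(traits$trophic_group[idx], levels = trophic_groups)
  by_group <- tapply(mass_g, grp, sum, default = 0) * conv
  out[trophic_groups] <- by_group
  out["total"] <- sum(by_group)
  out
}

#' Species richness of one replicate point count
#'
#' Number of distinct species recorded (count >= 1) in a single point count:
#' the "density of species" per ~154 m^2 replicate.
#'
#' @param fish fish observation rows of a single replicate.
#' @return integer species count.
#' @export
replicate_richness <- function(fish) {
  if (nrow(fish) == 0) return(0L)
  length(unique(fish$species_id[fish$count >= 1]))
}

#' Aggregate surveys to reef-year summaries
#'
#' Computes, for every surveyed (reef, year), the arithmetic mean over
#' replicate point counts of: total fish biomass and its trophic-group
#' partition (kg ha^-1), carnivore (piscivore + mixed diet) and herbivore
#' (grazer + scraper/excavator + browser) biomass, species richness per
#' replicate, benthic cover per category (%), and structural complexity.
#' The replicate registry is taken from the benthic table: point counts with
#' benthic scores but no fish rows contribute zero biomass and richness.
#' Reef-years present in the fish table but with no benthic record are
#' excluded with a warning.
#'
#' @param x a [survey_data()] object.
#' @param radius_m point count radius in metres.
#' @return data frame with one row per surveyed reef-year, columns `reef_id`,
#'   `year`, `n_replicates`, `total_biomass`, `biomass_<group>` for each
#'   trophic group, `carnivore_biomass`, `herbivore_biomass`, `richness`,
#'   one column per benthic category, and `complexity`.
#' @export
summarize_reef_years <- function(x, radius_m = POINT_COUNT_RADIUS_M) {
  validate_survey_data(x)
  benthic <- x$benthic
  fish <- x$fish
  if (nrow(benthic) == 0) stop("no benthic records: replicate registry is empty", call. = FALSE)

  orphan_ry <- setdiff(
    unique(paste(fish$reef_id, fish$year)),
    unique(paste(benthic$reef_id, benthic$year))
  )
  if (length(orphan_ry)) {
    warning(sprintf(
      "reef-years with fish but zero registered replicates excluded: %s",
      paste(orphan_ry, collapse = "; ")
    ), call. = FALSE)
  }

  rep_key <- paste(benthic$reef_id, benthic$year, benthic$replicate, sep = "\r")
  stopifnot(!anyDuplicated(rep_key))
  fish_rep <- match(paste(fish$reef_id, fish$year, fish$replicate, sep = "\r"), rep_key)

  n_rep <- length(rep_key)
  idx <- match(fish$species_id, x$traits$species_id)
  conv <- G_M2_TO_KG_HA / area_m2(radius_m)
  mass_g <- fish$count * length_weight_mass(fish$length_cm, x$traits$lw_a[idx], x$traits$lw_b[idx])
  grp <- factor(x$traits$trophic_group[idx], levels = trophic_groups)

  rep_f <- factor(fish_rep, levels = seq_len(n_rep))
  bm <- matrix(0, n_rep, length(trophic_groups), dimnames = list(NULL, trophic_groups))
  for (g in trophic_groups) {
    sel <- grp == g
    bm[, g] <- tapply(mass_g[sel] * conv, rep_f[sel], sum, default = 0)
  }
  bm[is.na(bm)] <- 0
  rich <- tapply(fish$species_id, rep_f, function(s) length(unique(s)), default = 0L)
  rich[is.na(rich)] <- 0L

  ry <- factor(paste(benthic$reef_id, benthic$year, sep = "\r"))
  agg <- function(v) as.numeric(tapply(v, ry, mean))
  out <- data.frame(
    reef_id = sub("\r.*", "", levels(ry)),
    year = as.numeric(sub(".*\r", "", levels(ry))),
    n_replicates = as.integer(tapply(rep_key, ry, length)),
    total_biomass = agg(rowSums(bm)),
    stringsAsFactors = FALSE
  )
  for (g in trophic_groups) out[[paste0("biomass_", g)]] <- agg(bm[, g])
  out$carnivore_biomass <- rowSums(out[paste0("biomass_", carnivore_groups)])
  out$herbivore_biomass <- rowSums(out[paste0("biomass_", herbivore_groups)])
  out$richness <- agg(rich)
  for (b in benthic_categories) out[[b]] <- agg(benthic[[b]])
  out$complexity <- agg(benthic$complexity)
  out <- out[order(out$reef_id, out$year), ]
  rownames(out) <- NULL
  out
}
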