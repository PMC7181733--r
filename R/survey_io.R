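## Survey data model: validated long-format UVC tables and CSV round-trip.
##
## Canonical CSV schemas (UTF-8, "." decimal separator):
##   sites.csv   reef_id, management[, regime]
##   fish.csv    reef_id, year, replicate, species_id, count, length_cm
##   benthic.csv reef_id, year, replicate, hard_coral, soft_coral, macroalgae,
##               sand, rubble, rock, complexity
##   traits.csv  species_id, family, trophic_group, lw_a, lw_b

SITES_COLS <- c("reef_id", "management")
FISH_COLS <- c("reef_id", "year", "replicate", "species_id", "count", "length_cm")
BENTHIC_COLS <- c("reef_id", "year", "replicate", benthic_categories, "complexity")
TRAITS_COLS <- c("species_id", "family", "trophic_group", "lw_a", "lw_b")

# visual cover estimates are coarse: unscored substrate may leave the sum
# below 100, and rounding may push it slightly above; reject sums > 100.5
BENTHIC_SUM_TOL <- 0.5

#' Bundle and validate the four UVC survey tables
#'
#' Constructs a `survey_data` object from site, fish, benthic and trait
#' tables, checking every type invariant (counts at least 1, positive lengths,
#' cover percentages in \[0, 100\] summing to at most 100.5, complexity scores
#' on the 0-5 scale, positive length-weight coefficients with exponents in
#' \[2, 4\], trait coverage for every observed species, and fish replicates
#' registered in the benthic replicate registry). Validation errors name the
#' offending table, rows and values.
#'
#' @param sites data frame with columns `reef_id`, `management`
#'   (`"fished"`/`"protected"`) and optionally `regime` (`"recovering"`,
#'   `"regime_shifted"` or `"unassigned"`; defaults to `"unassigned"`).
#' @param fish data frame of fish observations, one row per (species, length)
#'   with a `count` field: columns `reef_id`, `year`, `replicate`,
#'   `species_id`, `count`, `length_cm`.
#' @param benthic data frame of per-point-count benthic records: cover
#'   percentages for `r toString(benthic_categories)` plus a `complexity`
#'   score.
#' @param traits data frame of per-species length-weight coefficients
#'   (`lw_a`, `lw_b`; grams from length in cm) and `trophic_group`.
#' @return A list of the four validated data frames with class
#'   `"survey_data"`.
#' @export
survey_data <- function(sites, fish, benthic, traits) {
  x <- structure(
    list(
      sites = as.data.frame(sites),
      fish = as.data.frame(fish),
      benthic = as.data.frame(benthic),
      traits = as.data.frame(traits)
    ),
    class = "survey_data"
  )
  if (is.null(x$sites$regime)) x$sites$regime <- "unassigned"
  validate_survey_data(x)
  x
}

#' @export
print.survey_data <- function(x, ...) {
  cat("UVC survey data\n")
  cat(sprintf(
    "  %d reefs (%d protected, %d fished)\n", nrow(x$sites),
    sum(x$sites$management == "protected"),
    sum(x$sites$management == "fished")
  ))
  cat(sprintf(
    "  %d fish observation rows (%d individuals, %d species), years %s\n",
    nrow(x$fish), sum(x$fish$count), length(unique(x$fish$species_id)),
    paste(sort(unique(x$fish$year)), collapse = " ")
  ))
  cat(sprintf(
    "  %d benthic point-count records, %d trait rows\n",
    nrow(x$benthic), nrow(x$traits)
  ))
  invisible(x)
}

stop_rows <- function(table, what, rows) {
  stop(sprintf(
    "%s: %s (row%s %s)", table, what,
    if (length(rows) > 1) "s" else "",
    paste(utils::head(rows, 10L), collapse = ", ")
  ), call. = FALSE)
}

require_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s: missing column%s %s", table,
      if (length(missing) > 1) "s" else "",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
}

#' Validate a survey_data object
#'
#' Checks all table-level and cross-table invariants. Called by
#' [survey_data()] and [read_survey_tables()]; exported so externally built
#' tables can be checked too.
#'
#' @param x a `survey_data` object (or plain list with the four tables).
#' @return `x`, invisibly; errors describe the first violated invariant with
#'   row indices.
#' @export
validate_survey_data <- function(x) {
  sites <- x$sites
  fish <- x$fish
  benthic <- x$benthic
  traits <- x$traits

  require_cols(sites, SITES_COLS, "sites")
  require_cols(fish, FISH_COLS, "fish")
  require_cols(benthic, BENTHIC_COLS, "benthic")
  require_cols(traits, TRAITS_COLS, "traits")

  if (anyDuplicated(sites$reef_id)) {
    stop_rows("sites", "duplicated reef_id", which(duplicated(sites$reef_id)))
  }
  bad <- which(!sites$management %in% c("fished", "protected"))
  if (length(bad)) stop_rows("sites", "management must be 'fished' or 'protected'", bad)
  bad <- which(!sites$regime %in% c("recovering", "regime_shifted", "unassigned"))
  if (length(bad)) stop_rows("sites", "invalid regime label", bad)

  if (nrow(fish) > 0) {
    bad <- which(!(fish$count >= 1) | fish$count != round(fish$count))
    if (length(bad)) stop_rows("fish", "count must be an integer >= 1", bad)
    bad <- which(!(fish$length_cm > 0))
    if (length(bad)) stop_rows("fish", "length_cm must be > 0", bad)
    bad <- which(is.na(fish$length_cm))
    if (length(bad)) stop_rows("fish", "length_cm missing (imputation refused)", bad)
    bad <- which(!fish$reef_id %in% sites$reef_id)
    if (length(bad)) stop_rows("fish", "reef_id not in sites table", bad)
    orphan <- setdiff(unique(fish$species_id), traits$species_id)
    if (length(orphan)) {
      stop(sprintf(
        "fish: species without trait rows: %s",
        paste(orphan, collapse = ", ")
      ), call. = FALSE)
    }
    # benthic records define the replicate registry (every point count is
    # scored for benthos even when no fish were recorded)
    if (nrow(benthic) > 0) {
      reg <- unique(paste(benthic$reef_id, benthic$year, benthic$replicate))
      bad <- which(!paste(fish$reef_id, fish$year, fish$replicate) %in% reg)
      if (length(bad)) {
        stop_rows("fish", "(reef, year, replicate) not in benthic replicate registry", bad)
      }
    }
  }

  if (nrow(benthic) > 0) {
    covers <- as.matrix(benthic[, benthic_categories])
    bad <- which(apply(covers < 0 | covers > 100, 1L, any))
    if (length(bad)) stop_rows("benthic", "cover percentages must be in [0, 100]", bad)
    sums <- rowSums(covers)
    bad <- which(sums > 100 + BENTHIC_SUM_TOL)
    if (length(bad)) {
      stop_rows(
        "benthic",
        sprintf("cover sum exceeds %.1f", 100 + BENTHIC_SUM_TOL), bad
      )
    }
    bad <- which(!benthic$complexity %in% 0:5)
    if (length(bad)) stop_rows("benthic", "complexity must be an integer in 0..5", bad)
    bad <- which(!benthic$reef_id %in% sites$reef_id)
    if (length(bad)) stop_rows("benthic", "reef_id not in sites table", bad)
  }

  if (anyDuplicated(traits$species_id)) {
    stop_rows("traits", "duplicated species_id", which(duplicated(traits$species_id)))
  }
  bad <- which(!(traits$lw_a > 0))
  if (length(bad)) stop_rows("traits", "lw_a must be > 0", bad)
  bad <- which(traits$lw_b < 2 | traits$lw_b > 4)
  if (length(bad)) stop_rows("traits", "lw_b outside sanity bounds [2, 4]", bad)
  bad <- which(!traits$trophic_group %in% trophic_groups)
  if (length(bad)) stop_rows("traits", "unknown trophic_group", bad)

  invisible(x)
}

survey_paths <- function(dir) {
  files <- c(
    sites = "sites.csv", fish = "fish.csv",
    benthic = "benthic.csv", traits = "traits.csv"
  )
  setNames(file.path(dir, files), names(files))
}

read_table <- function(path, cols, table) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", table, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  require_cols(df, cols, table)
  df
}

#' Read the four survey CSV tables from a directory
#'
#' Reads `sites.csv`, `fish.csv`, `benthic.csv` and `traits.csv` from `dir`,
#' checks headers against the documented schemas, validates all invariants
#' and reports row counts.
#'
#' @param dir directory containing the four CSV files.
#' @param quiet suppress the row-count message.
#' @return a validated [survey_data()] object.
#' @export
read_survey_tables <- function(dir, quiet = FALSE) {
  p <- survey_paths(dir)
  sites <- read_table(p[["sites"]], SITES_COLS, "sites")
  fish <- read_table(p[["fish"]], FISH_COLS, "fish")
  benthic <- read_table(p[["benthic"]], BENTHIC_COLS, "benthic")
  traits <- read_table(p[["traits"]], TRAITS_COLS, "traits")
  if (!quiet) {
    message(sprintf(
      "read %d sites, %d fish rows, %d benthic rows, %d trait rows from %s",
      nrow(sites), nrow(fish), nrow(benthic), nrow(traits), dir
    ))
  }
  survey_data(sites, fish, benthic, traits)
}

#' Write survey tables as CSV
#'
#' Writes the four tables in documented column order; files can be read back
#' losslessly with [read_survey_tables()].
#'
#' @param x a `survey_data` object.
#' @param dir output directory (created if absent).
#' @return the four file paths, invisibly.
#' @export
write_survey_tables <- function(x, dir) {
  validate_survey_data(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- survey_paths(dir)
  sites_cols <- c(SITES_COLS, "regime")
  tabs <- list(
    sites = x$sites[, sites_cols], fish = x$fish[, FISH_COLS],
    benthic = x$benthic[, BENTHIC_COLS], traits = x$traits[, TRAITS_COLS]
  )
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], p[[nm]], row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(p)
}
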