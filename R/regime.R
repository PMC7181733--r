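## Regime classification: recovering vs regime-shifted reefs from
## post-disturbance coral and macroalgal cover trajectories.

#' Classify one reef's post-disturbance trajectory
#'
#' A reef is labelled `regime_shifted` when macroalgal cover exceeds hard
#' coral cover in the final post-disturbance survey year AND macroalgae is at
#' least as high as coral in at least half of the post-disturbance years
#' (macroalgal dominance that "remains high or is increasing"); otherwise it
#' is `recovering`. Ties in the final year break toward `recovering`. Only
#' surveys strictly after the 1998 disturbance are consulted: pre-disturbance
#' years passed in are ignored.
#'
#' @param coral per-year hard coral cover (%).
#' @param macroalgae per-year macroalgal cover (%), aligned with `coral`.
#' @param years calendar years aligned with the two series.
#' @return list with `label` (`"recovering"` or `"regime_shifted"`) and
#'   `evidence`, the post-disturbance (year, coral, macroalgae) table used.
#' @export
classify_reef <- function(coral, macroalgae, years) {
  stopifnot(length(coral) == length(years), length(macroalgae) == length(years))
  post <- years > BLEACHING_YEAR
  if (sum(post) < 2) {
    stop(sprintf(
      "need >= 2 post-disturbance survey years to classify (got %d)", sum(post)
    ), call. = FALSE)
  }
  ord <- order(years[post])
  ev <- data.frame(
    year = years[post][ord],
    coral = coral[post][ord],
    macroalgae = macroalgae[post][ord]
  )
  final_dominant <- ev$macroalgae[nrow(ev)] > ev$coral[nrow(ev)]
  persistent <- mean(ev$macroalgae >= ev$coral) >= 0.5
  list(
    label = if (final_dominant && persistent) "regime_shifted" else "recovering",
    evidence = ev
  )
}

#' Classify every reef and tabulate the management-by-regime design
#'
#' Applies [classify_reef()] to each reef's post-disturbance cover
#' trajectory from the reef-year summaries and fills the `regime` column of
#' the site table. Sites that already carry an external label (anything
#' other than `"unassigned"`) are left untouched, so labels from earlier
#' published classifications can be supplied directly.
#'
#' @param summaries reef-year summary table from [summarize_reef_years()].
#' @param sites site table with `reef_id`, `management` and (optionally)
#'   `regime`.
#' @return list with `sites` (regime filled in) and `design`, the 2x2
#'   management-by-regime count table.
#' @export
classify_all <- function(summaries, sites) {
  if (is.null(sites$regime)) sites$regime <- "unassigned"
  for (i in seq_len(nrow(sites))) {
    if (sites$regime[i] != "unassigned") next
    s <- summaries[summaries$reef_id == sites$reef_id[i], ]
    if (nrow(s) == 0) stop(sprintf("no summaries for reef %s", sites$reef_id[i]), call. = FALSE)
    lab <- tryCatch(
      classify_reef(s$hard_coral, s$macroalgae, s$year),
      error = function(e) {
        stop(sprintf("reef %s: %s", sites$reef_id[i], conditionMessage(e)), call. = FALSE)
      }
    )
    sites$regime[i] <- lab$label
  }
  design <- table(
    management = factor(sites$management, c("fished", "protected")),
    regime = factor(sites$regime, c("recovering", "regime_shifted"))
  )
  list(sites = sites, design = design)
}
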