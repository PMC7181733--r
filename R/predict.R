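## Posterior prediction: percent-recovery trajectories and condition-level
## biomass posteriors.

strata_grid <- function() {
  expand.grid(habitat = 0:1, management = 0:1)
}

stratum_labels <- function(d) {
  d$habitat_label <- ifelse(d$habitat == 1, "regime_shifted", "recovering")
  d$management_label <- ifelse(d$management == 1, "protected", "fished")
  d
}

#' Posterior percent-recovery trajectories and yearly rates
#'
#' From a fitted recovery model, draws `n_draws` posterior samples and, for
#' every habitat x management stratum and survey year, predicts the absolute
#' difference from the 1994 baseline, rescaled to percent recovery from
#' pre-disturbance levels (0% = pre-disturbance value) by dividing by the
#' stratum-mean 1994 level. The per-year recovery rate (% year^-1) is the
#' posterior of the stratum's year slope rescaled the same way. Medians and
#' 95% certainty intervals are reported.
#'
#' @param fit a `"reef_fit"` from [fit_recovery_model()].
#' @param n_draws posterior draws used for the trajectory summaries.
#' @param seed seed for the draw subsample.
#' @return list with `trajectory` (stratum x year, percent scale) and
#'   `rates` (stratum, % year^-1), each with `median`, `lower`, `upper`.
#' @export
predict_recovery <- function(fit, n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "reef_fit"), !is.null(fit$pre_levels))
  post <- as.matrix(fit$samples)
  beta <- post[, RECOVERY_TERMS, drop = FALSE]
  set.seed(seed)
  sub <- beta[sample(nrow(beta), min(n_draws, nrow(beta))), , drop = FALSE]

  cells <- strata_grid()
  year_c <- fit$years - mean(fit$years)
  qs <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)

  traj <- list()
  rates <- list()
  for (r in seq_len(nrow(cells))) {
    h <- cells$habitat[r]
    m <- cells$management[r]
    ref <- fit$pre_levels$pre_level[
      fit$pre_levels$habitat == h & fit$pre_levels$management == m
    ]
    if (length(ref) != 1) {
      stop(sprintf("no pre-disturbance reference level for stratum (habitat=%d, management=%d)", h, m),
        call. = FALSE
      )
    }
    for (k in seq_along(fit$years)) {
      eta <- sub[, 1] + sub[, 2] * h + sub[, 3] * year_c[k] + sub[, 4] * m +
        sub[, 5] * h * year_c[k] + sub[, 6] * m * year_c[k]
      q <- qs(eta / ref * 100)
      traj[[length(traj) + 1L]] <- data.frame(
        habitat = h, management = m, year = fit$years[k],
        lower = q[1], median = q[2], upper = q[3]
      )
    }
    slope <- (beta[, 3] + beta[, 5] * h + beta[, 6] * m) / ref * 100
    q <- qs(slope)
    rates[[length(rates) + 1L]] <- data.frame(
      habitat = h, management = m,
      lower = q[1], median = q[2], upper = q[3]
    )
  }
  list(
    trajectory = stratum_labels(do.call(rbind, traj)),
    rates = stratum_labels(do.call(rbind, rates))
  )
}

#' Posterior biomass by condition
#'
#' Posterior distribution of expected carnivore and herbivore biomass
#' (kg ha^-1) under a named condition: `"pre"` (from the pre-disturbance
#' model) or `"recovering"` / `"regime_shifted"` (from the post-disturbance
#' model, evaluated at the centred-year origin), for fished and protected
#' management. Reef-level terms are set at their population mean (zero), so
#' the summaries describe a typical reef.
#'
#' @param fit a `"reef_fit"` from [fit_trophic_model()].
#' @param conditions subset of conditions to report (defaults to all the
#'   fitted period supports).
#' @param draws optional posterior matrix overriding `as.matrix(fit$samples)`
#'   (used e.g. to examine counterfactuals with coefficients zeroed).
#' @return data frame: `condition`, `fg`, `management`, `median`, `lower`,
#'   `upper` (kg ha^-1).
#' @export
posterior_biomass_by_condition <- function(fit, conditions = NULL, draws = NULL) {
  stopifnot(inherits(fit, "reef_fit"), !is.null(fit$period))
  supported <- if (fit$period == "pre") "pre" else c("recovering", "regime_shifted")
  if (is.null(conditions)) conditions <- supported
  bad <- setdiff(conditions, supported)
  if (length(bad)) {
    stop(sprintf(
      "condition(s) not in the fitted %s-disturbance design: %s",
      fit$period, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  post <- if (is.null(draws)) as.matrix(fit$samples) else draws
  out <- list()
  for (cond in conditions) {
    h <- as.numeric(cond == "regime_shifted")
    for (fg in c("carnivore", "herbivore")) {
      for (m in 0:1) {
        eta <- post[, paste0("(Intercept)_", fg)] +
          m * post[, paste0("management_protected_", fg)]
        if (fit$period == "post") {
          eta <- eta + h * post[, paste0("habitat_shifted_", fg)]
        }
        q <- stats::quantile(exp(eta), c(0.025, 0.5, 0.975), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, fg = fg,
          management = ifelse(m == 1, "protected", "fished"),
          lower = q[1], median = q[2], upper = q[3]
        )
      }
    }
  }
  do.call(rbind, out)
}
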