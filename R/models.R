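## Hierarchical model specification: design builders, parameter layout and
## the exact log posterior (the reference implementation the fast sampling
## engine is checked against).
##
## Two model families share one structure:
##   eta_i = X_i beta + u[g1_i] + v[g2_i] * z_i
## with partial pooling u ~ N(0, tau_u), v ~ N(0, tau_v), and either
##   y_i ~ Normal(eta_i, sigma)                  (recovery trajectories)
##   y_i ~ Gamma(mean = exp(eta_i), shape = k)   (trophic biomass, log link)
## Priors: beta ~ N(0, 10); sigma, tau ~ half-Cauchy(0, 2); k ~ Exp(1).
## Positive scales are sampled on the log scale (log-Jacobian included).

RECOVERY_TERMS <- c(
  "(Intercept)", "habitat_shifted", "year_c", "management_protected",
  "habitat_shifted:year_c", "management_protected:year_c"
)

#' Build the recovery-trajectory design
#'
#' Converts reef-year summaries into the response table of the recovery
#' models: for each post-disturbance survey, `y` is the absolute difference
#' of biomass (kg ha^-1) or richness (species per replicate) from the same
#' reef's 1994 pre-disturbance value. Covariates are habitat regime
#' (recovering = 0, regime-shifted = 1), management (fished = 0, protected =
#' 1), and survey year mean-centred over the post-disturbance years present
#' (2005-2014 gives -4.5, -1.5, 1.5, 4.5).
#'
#' @param summaries reef-year summary table ([summarize_reef_years()]).
#' @param sites labelled site table ([classify_all()]).
#' @param response `"biomass"` (total biomass) or `"richness"`.
#' @return data frame with `reef_id`, `year`, `year_c`, `habitat`,
#'   `management`, `y` and `pre_level` (the reef's 1994 value).
#' @export
build_recovery_design <- function(summaries, sites, response = c("biomass", "richness")) {
  response <- match.arg(response)
  var <- if (response == "biomass") "total_biomass" else "richness"
  pre <- summaries[summaries$year <= BLEACHING_YEAR, c("reef_id", var)]
  if (anyDuplicated(pre$reef_id)) stop("multiple pre-disturbance years per reef", call. = FALSE)
  post <- summaries[summaries$year > BLEACHING_YEAR, ]
  missing <- setdiff(unique(post$reef_id), pre$reef_id)
  if (length(missing)) {
    stop(sprintf(
      "reefs without a 1994 baseline: %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  d <- merge(post, pre, by = "reef_id", suffixes = c("", "_pre"))
  d <- merge(d, sites[, c("reef_id", "management", "regime")], by = "reef_id")
  if (any(d$regime == "unassigned")) {
    stop("sites must carry regime labels (run classify_all first)", call. = FALSE)
  }
  out <- data.frame(
    reef_id = d$reef_id,
    year = d$year,
    year_c = d$year - mean(sort(unique(d$year))),
    habitat = as.integer(d$regime == "regime_shifted"),
    management = as.integer(d$management == "protected"),
    y = d[[var]] - d[[paste0(var, "_pre")]],
    pre_level = d[[paste0(var, "_pre")]],
    stringsAsFactors = FALSE
  )
  if (any(!(out$pre_level > 0))) stop("pre-disturbance levels must be > 0", call. = FALSE)
  out[order(out$reef_id, out$year), ]
}

#' Build the carnivore/herbivore biomass design
#'
#' One row per reef-year and functional group (FG: carnivore or herbivore)
#' with `y` the FG biomass in kg ha^-1 (strictly positive, Gamma support).
#' The pre-disturbance design carries only FG and management; the
#' post-disturbance design adds habitat regime and mean-centred survey year.
#'
#' @inheritParams build_recovery_design
#' @param period `"pre"` (1994 surveys) or `"post"` (2005-2014 surveys).
#' @return data frame with `reef_id`, `year`, `fg`, `management`, `y`, and
#'   for `period = "post"` also `habitat` and `year_c`.
#' @export
build_trophic_design <- function(summaries, sites, period = c("pre", "post")) {
  period <- match.arg(period)
  s <- if (period == "pre") {
    summaries[summaries$year <= BLEACHING_YEAR, ]
  } else {
    summaries[summaries$year > BLEACHING_YEAR, ]
  }
  s <- merge(s, sites[, c("reef_id", "management", "regime")], by = "reef_id")
  if (period == "post" && any(s$regime == "unassigned")) {
    stop("sites must carry regime labels (run classify_all first)", call. = FALSE)
  }
  long <- rbind(
    data.frame(s[c("reef_id", "year", "management", "regime")],
      fg = "carnivore", y = s$carnivore_biomass
    ),
    data.frame(s[c("reef_id", "year", "management", "regime")],
      fg = "herbivore", y = s$herbivore_biomass
    )
  )
  if (any(!(long$y > 0))) {
    stop_rows("trophic design", "FG biomass must be > 0 (Gamma support)", which(!(long$y > 0)))
  }
  out <- data.frame(
    reef_id = long$reef_id, year = long$year, fg = long$fg,
    management = as.integer(long$management == "protected"),
    y = long$y, stringsAsFactors = FALSE
  )
  if (period == "post") {
    out$habitat <- as.integer(long$regime == "regime_shifted")
    out$year_c <- long$year - mean(sort(unique(long$year)))
  }
  out[order(out$fg, out$reef_id, out$year), ]
}

#' Specify a hierarchical model over a built design
#'
#' Assembles the fixed-effect design matrix, grouping indices for partially
#' pooled reef terms, parameter layout and priors for one of the three model
#' structures: `"recovery"` (Normal likelihood, identity link, reef
#' intercepts and reef year-slopes), `"trophic_pre"` (Gamma likelihood, log
#' link, FG-specific intercept and management effect, reef-within-FG
#' intercepts) or `"trophic_post"` (Gamma, log link, FG-specific habitat /
#' year / management effects and interactions, reef-within-FG intercepts and
#' year-slopes).
#'
#' @param design design data frame from [build_recovery_design()] or
#'   [build_trophic_design()].
#' @param structure one of `"recovery"`, `"trophic_pre"`, `"trophic_post"`.
#' @param prior_beta_sd SD of the Normal(0, .) prior on fixed coefficients.
#' @param prior_scale scale of the half-Cauchy(0, .) prior on sigma and the
#'   pooling SDs.
#' @param prior_shape_rate rate of the Exponential prior on the Gamma shape.
#' @return object of class `"hier_model"`: likelihood, design matrix `X`,
#'   group indices, parameter names and an initial value.
#' @export
hier_model <- function(design, structure = c("recovery", "trophic_pre", "trophic_post"),
                       prior_beta_sd = 10, prior_scale = 2, prior_shape_rate = 1) {
  structure <- match.arg(structure)
  n <- nrow(design)
  if (structure == "recovery") {
    likelihood <- "normal"
    X <- cbind(
      rep(1, n), design$habitat, design$year_c, design$management,
      design$habitat * design$year_c, design$management * design$year_c
    )
    colnames(X) <- RECOVERY_TERMS
    g_levels <- sort(unique(design$reef_id))
    g1 <- match(design$reef_id, g_levels)
    g2 <- g1
    z <- design$year_c
    s_levels <- g_levels
  } else {
    likelihood <- "gamma_mean_shape"
    fgs <- c("carnivore", "herbivore")
    terms <- if (structure == "trophic_pre") {
      c("(Intercept)", "management_protected")
    } else {
      RECOVERY_TERMS
    }
    X <- matrix(0, n, length(terms) * 2)
    colnames(X) <- as.vector(outer(terms, fgs, paste, sep = "_"))
    for (j in seq_along(fgs)) {
      ind <- as.numeric(design$fg == fgs[j])
      block <- if (structure == "trophic_pre") {
        cbind(ind, ind * design$management)
      } else {
        cbind(
          ind, ind * design$habitat, ind * design$year_c, ind * design$management,
          ind * design$habitat * design$year_c, ind * design$management * design$year_c
        )
      }
      X[, (j - 1) * length(terms) + seq_along(terms)] <- block
    }
    key <- paste(design$reef_id, design$fg, sep = ":")
    g_levels <- sort(unique(key))
    g1 <- match(key, g_levels)
    if (structure == "trophic_post") {
      g2 <- g1
      z <- design$year_c
      s_levels <- g_levels
    } else {
      g2 <- NULL
      z <- NULL
      s_levels <- character(0)
    }
  }

  par_names <- c(
    colnames(X),
    if (length(g_levels)) paste0("u[", g_levels, "]"),
    if (length(s_levels)) paste0("v[", s_levels, "]"),
    if (length(g_levels)) "log_tau_u",
    if (length(s_levels)) "log_tau_v",
    if (likelihood == "normal") "log_sigma" else "log_k"
  )

  init <- setNames(numeric(length(par_names)), par_names)
  if (n > 0) {
    if (likelihood == "normal") {
      init["(Intercept)"] <- mean(design$y)
      init["log_sigma"] <- log(stats::sd(design$y) + 1e-3)
    } else {
      init[grep("^\\(Intercept\\)", par_names)] <- log(mean(design$y))
    }
  }

  out <- structure(
    list(
      structure = structure, likelihood = likelihood,
      y = design$y, X = X, g1 = g1, g2 = g2, z = z,
      group_levels = g_levels, slope_levels = s_levels,
      prior_beta_sd = prior_beta_sd, prior_scale = prior_scale,
      prior_shape_rate = prior_shape_rate,
      par_names = par_names, n_par = length(par_names), init = init,
      design = design,
      # priors on fixed coefficients are applied on a standardized response
      # scale for the Normal models, so N(0, 10) is weakly informative
      # whatever the measurement units; draws are rescaled back after
      # sampling (see fit_hier_model)
      y_scale = if (likelihood == "normal" && n > 1 && stats::sd(design$y) > 0) {
        stats::sd(design$y)
      } else {
        1
      }
    ),
    class = "hier_model"
  )
  out$recenter <- recenter_map(out)
  out
}

# For every fixed-effect column that is constant within pooling groups
# (type 1, value c_g per intercept group) or proportional to the slope
# covariate with a group-constant factor (type 2, x_ij = c_g * z_i), the
# direction {beta_j += delta, group effects -= delta * c_g} leaves the
# likelihood invariant. The sampler exploits this with exact Gibbs
# recentering moves, which removes the fixed-vs-pooled confounding that
# otherwise cripples componentwise mixing.
recenter_map <- function(model) {
  p <- ncol(model$X)
  type <- integer(p)
  coef <- vector("list", p)
  group_const <- function(x, g, n_g) {
    c_g <- rep(NA_real_, n_g)
    for (g_i in seq_len(n_g)) {
      vals <- x[g == g_i]
      if (length(vals) == 0) {
        c_g[g_i] <- 0
      } else if (max(vals) - min(vals) < 1e-12) {
        c_g[g_i] <- vals[1]
      } else {
        return(NULL)
      }
    }
    c_g
  }
  for (j in seq_len(p)) {
    x <- model$X[, j]
    if (length(model$group_levels)) {
      c_g <- group_const(x, model$g1, length(model$group_levels))
      if (!is.null(c_g)) {
        type[j] <- 1L
        coef[[j]] <- c_g
        next
      }
    }
    if (length(model$slope_levels)) {
      ok <- abs(model$z) > 1e-12 | abs(x) < 1e-12
      if (all(ok)) {
        ratio <- ifelse(abs(model$z) > 1e-12, x / model$z, NA_real_)
        c_g <- rep(NA_real_, length(model$slope_levels))
        const <- TRUE
        for (g_i in seq_along(c_g)) {
          vals <- ratio[model$g2 == g_i & !is.na(ratio)]
          if (length(vals) == 0) {
            c_g[g_i] <- 0
          } else if (max(vals) - min(vals) < 1e-9) {
            c_g[g_i] <- vals[1]
          } else {
            const <- FALSE
            break
          }
        }
        if (const) {
          type[j] <- 2L
          coef[[j]] <- c_g
        }
      }
    }
  }
  list(type = type, coef = coef)
}

#' @export
print.hier_model <- function(x, ...) {
  cat(sprintf(
    "Hierarchical %s model (%s likelihood): %d observations, %d parameters\n",
    x$structure, x$likelihood, length(x$y), x$n_par
  ))
  cat("  fixed effects:", paste(colnames(x$X), collapse = ", "), "\n")
  if (length(x$group_levels)) {
    cat(sprintf("  %d partially pooled intercepts", length(x$group_levels)))
    if (length(x$slope_levels)) cat(sprintf(", %d pooled slopes", length(x$slope_levels)))
    cat("\n")
  }
  invisible(x)
}

split_params <- function(model, params) {
  p <- ncol(model$X)
  nu <- length(model$group_levels)
  nv <- length(model$slope_levels)
  stopifnot(length(params) == model$n_par)
  i <- p
  u <- if (nu) params[i + seq_len(nu)] else numeric(0)
  i <- i + nu
  v <- if (nv) params[i + seq_len(nv)] else numeric(0)
  i <- i + nv
  log_tau_u <- if (nu) params[[i <- i + 1L]] else NA_real_
  log_tau_v <- if (nv) params[[i <- i + 1L]] else NA_real_
  log_scale <- params[[i + 1L]]
  list(
    beta = params[seq_len(p)], u = u, v = v,
    log_tau_u = log_tau_u, log_tau_v = log_tau_v, log_scale = log_scale
  )
}

linear_predictor <- function(model, pars) {
  eta <- as.numeric(model$X %*% pars$beta)
  if (length(pars$u)) eta <- eta + pars$u[model$g1]
  if (length(pars$v)) eta <- eta + pars$v[model$g2] * model$z
  eta
}

#' Exact log posterior of a hierarchical model
#'
#' Sum of the observation log likelihood, the partial-pooling terms for reef
#' intercepts/slopes, and all prior log densities (including log-Jacobians
#' for the log-scale parameterisation of sigma, the pooling SDs and the
#' Gamma shape). With zero observations it returns the log prior alone.
#' This pure-R implementation is the reference the compiled sampling engine
#' is verified against.
#'
#' @param model a [hier_model()].
#' @param data observation list (`y`, `X`, `g1`, `g2`, `z`); defaults to the
#'   model's own data, overridable for toy checks.
#' @param params flat named parameter vector in `model$par_names` order.
#' @return scalar log posterior density (unnormalised).
#' @export
log_posterior <- function(model, data = NULL, params) {
  if (!is.null(data)) {
    model[c("y", "X", "g1", "g2", "z")] <- data[c("y", "X", "g1", "g2", "z")]
  }
  pars <- split_params(model, params)
  lp <- sum(stats::dnorm(pars$beta, 0, model$prior_beta_sd, log = TRUE))
  if (length(pars$u)) {
    tau_u <- exp(pars$log_tau_u)
    lp <- lp + log_density_half_cauchy(tau_u, model$prior_scale) + pars$log_tau_u
    lp <- lp + sum(stats::dnorm(pars$u, 0, tau_u, log = TRUE))
  }
  if (length(pars$v)) {
    tau_v <- exp(pars$log_tau_v)
    lp <- lp + log_density_half_cauchy(tau_v, model$prior_scale) + pars$log_tau_v
    lp <- lp + sum(stats::dnorm(pars$v, 0, tau_v, log = TRUE))
  }
  scale <- exp(pars$log_scale)
  if (model$likelihood == "normal") {
    lp <- lp + log_density_half_cauchy(scale, model$prior_scale) + pars$log_scale
  } else {
    lp <- lp + stats::dexp(scale, model$prior_shape_rate, log = TRUE) + pars$log_scale
  }
  if (length(model$y) > 0) {
    eta <- linear_predictor(model, pars)
    lp <- lp + if (model$likelihood == "normal") {
      sum(log_density_normal(model$y, eta, scale))
    } else {
      sum(log_density_gamma_mean_shape(model$y, exp(eta), scale))
    }
  }
  lp
}
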