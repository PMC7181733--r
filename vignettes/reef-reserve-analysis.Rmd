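---
title: "Assessing marine reserve effects across a coral bleaching event"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing marine reserve effects across a coral bleaching event}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

No-take marine reserves reliably raise fish biomass, species richness and
(often) coral cover relative to fished reefs — under the benthic conditions
in which that evidence was collected. Mass coral bleaching reshuffles those
conditions: after a severe thermal disturbance some reefs recover to hard
coral dominance while others shift to macroalgal dominance, and it is an
open question which reserve benefits survive the transition, and for which
trophic groups of fish.

`reefmpa` implements a complete before–after–control–impact analysis of this
question for long-term underwater visual census (UVC) monitoring data: 21
reefs (9 inside no-take reserves, 12 fished), surveyed before a mass
bleaching event (1994) and four times afterwards (2005, 2008, 2011, 2014),
with 8–16 replicate 7 m-radius point counts per reef per year. All field
quantities flow through four stages: biomass construction, regime
classification, jackknifed reserve-effect estimation, and Bayesian
hierarchical trajectory models. A synthetic-data generator reproduces the
design with known ground truth, so every stage is testable end to end
without field data.

## Biomass construction

Each fish record is a (species, length, count) triple within a point count.
Length converts to mass through the allometric power law $W = a L^b$ (grams
from cm), with species-specific coefficients from the trait table. A
replicate's biomass is the summed mass divided by the count area
$\pi \cdot 7^2 \approx 153.9\ \mathrm{m}^2$ and scaled to kg ha$^{-1}$
(1 g m$^{-2}$ = 10 kg ha$^{-1}$). Reef–year summaries are arithmetic means
over replicates — the mean rather than the sum keeps units per-area and is
insensitive to the varying replicate count (8–16). Species richness is
reported per replicate (a density of species per ~154 m²), not pooled per
reef, because pooled richness would conflate survey effort with diversity.

Records with a count but no length are rejected rather than imputed; silent
imputation would bias biomass low or high depending on the species' size
distribution. The benthic table defines the replicate registry: every point
count receives benthic scores even when no fish were recorded, so an empty
replicate legitimately contributes zero biomass to the reef mean.

Trophic groups follow diet: piscivores, mixed-diet feeders,
scrapers/excavators, grazers, macroalgal browsers, planktivores,
corallivores. Carnivores = piscivores + mixed-diet; herbivores = grazers +
scrapers/excavators + browsers.

## Regime classification

A reef is *regime-shifted* when post-disturbance macroalgal cover exceeds
hard-coral cover in the final survey year **and** macroalgae is at least as
high as coral in at least half the post-disturbance years; otherwise it is
*recovering*. This operationalises "macroalgal cover becomes greater than
coral cover and remains high or is increasing" as a deterministic,
order-independent rule; exact ties break toward recovering (a tie is not
macroalgal dominance). Only surveys after the 1998 disturbance are
consulted. Because published labels for these reefs come from earlier work,
`classify_all()` accepts externally supplied labels (any non-`"unassigned"`
regime in the site table bypasses the rule).

## Reserve effects and the drop-one jackknife

For any reef-level variable we estimate the protected–fished contrast as a
mean difference or as the response ratio
$(\bar{x}_P/\bar{x}_F - 1) \times 100$ (percent scale, 0 = no effect).
Uncertainty uses a drop-one jackknife over *sites* (never replicates):
recompute the contrast leaving out each reef in turn — 21 leave-one-out
estimates per survey year for the full design. Pre-disturbance (1994)
contrasts pool all 21 reefs; post-disturbance contrasts are computed within
recovering and regime-shifted strata separately.

Two jackknife summaries are reported:

* `jackknife_min` / `jackknife_max` — the extreme leave-one-out estimates.
  This is a *site-influence band*: how far a single exceptional reef can
  move the estimate. It is deliberately not a confidence interval; its
  half-width is roughly the largest single-site deviation divided by
  (group size − 1), which sits *below* the sampling SD of the estimate, so
  under a true null it covers zero only ~35–45% of the time regardless of
  the data distribution.
* `jackknife_se` — the classical (Tukey) jackknife standard error
  $\sqrt{\frac{n-1}{n}\sum_i(\hat\theta_{(i)}-\bar\theta_{(\cdot)})^2}$.
  This is the calibrated uncertainty: `estimate ± 1.96 × jackknife_se` is
  the interval the package uses for any significance-style statement, and
  it covers zero at near-nominal rates under a null (verified by
  simulation in the test suite).

## Hierarchical models

### Recovery trajectories (Normal likelihood)

For each reef $r$ and post-disturbance survey $i$, the response is the
absolute difference of total biomass (kg ha$^{-1}$) or richness from the
reef's own 1994 value:

$$y_i \sim \mathrm{N}(\mu_i, \sigma)$$
$$\mu_i = \beta_{0,r} + \beta_1\,\mathrm{habitat}_i + \beta_2\,\mathrm{year}_{i,r}
  + \beta_3\,\mathrm{management}_i + \beta_4\,\mathrm{habitat} \times \mathrm{year}_i
  + \beta_5\,\mathrm{management} \times \mathrm{year}_i$$

Habitat is recovering (0) vs regime-shifted (1), management fished (0) vs
protected (1), and survey year is mean-centred (2005–2014 gives −4.5, −1.5,
1.5, 4.5). Reef-specific intercepts and year slopes are *partially pooled*:
$u_r \sim \mathrm{N}(0, \tau_u)$, $v_r \sim \mathrm{N}(0, \tau_v)$ with
half-Cauchy(0, 2) hyperpriors on the pooling SDs. With 21 reefs, unpooled
reef terms would be noisy and fully pooled ones would ignore the repeated
measures; partial pooling is the idiom of the hierarchical-regression
software this design follows.

### Carnivore/herbivore biomass (Gamma likelihood)

Functional-group (FG) biomass is strictly positive and right-skewed, so it
is modelled as Gamma in mean–shape form, $y_i \sim
\mathrm{Gamma}(\mu_i, k)$ with $E[y] = \mu$, $\mathrm{Var}[y] = \mu^2/k$,
and shape prior $k \sim \mathrm{Exponential}(1)$. The linear predictor is on
the **log scale** — the likelihood requires $\mu > 0$ and reserve effects on
biomass are naturally multiplicative — so reported condition medians are
exponentials of linear-predictor posteriors. The pre-disturbance model has
FG-specific intercepts and management effects with pooled reef-within-FG
intercepts; the post-disturbance model adds FG-specific habitat, centred
year and management effects with year interactions, plus pooled
reef-within-FG year slopes.

### Priors and scaling

Fixed coefficients get $\mathrm{N}(0, 10)$ priors and scale parameters
half-Cauchy(0, 2) (the positive-support reading of a Cauchy(0, 2) prior on
$\sigma$). On the log-link Gamma models these are weakly informative as
stated. For the identity-link Normal models, whether N(0, 10) is weak
depends entirely on the measurement units, so the package fits those models
on a standardized response ($y/\mathrm{sd}(y)$) and rescales the draws
back afterwards: the stated priors then act on a unit-scale response and
remain weakly informative whatever the units of the input data.

### Sampling

Posteriors are sampled by componentwise adaptive random-walk Metropolis:
7000 iterations with 1500 warmup across 3 chains by default. Each parameter
has its own proposal SD, adapted toward 44% acceptance during warmup and
frozen afterwards so the post-warmup kernel is fixed. Three standard
refinements make the hierarchical geometry tractable for a random-walk
sampler:

1. **Non-centred pooling.** Reef effects are sampled as $u = \tau_u
   \tilde{u}$ with $\tilde{u} \sim \mathrm{N}(0,1)$. The centred form has an
   unbounded density spike at $\tau \to 0$ (the "funnel") that can trap a
   random-walk chain in a spurious complete-pooling mode.
2. **Interweaved scale updates.** Each pooling SD is updated twice per
   iteration, once in non-centred and once in centred form (the latter is
   likelihood-invariant), which mixes $\tau$ efficiently in both strong- and
   weak-pooling regimes.
3. **Gibbs recentering.** Every fixed effect whose design column is
   constant within pooling groups (all of them, in these models) is exactly
   confounded with a direction in the reef effects; a Gibbs move along that
   likelihood-invariant direction is drawn from its closed-form Gaussian
   conditional each iteration, removing the confounding that otherwise
   dominates the autocorrelation.

The engine is compiled (Rcpp) with the linear predictor cached and
reef-level updates touching only their own observations; a paper-scale fit
takes about a second. The identical algorithm, minus the model-specific
moves, is available for arbitrary log posteriors as `sample_posterior()`,
and the pure-R `log_posterior()` is the reference the compiled log
posterior is verified against (to 1e-10) in the tests.

Convergence is assessed with split R-hat (pass requires every parameter
within 0.01 of 1) and autocorrelation-based effective sample sizes;
`diagnostics()` implements both from first principles and is itself tested
against iid and deliberately separated chains.

### Posterior prediction

Recovery trajectories are summarised by drawing 1000 posterior samples per
habitat × management stratum and survey year and rescaling the predicted
absolute difference to *percent recovery from pre-disturbance levels*
(0% = the 1994 value). The denominator is the stratum-mean 1994 level
(mean over that cell's reefs); per-reef outputs would use per-reef 1994
levels. Yearly recovery rates (% year$^{-1}$) are the posterior of the
stratum slope $\beta_2 + \beta_4\,\mathrm{habitat} +
\beta_5\,\mathrm{management}$ under the same rescaling — the stratum-level
slope posterior, not including reef-level slope spread. Summaries are
posterior medians with 95% certainty intervals. Condition-level
carnivore/herbivore biomass is $\exp(\eta)$ at the centred-year origin with
reef effects at their population mean of zero — a "typical reef" summary.

## The synthetic-data generator

`simulate_survey_data()` emulates the study conditions, which are fixed as
generator defaults:

* 21 reefs in the 2×2 design (7 fished-recovering, 5 protected-recovering,
  5 fished-shifted, 4 protected-shifted), 8–16 replicates per reef-year,
  survey years 1994–2014, 134 species in 16 families with all trophic
  groups represented.
* A uniform pre-disturbance reserve multiplier of 1.75 on expected biomass
  (the +75% response ratio) over a fished baseline of 340 kg ha$^{-1}$
  split across groups so carnivores and herbivores are near parity
  (~145 kg ha$^{-1}$ each).
* Post-disturbance expected total biomass follows linear
  percent-of-pre-level trajectories per stratum with slopes 7 / 4 / 2 / 0 %
  year$^{-1}$ (fished-recovering / protected-recovering / fished-shifted /
  protected-shifted), and trophic composition shifts toward herbivores
  (more scrapers on recovering reefs, more browsers on shifted reefs).
* Benthic cover is piecewise linear with a 1998 collapse: coral crashes
  then regrows on recovering reefs; macroalgae takes over on shifted reefs.
  Protected reefs carry a +15 point pre-disturbance coral bonus.
* Counts are gamma-mixed Poisson (negative binomial, dispersion 4) per
  species × replicate; expected counts are derived from the target biomass
  through each species' expected individual mass, using the exact lognormal
  length-moment so the expectation is unbiased. Reef quality is
  mean-corrected lognormal (SD 0.25), giving realistic right-skewed
  between-reef variation. Individual lengths are lognormal around
  species-typical sizes and recorded to the nearest cm, as in UVC practice.

What the generator does **not** emulate: species-level ecological realism
(abundance ranks are a fixed geometric series within groups), spatial or
temporal autocorrelation beyond reef identity, observer error in lengths or
covers, and — importantly — species richness is *emergent* from the count
process rather than controlled. Richness contrasts come out qualitatively
right (protected reefs record more species per replicate because they hold
more individuals) but their magnitudes are not calibrated, so richness
checks in the tests are directional, not quantitative. Passing tests
therefore demonstrate that the estimators recover the moment structure the
analyses assume, not that they are robust to every feature of real survey
data.

The null scenario (`scenario = "null"`) sets the multiplier to 1, all
trajectory slopes and offsets to 0 and removes the protected coral bonus;
it is used for calibration checks (a null world should produce no
significant reserve effects).

## Numerical choices and degenerate inputs

* Benthic cover rows may sum below 100 (unscored substrate) and up to 100.5
  (rounding of visual estimates); larger sums are validation errors.
  Structural complexity is the 6-point scale coded 0–5.
* Classification requires at least two post-disturbance years; fewer is an
  error, not a guess.
* Jackknife strata require at least two sites per management group so no
  drop can empty a group; thinner strata are skipped with a warning.
* Gamma responses must be strictly positive; a zero FG biomass is an error
  at design-building time rather than a silent exclusion.
* MCMC runs are reproducible: chain $c$ of `sample_posterior()` uses seed
  `seed + c − 1`; the compiled engine draws all chains from one R RNG
  stream seeded once. Same seed, byte-identical draws.
* Posterior summaries use medians (and 95% quantile intervals) rather than
  means: medians are link-equivariant for the log-link models and agree
  with the mean for the symmetric Normal-model posteriors.

## Problem sizes used in the tests

The test suite runs everything at the study's own size (21 reefs, 5 survey
years). Model-fit tests use 2000–5000 iterations with 2 chains — enough for
the convergence rule to pass on these posteriors — while the acceptance
checks of the sampling protocol itself use the full 7000/1500 × 3
configuration. The interval-calibration experiment uses 50 replicate
datasets drawn directly from the recovery model's data-generating process
at study size, and the generator-calibration experiment averages 20 seeds
of the 1994 survey; both sizes give binomial/Monte-Carlo margins well
inside the thresholds they are tested against.

## Known limitations

* The sampler is random-walk based; posteriors with hundreds of strongly
  correlated parameters beyond the built-in structures would mix poorly
  compared to gradient-based samplers. For the models here, effective
  sample sizes are in the thousands.
* The regime rule is a deterministic reconstruction of a verbal definition;
  borderline reefs (macroalgae ≈ coral in the final year) are sensitive to
  survey noise, which is why external labels can be supplied.
* Percent-recovery rates share one denominator per stratum; reefs with
  atypical 1994 levels are better served by the per-reef outputs.
* The four-model structure (biomass and richness recovery; pre- and
  post-disturbance trophic) treats the two recovery responses in separate
  fits; no cross-response correlation is modelled.
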