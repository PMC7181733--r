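# reefmpa

Before–after–control–impact analysis of **no-take marine reserve effects on
coral reefs across a mass bleaching event**, for long-term underwater visual
census (UVC) monitoring data.

The package is aimed at reef ecologists and monitoring programmes that hold
repeated UVC surveys (fish counts and lengths, benthic cover, structural
complexity) inside and outside no-take reserves, spanning a climate-driven
disturbance, and want to answer: did reserve benefits on the benthos, fish
richness, fish biomass and trophic structure survive the disturbance — and
on which reef trajectories (coral-recovering vs macroalgal regime-shifted)?

## What it computes

1. **Biomass construction.** Fish lengths convert to mass with the
   allometric power law *W = a·L^b* (g from cm); replicate biomass is summed
   mass over the 7 m-radius point-count area (π·7² ≈ 153.9 m²) expressed in
   kg ha⁻¹; reef-year summaries are means over 8–16 replicates, totalled and
   partitioned by trophic group (carnivores = piscivores + mixed-diet;
   herbivores = grazers + scrapers/excavators + browsers).
2. **Regime classification.** A reef is *regime-shifted* when
   post-disturbance macroalgal cover exceeds hard-coral cover in the final
   survey year and in at least half of the post-disturbance years; otherwise
   *recovering*. External labels can be supplied instead.
3. **Reserve effects.** Protected-vs-fished mean differences and response
   ratios ((x̄_P/x̄_F − 1)·100), with **drop-one jackknife** uncertainty over
   sites: one leave-one-out estimate per reef (21 per survey year), reported
   as the min/max influence band plus the classical jackknife SE.
4. **Bayesian hierarchical models** (adaptive MCMC, split R-hat and ESS
   diagnostics):
   - recovery trajectories: yᵢ ~ N(μᵢ, σ), μᵢ = β₀,ᵣ + β₁·habitat +
     β₂·yearᵢ,ᵣ + β₃·management + β₄·habitat×year + β₅·management×year,
     where y is the difference from the reef's 1994 value and reef
     intercepts/slopes are partially pooled;
   - carnivore/herbivore biomass: y ~ Gamma(μ, k) in mean–shape form with a
     log link, FG-specific effects, pre- and post-disturbance structures.
   Posterior predictions are rescaled to **percent recovery from
   pre-disturbance levels** with per-year rates (% yr⁻¹) and 95% certainty
   intervals.
5. **Synthetic data with known truth.** `simulate_survey_data()` reproduces
   the study design (21 reefs: 7 fished-recovering, 5 protected-recovering,
   5 fished-shifted, 4 protected-shifted; 134 species in 16 families;
   negative-binomial counts; a 1.75× pre-disturbance reserve multiplier and
   7/4/2/0 % yr⁻¹ stratum recovery slopes), so every stage is testable
   without field data.

## Worked example

```r
library(reefmpa)

sim <- simulate_survey_data(seed = 1)          # synthetic study-design dataset
summaries <- summarize_reef_years(sim$data)    # kg/ha, richness, covers per reef-year
cls <- classify_all(summaries, sim$data$sites) # regime labels + design table
cls$design
#>            regime
#> management  recovering regime_shifted
#>   fished             7              5
#>   protected          5              4

effects_by_group(summaries, cls$sites, years = 1994,
                 grouping = "total", estimator = "response_ratio_pct")
#>       variable year stratum          estimator estimate jackknife_min
#>  total_biomass 1994     all response_ratio_pct     69.5         59.81
#>  jackknife_max jackknife_se n_protected n_fished
#>          78.44        20.51           9       12

fit <- fit_recovery_model(summaries, cls$sites, "biomass", seed = 1)
fit$report
#> Convergence: PASS (all |R-hat - 1| <= 0.01: max R-hat 1.0033, min ESS 12859)

predict_recovery(fit, seed = 1)$rates
#>    habitat_label management_label median lower upper
#> 1     recovering           fished    7.2  4.26  10.0
#> 2 regime_shifted           fished    3.2  0.29   6.1
#> 3     recovering        protected    3.4  1.51   5.3
#> 4 regime_shifted        protected    1.2 -0.66   3.0
```

Reading the output: fish biomass was 69.5% higher on protected reefs in
1994 (the generator's truth is +75%; the jackknife band shows the influence
of single reefs). After the disturbance, biomass re-accumulates fastest on
fished recovering reefs (7.2% of the pre-disturbance level per year, truth
7) and is flat on protected shifted reefs (1.2% yr⁻¹ with an interval
spanning zero, truth 0) — the pattern that erodes the reserve effect on
recovering reefs.

`fit_trophic_model()` + `posterior_biomass_by_condition()` give posterior
carnivore/herbivore biomass per management and reef condition, and
`run_pipeline()` (or `inst/scripts/reefmpa.R run-all`) executes every stage
and writes CSV/JSON outputs, a text report and reproducibility metadata.

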