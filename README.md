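# edgecndd

Analysis of how proximity to forest edges and experimental exclusion of
natural enemies (fungal pathogens, insect herbivores) alter seedling
diversity and conspecific negative density dependence (CNDD) during the
seed-to-seedling transition.

The package is aimed at community ecologists running (or simulating)
edge-gradient recruitment experiments: stations arrayed at increasing
distance from a forest edge, each with a pair of 1 m² seed traps and
five 1 m² seedling plots under pesticide treatments (untreated control,
water control, fungicide, insecticide, both pesticides).

## What it computes

**CNDD.** Recruitment follows the power law **R** = *a* · **S**^*b*
with negative-binomial errors, where *S* is seed density and *b* the
strength of density dependence (*b* = 1: no CNDD; *b* < 1: recruitment
saturates with conspecific density).  The hierarchical Bayesian model
estimates one community slope per edge-distance × treatment cell with
species random slopes and species/station intercepts, fitted by MCMC
(JAGS).  Because seeds are counted in traps adjacent to the plots, trap
noise attenuates the slope and mimics CNDD; the model corrects for this
by treating true log seed density as latent, with a log-normal prior
moment-matched to the mean and variance of the two adjacent traps.
Species enter the model if they occur in ≥ 10 stations, vary ≥ 3-fold
in seed density, and have ≥ 5 seedlings.

**Diversity.** Inverse Simpson, exponentiated Shannon and rarefied
richness (2 seedlings / 5 seeds) per plot and per station seed
assemblage, then Gaussian mixed-model contrasts of recruit diversity
across edge × treatment cells with seed diversity as an additive
covariate, Wald z tests with Tukey adjustment, and compact-letter
displays.

**Synthetic data.** A generator reproducing the full sampling design
(15 locations × 3 stations at 0–5 m, 20–30 m, 50–60 m from the edge,
plus 15 interior stations at 90–100 m; two traps and five treatment
plots per station) and the assumed statistical structure (log-series
community, log-normally aggregated seed rain, Poisson trap counts,
power-law recruitment with configurable slopes per cell) under known
ground truth, so every estimator can be validated by simulation.

## Worked example

```r
library(edgecndd)

# simulate a full campaign: 146 stations, 730 plots
sim  <- simulate_dataset(design_config(keep_stations = 146),
                         community_params(rng_seed = 7))
dtab <- diversity_table(sim$data, indices = "inverse_simpson")
fit  <- fit_diversity_model(dtab, index = "inverse_simpson")
fit$letters[fit$letters$group == "E3", ]
#>  group   treatment letters
#>     E3     Control       a
#>     E3   fungicide       b
#>     E3        both       b
#>     E3 insecticide       b

flt  <- filter_species(sim$data)   # all 40 species pass in this community
cndd <- fit_cndd_model(sim$data, flt$species,
                       cndd_model_spec(chains = 1, iter = 1000,
                                       warmup = 300, seed = 1))
subset(cndd$summary, edge == "E3",
       select = c(cell, mean_b, ci_low, ci_high, cndd_flag))
#>            cell    mean_b    ci_low    ci_high cndd_flag
#>         E3:both 0.8441025 0.7747422 0.9006498      TRUE
#>      E3:Control 0.4478046 0.3839387 0.5072013      TRUE
#>    E3:fungicide 0.8230073 0.7520070 0.8895986      TRUE
#>  E3:insecticide 0.8587177 0.7890430 0.9277894      TRUE
```

Interior control plots show strong CNDD (slope ~0.45, far below 1, the
no-CNDD reference); in pesticide-sprayed plots density dependence is
much weaker (~0.82-0.86) — the treatments removed most of the
density-dependent mortality, and correspondingly their recruit
diversity is lower than in controls (the letter display separates
Control from all pesticide cells at E3 only).  Numbers above are from
the exact commands shown (values vary with the seed; the CNDD table
uses the shortened chain shown, not the 4 × 2000 default, and
estimates carry the small attenuation documented in the vignette).

A pipeline driver runs everything from one YAML config
(`run_pipeline()`, or `inst/cli/edgecndd run --config cfg.yaml`),
writing diversity tables, model summaries, posterior draws,
diagnostics and a markdown report.

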