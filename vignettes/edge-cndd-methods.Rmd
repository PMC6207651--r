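---
title: "Models and design choices in edgecndd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in edgecndd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Forest fragmentation puts a large share of remaining tropical forest
within a hundred metres of an edge.  One mechanism thought to maintain
tree diversity — conspecific negative density dependence (CNDD), in
which specialised fungal pathogens and insect herbivores
disproportionately kill seeds and seedlings of locally abundant
species — may weaken near edges, eroding diversity during the
seed-to-seedling transition even when the arriving seed rain stays
diverse.  `edgecndd` implements a complete analysis pipeline for field
experiments designed to test this: stations along an edge-to-interior
gradient, each with a pair of 1 m² seed traps and five 1 m² seedling
plots assigned to pesticide treatments (untreated control,
water-sprayed control, fungicide, insecticide, both).

Because such field data are typically not public, the package includes
a first-class synthetic-data generator that reproduces the sampling
design and the statistical structure the analyses assume, under fully
known ground truth.  Every stage of the pipeline is tested against that
generator.

# The recruitment model

The seed-to-seedling transition for species $s$ at station $j$ follows
a power law

$$R = a \, S^{b},$$

where $S$ is the (latent) seed density, $a$ the baseline transition
probability, and $b$ the strength of density dependence: $b = 1$ means
recruitment proportional to seed arrival (no CNDD), $b < 1$ means
per-capita recruitment declines with conspecific density.  Observed
recruit counts are negative binomial around this mean.  On the log
scale the fitted model is

$$\log \mu_{i} = \alpha + \delta_{c(i)} + a_{s(i)} + g_{j(i)} +
  \left(\beta_{c(i)} + u_{s(i)}\right)\, (z_{js} - \bar z),\qquad
  R_i \sim \mathrm{NB}(\mu_i, \phi),$$

with one fixed slope $\beta_c$ per edge-distance × treatment cell,
species slope deviations $u_s \sim N(0, \tau^2)$ shared across cells,
species and station random intercepts, cell main effects $\delta_c$ on
the baseline rate (reference cell zero), and $z_{js} = \log S_{js}$.
The cell intercepts reflect that enemy exclusion changes recruitment
rates everywhere, not only the density-dependent slope; they are also
what makes centring the covariate valid across cells (the
$-\beta_c \bar z$ offsets fold into $\delta_c$).  Centring $z$ at its
mean prior value decorrelates slope and intercept and improves MCMC
mixing by an order of magnitude; $\beta_c$, the community-wide slope
reported per cell, is unaffected.

## Measurement-error correction

Seed rain is measured in traps adjacent to, not inside, the seedling
plots.  Trap counting noise acts as classical errors-in-variables and
attenuates the slope toward zero — which *mimics* CNDD ($b < 1$), so an
uncorrected analysis overstates density dependence.  The correction
treats the true log seed density as latent with a log-normal prior
moment-matched to the two adjacent traps: with pair mean $m$ and
sample variance $v' = \max(v, 0.25)$,

$$\sigma^2 = \log(1 + v'/m^2), \qquad \mu = \log m - \sigma^2/2,$$

so the implied log-normal has mean $m$ and variance $v'$ exactly.  The
variance floor (0.25, below one-seed resolution) keeps the prior proper
when the two traps agree exactly.  When both traps are empty but
seedlings of the species occurred at the station, the seedling count
substitutes for both moments — a deliberately conservative imputation
that biases *against* detecting CNDD.  Pairs with neither seeds nor
seedlings carry no information and are dropped.

The package also exposes the uncorrected model (`fit_naive_model()`,
log seed density fixed at $\log\max(m, 0.5)$) purely as the comparison
arm: on simulations with $b = 1$ and Poisson trap noise the naive
posterior mean falls below the corrected one, and the corrected one is
closer to the truth.  The correction is partial, not exact — with only
two trap replicates the moment prior ignores population-level
shrinkage, so a small residual attenuation remains at sparse seed
densities.  This is a property of the two-trap design itself.

## Priors and sampler

Priors are weakly informative and centred on "no CNDD":
$\beta_c \sim N(1, 1)$, intercept $\alpha \sim N(-1, 1.5)$ on the log
scale, all hierarchical SDs half-Normal(0, 1), and
$\phi \sim \mathrm{Gamma}(2, 0.2)$.  Sampling uses JAGS; the default
settings are 4 chains × 2000 iterations with the first 1000 discarded
(split between adaptation and burn-in).

Parameterisation matters for mixing here.  In the non-centred form
$\beta + u_s$, the species-mean of $u$ is identified against $\beta$
only through its prior, and a single-site sampler can strand a chain
far out on that ridge.  Single-cell fits therefore centre the species
slopes hierarchically ($b_s \sim N(\beta, \tau^2)$), which removes the
ridge and raises the effective sample size of $\beta$ by more than an
order of magnitude; multi-cell fits keep the shared-deviation form
(cell *contrasts* are ridge-free, and the shared deviation is the
minimal reading of "separate slopes per species").  Station intercept
SDs hug their zero boundary when the data carry no station-level
recruitment effects beyond seed density; their slow mixing is benign
for the slopes but can honestly trip the R-hat flag in short chains.  Split R-hat (each chain
halved) and effective sample sizes are attached to every fit; a fit
with any split R-hat above 1.01 is flagged non-converged but its
summaries are still reported.  Identical seeds and settings reproduce
draws exactly.

# Species filters

CNDD is estimable only for species whose data span a density gradient.
Following standard practice the model uses species that occur (as
seeds or seedlings) in at least 10 stations, vary at least 3-fold in
station-level seed density, and have at least 5 seedlings in total.
Station seed density for the fold criterion is the trap-pair mean (a
config switch allows per-trap or station-sum bases); the ratio is taken
over stations with positive density, so fewer than two positive
stations fails the criterion.  Control and water plots enter the
model as separate observations sharing the station's latent density,
in the Control cell.

# Diversity analysis

Three Hill-number indices, all in effective-species units: inverse
Simpson ($1/\sum p_i^2$), exponentiated Shannon
($e^{-\sum p_i \log p_i}$), and hypergeometric rarefied richness (2
individuals for seedling plots, 5 for seed assemblages — sparse recruit
plots cannot support larger subsamples).  Station seed assemblages pool
the two traps.  Choices where the convention is genuinely open:

* Units with no individuals get `NA`, not zero — an empty plot says
  nothing about evenness; these are dropped from the models with a
  logged count.  Single-individual units score 1 on non-rarefied
  indices.
* Rarefaction below the sample size returns `NA` rather than observed
  richness, avoiding a downward-biased imputation.
* Control and water plot values are averaged per station into a single
  Control value (they are operationally interchangeable; when only one
  exists it is used and flagged).

Recruit diversity is modelled with a Gaussian linear mixed model,
`value ~ edge_category * treatment + seed_diversity + (1 | station)`,
the station's seed diversity entering additively so treatment
contrasts are read conditional on what arrived.  Pairwise treatment
contrasts within each edge category use Wald z tests with Tukey
familywise adjustment by default (`none` available — the adjustment
convention is not fixed by common practice here), summarised as a
compact letter display computed by the insert-and-absorb algorithm.
A singular station variance triggers a warning and a plain
fixed-intercept fallback.  The light-availability variant replaces the
edge category with a continuous per-plot canopy-openness covariate.

# What the generator emulates

`generate_design()` reproduces the reference layout: 15 locations × 3
stations in each of E0 (0–5 m), E1 (20–30 m), E2 (50–60 m), plus 15
interior E3 stations (90–100 m) hosted by 5 locations — interior bands
are rarely available everywhere in fragmented landscapes.  A
`keep_stations` override subsamples the design (the reference landscape
retained 146 of the 150 planned stations; the exclusion mechanism is
not modelled, so the override is random).

`simulate_seed_rain()` draws species relative abundances from a Fisher
log-series (x = 0.995; a log-normal alternative is available), splits a
community seed rain of 600 seeds m⁻² yr⁻¹ across species, and draws
station-level latent densities log-normally with log-SD 1.0 — seed rain
is strongly spatially aggregated in wet tropical forest.  Each trap is
an independent Poisson count of the station density: the minimal
counting model, and exactly the noise structure the measurement-error
correction targets.  `simulate_recruitment()` applies the power law
with cell slopes from `b_matrix`, species slope deviations
(SD 0.2 — interspecific variation in CNDD is substantial in published
estimates), per-species baselines $a_s$ (logit-normal around 0.3), and
negative-binomial noise ($\phi = 5$).

The default `b_matrix` encodes the pattern the experiment is designed
to detect: moderate CNDD everywhere (0.85), strongest in interior
controls (E3 Control 0.60, within the range of published community
slopes), and near-absent under pesticides only at E3 (0.95).
Treatments act through $b$ only by default; an optional multiplier on
$a$ exists for sensitivity runs.

Two calibration notes, fixed at design time.  First, detecting the
CNDD–diversity link at plot scale requires fairly dense recruitment
(the defaults produce on the order of a hundred recruits per plot):
in sparse plots the evenness gain in strong-CNDD plots is cancelled by
the small-sample downward bias of diversity indices at the lower plot
totals that strong CNDD also causes.  Sparse-recruitment communities
genuinely hide this signal at the design's 15 interior stations.
Second, simulation studies of the slope estimator use log-normal
species-abundance panels rather than the log-series community: the
species filters remove the log-series' rare tail anyway, and the
filtered panel is what the model sees on real data.

What the generator does *not* emulate: spatial coordinates and
dispersal kernels, seasonality, survival beyond the single
seed-to-seedling transition, taxonomic error, and any decoupling of
recruit totals from treatment.  Passing tests therefore demonstrate
correctness of the machinery under the stated statistical structure,
not robustness to every feature of real field data.

# Numerical choices and scaled-down study sizes

Monte-Carlo calibration studies in the test suite use scaled-down
designs chosen to keep the full suite within a desktop run: null
calibration of the slope (50 datasets, 24 stations × 20 species,
single cell), recovery of $b = 0.7$ (50 datasets, 60 stations × 20
species), attenuation ordering (25 paired datasets, 45 stations × 10
species on sparse seed rain), and the diversity power check (100
replicates of the full 146-station design).  Single short chains
(600–800 retained iterations) are used per fit; posterior-mean Monte
Carlo error is small relative to the effect sizes under test.  Species
panels below ~15 species leave the cross-species slope heterogeneity
$\tau$ poorly identified and make hyper-mean intervals overconfident;
the calibration studies therefore use 20-species panels.

# Known limitations

* The moment-matched trap prior undercorrects attenuation for very
  sparse species (trap-pair means below ~2 seeds); community slopes
  estimated from such data retain a small negative bias.
* The compact-letter display depends on the chosen familywise
  adjustment; with `correction = "none"` letters separate more pairs.
* Convergence flagging uses split R-hat on monitored scalar
  parameters only; latent densities are not monitored.
* The pipeline treats canopy openness as a given covariate; no
  photo-processing is included.
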