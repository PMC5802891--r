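---
title: "Simulating cumulative harvesting and climate-change impacts on Black-backed Woodpecker habitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cumulative harvesting and climate-change impacts on Black-backed Woodpecker habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbwohab)
```

## What the package models

`bbwohab` is a desk-scale pipeline for asking how harvesting and
climate-driven changes in fire regimes and stand-scale processes combine to
reshape the habitat of the Black-backed Woodpecker (*Picoides arcticus*,
"BBWO"), an indicator species of old-growth and recently burned coniferous
boreal forest. It has three layers:

1. **A simplified cohort-based forest landscape model.** The landscape is a
   grid of 6.25-ha cells (250-m resolution), each holding a list of species
   cohorts (species, age, aboveground biomass in t/ha). The model advances
   in 5-yr steps over a 100-yr horizon (2000–2100), applying succession,
   seed dispersal, stochastic fire, spruce budworm (SBW) outbreaks and
   harvesting.
2. **A rule-based habitat classifier and productivity model.** Cell layers
   (stand age, conifer fraction, time since fire, pre-fire stand history)
   are reclassified into six habitat types; contiguous same-type cells are
   aggregated into patches; patches at least as large as the type's mean
   home range each contribute the type's mean productivity
   (fledglings/yr); totals are normalized per 100 km².
3. **A factorial sensitivity analysis.** Three drivers — harvesting,
   climate-induced fire-regime change, and climate-induced stand-scale
   change — are crossed 2×2×2 within each forcing scenario (RCP 2.6 / 4.5 /
   8.5), with paired replicate seeds. Driver importance is ranked by the
   omega-squared effect size from a three-way factorial ANOVA on total
   potential productivity at each timestep,

   $$\omega^2 = \frac{SS_{effect} - df_{effect}\, MS_{error}}{MS_{error} + SS_{tot}},$$

   and driver impact is quantified by ΔProd (and per-species ΔB), the
   percentage difference between the full model and a reduced model
   omitting one driver.

## The succession model and its assumptions

Full-fidelity forest-landscape simulators track cohort growth with
calibrated process internals that are not reproducible from published
summaries. The succession used here is a stated simplification that keeps
the properties the habitat analysis depends on — realistic age structure,
competition-limited biomass, species turnover after disturbance — without
claiming bit-compatibility with any larger model:

* **Growth.** Each cohort gains
  `timestep × maxANPP × growth_factor × (1 − B_cell / maxAGB)` t/ha per
  step (maxANPP in kg/ha/yr is converted to t). `maxAGB` is the carrying
  capacity of a species on a landtype; the growth-shape parameter (0 or 1
  in the trait table) selects between age-independent growth and growth
  that slows linearly toward longevity. Cell biomass never exceeds the
  largest applicable `maxAGB`.
* **Mortality.** Senescent biomass loss per step is
  `(age/longevity)^mortality_shape`; with shapes of 15–25 the loss is
  negligible for most of a cohort's life and steep near longevity, and a
  cohort reaching longevity dies.
* **Establishment.** A species establishes a new 5-yr cohort with
  probability SEP (its per-timestep establishment probability, the chance
  of at least one success in five annual Bernoulli trials,
  `1 − (1 − 1/t)^5`), provided it has a seed source and adequate light.
  Light adequacy is encoded as a relative-occupancy ceiling
  (`B_cell / maxAGB` at most 0.15/0.30/0.50/0.70/0.85 for shade tolerance
  1–5). Establishment is skipped where an immature cohort of the species
  already occupies the regeneration niche, which keeps cohort lists
  bounded.
* **Dispersal.** Seed arrival decays with Euclidean distance to the
  nearest mature cohort under a truncated exponential kernel whose 95%
  quantile is the species' effective dispersal distance and whose support
  ends at its maximum dispersal distance; a cell holding a mature cohort
  (or any cohort, for vegetatively regenerating species) is always its own
  source. Distances use an exact Euclidean distance transform.

## Disturbances

* **Fire.** Each fire region has an annual burn rate and mean fire size
  per climate period. Expected fire occurrence is
  `rate × region area / mean size`; the per-step fire count is Poisson
  with mean `timestep × occurrence`, sizes are lognormal (CV 1 by
  default), and each fire grows from a random ignition by stochastic
  4-neighbour accretion, stopping at its target size, the region boundary
  or the grid edge. Burned cells record their pre-fire stand age and
  composition (the burned-habitat classes are judged on these, since live
  post-fire biomass is near zero), reset time-since-fire, and lose all
  cohorts except post-fire regeneration: serotinous species re-establish
  where a mature cohort burned, resprouters where any cohort burned.
  There are no fuel or vegetation feedbacks, so long-run realized burn
  rates converge to the calibrated rates (a Monte-Carlo test asserts
  this within 3 standard errors).
* **Spruce budworm.** Outbreaks recur every 35 yr, last at most 10 yr, and
  run in every simulation as background disturbance. During active steps,
  host cohorts lose a biomass fraction per step that decreases along the
  vulnerability ranking balsam fir (0.9) > white spruce (0.7) > red spruce
  (0.5) > black spruce (0.3), halved for cohorts of 30 yr or less. The
  neighbourhood host-abundance term of richer outbreak models is omitted;
  the schedule is deterministic with a configurable phase (default: first
  outbreak in simulation year 35).
* **Harvest.** Per management area, a constant area target per step
  (0.5 %/yr of the area by default, within the 0.4–0.8 %/yr range typical
  of the region's management units). Only cells containing a cohort older
  than 60 yr are eligible; cells are drawn at random among eligible ones
  until the target or the eligible pool is exhausted (the shortfall is
  reported). Clearcutting (public land) removes all cohorts except the
  0–5-yr class; partial harvesting (private land) removes a biomass
  fraction drawn uniformly within the prescribed class (1–40% or 41–80%).

## Habitat classification and productivity

The six habitat types and their coefficients:

| type | age | years post-fire | composition | home range (ha) | fledglings/yr |
|---|---|---|---|---|---|
| old coniferous unburned | ≥80 | – | coniferous | 150 | 1.5 |
| old mixed unburned | ≥80 | – | mixed | 300 | 1.0 |
| recently burned old coniferous | ≥80 | 1–5 | coniferous | 40 | 1.4 |
| recently burned young coniferous | <80 | 1–5 | coniferous | 100 | 0.25 |
| older burned coniferous | ≥80 | 6–10 | coniferous | 200 | 0.4 |
| non-habitat | — | — | — | — | 0 |

Design choices the source tables leave open, decided here and configurable:

* "Coniferous" means conifer biomass fraction ≥ 0.75 and "mixed" means
  0.25–0.75, following common forest-inventory cover-type conventions.
* With a 5-yr timestep, "1–5 yr post-fire" is the first post-fire
  snapshot and "6–10 yr" the second; a cell burned in the current step
  (time-since-fire 0) is not yet burned habitat.
* Burned classes are judged on composition and age recorded at burn time.
* Patch contiguity is rook (4-neighbour) by default; queen (8-neighbour)
  is available. Eligibility (patch area ≥ home range) is applied after
  aggregation.
* Productivity counts *eligible patches* — one home range's worth of
  fledglings per eligible patch — following the literal productivity
  definition; `count_mode = "home_ranges"` implements the alternative
  reading (whole home ranges fitting into each patch). The home-range
  figure for recently burned *young* coniferous forest (100 ha) exceeding
  that of recently burned *old* (40 ha) is taken at face value from the
  coefficients.
* Densities are reported per 100 km² (10 000 ha) of total landscape.

## The synthetic landscape

No real inventory, satellite or climate inputs are consumed. The generator
reproduces the statistical structure the analysis relies on:

* a south-to-north conifer gradient (default dominant-conifer probability
  0.75 → 0.95), over a black-spruce-led pool (PICE.MAR 0.40, ABIE.BAL
  0.18, PINU.BAN 0.12, PICE.GLA 0.08, LARI.LAR 0.04, POPU.TRE 0.08,
  BETU.PAP 0.07, ACER.RUB 0.03);
* a negative-exponential stand-age distribution (mean 100 yr, the
  stationary age structure under a constant-rate stand-replacing fire
  cycle), truncated at species longevity;
* spatial patchiness: age and composition are driven by spatially
  correlated uniform fields (smoothed Gaussian noise, rank-transformed),
  so old coniferous stands form contiguous patches as real landscapes do,
  while each cell's marginal distribution stays exactly the configured
  one;
* mixed stands: 35% of cells carry a secondary cohort of the opposite
  type at 10–50% of the dominant biomass;
* zonation into horizontal bands: 2 fire regions (burn rate 0.2 → 1 %/yr
  and mean fire size 100 → 500 ha, south to north), 3 management areas
  with the northernmost 12.7% of rows private land (partial harvesting)
  and the rest public (clearcutting);
* recent fire scars: two historic fire timesteps are applied at
  initialization so the year-2000 landscape carries 5- and 10-yr-old
  burns, as a landscape with an ongoing fire regime must.

Climate trends are configuration, not science: under an RCP scenario,
stand-scale inputs (SEP, maxANPP, maxAGB) are multiplied by
`1 ± strength × ramp(period)` — declining for conifers, rising for
deciduous species — with strength 0.15/0.30/0.50 for RCP 2.6/4.5/8.5 and a
ramp of 0, 1/3, 2/3, 1 over the periods 2000–2010, 2011–2040, 2041–2070,
2071–2100. Fire burn rates scale by `1 + strength × ramp` with strength
0.5/1.5/3.0, so the worst-case late-century fire cycle shortens roughly
four-fold (toward the ~30-yr fire returns projected for severe forcing in
this region). Only the sign and ordering structure of these trends is
asserted by tests; the magnitudes are defaults to be overridden from the
YAML configuration.

What the generator does **not** emulate: real spatial covariance between
soils, climate and composition (landtypes are random labels, collapsed to
5 classes); topographic or hydrographic constraints on fire spread;
non-forest inclusions. Passing tests therefore show the pipeline's logic
and calibration are correct under the stated statistical structure, not
that its absolute outputs match any particular real landscape — regional
magnitudes (e.g., fledgling densities) scale with landscape size and patch
structure and are not comparable to values from an 11.3-Mha study area.

## Experiment design and statistics

`run_factorial()` crosses the three driver toggles 2×2×2 per scenario;
replicate *r* shares its initial landscape and master seed across all
toggle combinations (paired design). Each stochastic process (fire,
harvest, establishment, SBW) draws from its own per-step seed stream
derived from the master seed, so switching one process off does not
perturb another's draws; an RCP run with all climate toggles off is
bit-identical to the corresponding baseline run.

The ANOVA response is total potential productivity, one value per run,
decomposed separately per scenario and timestep (balanced type-I sums of
squares; with a balanced design the decomposition is order-invariant and
matches a mean-based recomputation to 10⁻¹⁰ in tests). Omega-squared may
be negative when an effect's sum of squares falls below its error
expectation; values are reported as computed, not clamped. Interaction
effects are computed but only the three main effects are reported by
default, and interaction sums of squares are kept separate from the error
term. ΔProd uses the reduced model as denominator, so a negative value
means the driver lowers productivity; it is flagged undefined when the
reduced-model mean is zero (a real possibility when habitat collapses).

## Numerical choices and degenerate inputs

* Ages are multiples of the timestep; "older than 60" and "≥ 80" rules are
  applied to the stepped ages directly.
* An empty cell has stand age 0 and conifer fraction 0 by convention.
* A constant ANOVA response (zero total variance) raises an explicit
  degenerate-data error rather than returning 0/0.
* Cohorts whose biomass falls below 10⁻⁹ t/ha are removed.
* Lognormal fire sizes are floored at one cell; a fire that runs out of
  unburned same-region neighbours stops short of its target, which makes
  realized burn rates undershoot very slightly at extreme rates (the
  calibration test bounds this at normal rates).
* All scalar layers round-trip through ESRI ASCII grids bit-exactly
  (full `%.17g` precision; NODATA −9999).

## Problem sizes

Tests and the acceptance script run at desk scale, chosen once: a 100×100
grid (62 500 ha) for calibration and directional checks, 3–5 paired
replicates, and a 3-replicate × 8-combination factorial per scenario.
The full study design (5 replicates × 8 combinations × 3 scenarios = 120
runs) is available through `run_factorial()` defaults.

## Known limitations

* No vegetation–fire feedbacks, no CO₂ fertilization, no climate effects
  on SBW dynamics — deliberate omissions of the underlying design too.
* No demographic or population-viability modelling: potential productivity
  is a habitat-based proxy, not a population projection.
* The succession equations are a stated simplification; absolute biomass
  trajectories should be read as qualitative.
* Habitat-type coefficients (home ranges, productivities) are treated as
  exact constants; their field uncertainty is not propagated.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config()
st <- generate_initial_landscape(cfg, seed = 1)
sim <- run_simulation(st, "rcp85", seed = 1, config = cfg)
ps <- productivity_series(sim, cfg)
subset(as.data.frame(ps), type == "TOTAL" & year %in% c(2000, 2050, 2100))
```

The same pipeline drives `scripts/acceptance.R`, which reruns the
cumulative and factorial experiments from scratch and writes the headline
quantities as JSON.
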