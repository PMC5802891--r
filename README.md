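# bbwohab

Cumulative impacts of harvesting and climate change on Black-backed
Woodpecker habitat in boreal forest landscapes — a desk-scale, fully
synthetic re-implementation of the analysis pipeline.

## The problem

The Black-backed Woodpecker (*Picoides arcticus*, BBWO) breeds in
old-growth coniferous forest and in recently burned conifer stands, and is
widely used as an indicator of deadwood and old-growth boreal
biodiversity. Its habitat supply is squeezed from three directions at
once: harvesting removes old coniferous stands directly; a warming climate
intensifies the fire regime, lowering mean stand age and promoting
deciduous regrowth; and climate change alters stand-scale processes
(establishment, growth, carrying capacity) species by species. This
package lets you simulate those drivers together and apart on a synthetic
boreal landscape and rank their importance for BBWO habitat productivity.

It is aimed at landscape ecologists and quantitative wildlife biologists
who want a transparent, testable, small-scale version of the
forest-landscape-model → habitat-classification → factorial-sensitivity
workflow — not a calibrated regional forecasting tool.

## The model in brief

* **Forest landscape model**: a grid of 6.25-ha cells holding species
  cohorts (age, aboveground biomass), advanced in 5-yr steps over
  2000–2100 with competition-limited growth, a distance-decay seed
  dispersal kernel, stochastic fires (Poisson counts, lognormal sizes,
  neighbour-accretion spread), spruce budworm outbreaks every 35 yr, and
  constant-area harvesting restricted to stands with cohorts older than
  60 yr. Climate-sensitive parameters switch in 2010, 2040 and 2070 under
  RCP 2.6/4.5/8.5 forcing.
* **Habitat model**: cells are classified into six habitat types (old
  coniferous/mixed unburned; recently burned old/young coniferous; older
  burned coniferous; non-habitat), contiguous same-type cells are
  aggregated into patches, and each patch at least as large as its type's
  mean home range contributes the type's mean productivity
  (fledglings/yr). Totals are reported per 100 km².
* **Sensitivity analysis**: a 2×2×2 factorial over harvest, fire-climate
  and stand-climate toggles with paired seeds; per timestep, driver
  importance by the omega-squared effect size

  ω² = (SS_effect − df_effect · MS_error) / (MS_error + SS_tot)

  from a three-way factorial ANOVA on total potential productivity, and
  driver impact by ΔProd (and per-species ΔB), the percentage difference
  between the full model and a reduced model omitting that driver.

See `vignettes/methods.Rmd` for the full account of the model, its
assumptions, parameter defaults and limitations.

## A worked example

```r
library(bbwohab)
cfg <- default_config()                       # 100x100 cells, 2000-2100
st  <- generate_initial_landscape(cfg, seed = 1)
st
#> <landscape_state> year 2000, 100 x 100 cells
#>   12898 cohorts, mean stand age 60.2 yr, mean AGB 43.5 t/ha
#>   5 landtypes, 2 fire regions, 3 management areas

hm <- classify_habitat(st, cfg)
compute_productivity(aggregate_patches(hm, 4, cfg$habitat$coefficients))
#> <productivity_report> year 2000
#>                    type eligible_patches productivity density contribution
#>      OLD_CONIF_UNBURNED               16        24.00   3.840  0.921305182
#>      OLD_MIXED_UNBURNED                0         0.00   0.000  0.000000000
#>    BURNED_OLD_CONIF_1_5                1         1.40   0.224  0.053742802
#>  BURNED_YOUNG_CONIF_1_5                1         0.25   0.040  0.009596929
#>   BURNED_OLD_CONIF_6_10                1         0.40   0.064  0.015355086
#> total 26.05 fledglings/yr (4.17 per 100 km2)

sim <- run_simulation(st, "rcp85", seed = 1, config = cfg)
ps  <- productivity_series(sim, cfg)
subset(as.data.frame(ps), type == "TOTAL" & year %in% c(2000, 2030, 2060, 2100))
#>  year  type eligible_patches productivity density contribution
#>  2000 TOTAL               19        26.05   4.168            1
#>  2030 TOTAL                2         3.00   0.480            1
#>  2060 TOTAL                0         0.00   0.000            0
#>  2100 TOTAL                0         0.00   0.000            0
```

Reading the numbers: at year 2000 the synthetic landscape supports 26
potential fledglings per year (4.2 per 100 km²), over 92% of them from
old coniferous unburned patches. Under the worst-case forcing scenario
with harvesting active, cumulative disturbance erodes the eligible patch
base until habitat productivity collapses entirely — on this 62,500-ha
landscape, well before the end of the century. Direction and mechanism
mirror the large-landscape finding (strong declines, harvesting a dominant
driver); absolute magnitudes are desk-scale and do not transfer.

The factorial experiment and statistics:

```r
fact <- run_factorial(cfg, scenarios = "rcp85", replicates = 3, seed_base = 2000)
sens <- sensitivity_analysis(fact)
subset(as.data.frame(sens$table), year == 2030)
#>   scenario year  driver      omega2 delta_prod
#>      rcp85 2030 harvest 0.760186599  -76.88623
#>      rcp85 2030    fire 0.002993003  -21.86235
#>      rcp85 2030   stand 0.125360173  -60.81218
```

A command-line wrapper around the same functions is installed at
`inst/scripts/bbwohab` (subcommands `generate`, `simulate`, `classify`,
`productivity`, `experiment`, `stats`).

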