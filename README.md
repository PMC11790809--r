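# microbuffer

Forest canopies buffer the understory against temperature extremes:
below a dense canopy, hot summer days are cooler and cold nights milder
than the free-air ("macroclimate") weather that landscape simulators
normally use to drive every process. `microbuffer` brings that buffering
into simulation workflows. It is aimed at forest-landscape and
ecosystem modellers who want to know how much the macroclimate shortcut
distorts temperature-sensitive understory processes — decomposition,
bark beetle development, tree regeneration — and in which direction.

## What it computes

**Temperature offsets.** For every 10 m cell, two linear fixed-effect
models predict the average daily minimum and maximum temperature offset
(microclimate − macroclimate, °C):

    ΔT = β₀ + β_T·T̄_macro + β_L·LAI + β_N·northness + β_S·STol + β_P·TPI

with T̄_macro the monthly mean of daily minima or maxima, LAI the
overstory leaf area index, northness = cos(aspect), STol the
basal-area-weighted shade tolerance (1–5) and TPI the topographic
position index (500 m neighborhood). Coefficients ship at published
4-decimal precision; predictors are truncated to the fitting ranges; the
mean offset is the exact min/max midpoint. Offsets are updated monthly,
averaged over stockable 10 m cells to 100 m climate cells, and added to
the daily macroclimate series.

**Coupled processes.** The daily microclimate series drive
first-order-decay carbon pools (Lloyd–Taylor temperature modifier on
mean temperature), a degree-day phenology for *Ips typographus* (bark
temperature from daily maxima, 557 °C·d per generation, lethal winter
minimum from daily minima), and species-specific establishment filters
(minimum winter temperature, chilling days, growing-degree-day window,
post-budburst frost).

**Paired experiment.** `run_experiment()` runs macro- and
microclimate-driven simulations on identical climate-year and wind
sequences (shared RNG streams; with zeroed coefficients the pair is
bit-identical) over a synthetic mountain landscape, and reports
indicators at local (dense stands, LAI > 4), meso (disturbance patches,
elevation bands) and landscape scales.

## Worked example

```r
library(microbuffer)

# a hot month (T̄_max = 25 °C) under a dense canopy (LAI 6, STol 4), flat terrain
p <- predictor_vector(t_macro = 25, lai = 6, northness = 0, stol = 4,
                      tpi = 0, kind = "max")
predict_offset(truncate_predictors(p), offset_coefficients("max"))
#> [1] -4.4545

# paired experiment on the default 50 x 50 synthetic landscape
cfg <- simulation_config(years = 10, replicates = 2, seed = 1)
x   <- run_experiment(cfg)
li  <- local_indicators(x)         # dense-stand (LAI > 4) annual means
aggregate(li[, c("rh", "generations", "regen_density")],
          by = list(mode = li$mode), FUN = mean)
#>   mode    rh generations regen_density
#>  macro 3.612      1.9639          3654
#>  micro 3.223      0.9815          3243
aggregate(nep ~ mode, data = x$indicators, FUN = mean)
#>   mode   nep
#>  macro 2.671
#>  micro 2.995
```

Reading the numbers: under dense canopies the buffered (micro) runs
respire less carbon (3.22 vs 3.61 Mg C ha⁻¹ yr⁻¹ — cooler summers slow
decay), complete fewer beetle generations (0.98 vs 1.96 — cooler bark),
regenerate slightly less (cooler means push warm-preferring species
below their degree-day minimum), and the landscape NEP proxy is higher
(2.99 vs 2.67 Mg C ha⁻¹ yr⁻¹) because production is unchanged while
respiration falls. These are directions on a synthetic landscape, not
calibrated magnitudes.

A command-line front end wrapping the same functions lives at
`inst/cli/microbuffer` (`synth`, `offsets`, `simulate`, `report`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation — the
paired macro/micro experiment on the default synthetic landscape — from
an installed copy of the package and writes its report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/offset-model.R` — offset coefficients, predictor vectors, truncation, prediction
* `R/terrain-canopy.R` — northness, TPI, weighted shade tolerance, 100 m aggregation
* `R/microclimate-series.R` — monthly averages, monthly offset fields, daily application
* `R/decomposition.R`, `R/beetle.R`, `R/establishment.R` — the three process models
* `R/experiment.R` — annual loop, paired runs, multi-scale indicators
* `R/fixtures.R`, `R/species.R` — synthetic terrain/weather/stand generators
* `vignettes/microclimate-buffering.Rmd` — model description, assumptions, limitations
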