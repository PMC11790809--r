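---
title: "Microclimate temperature buffering and its effects on understory processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microclimate temperature buffering and its effects on understory processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbuffer)
```

## The problem

Forest canopies buffer the climate of the understory: hot afternoons are
cooler and cold nights are milder below a closed canopy than in the open.
Landscape simulators usually drive every process with free-air
("macroclimate") weather measured or interpolated at 2 m height in open
terrain, which systematically misrepresents the thermal environment that
decomposers, bark beetles and tree seedlings actually experience.
`microbuffer` implements a dynamic correction: empirically fitted linear
models predict the *offset* (below-canopy minus free-air temperature,
°C) of average daily minimum and maximum temperature from canopy and
terrain, and the resulting daily microclimate series drive three
temperature-sensitive understory processes — decomposition of dead
organic matter, degree-day development and overwintering of the European
spruce bark beetle (*Ips typographus*), and threshold-based tree
establishment. A paired simulation experiment quantifies what switching
those processes from macro- to microclimate changes, from stand to
landscape scale.

## The offset model

For each 10 m cell the minimum- and maximum-offset models are linear
fixed-effect predictors

$$\Delta T = \beta_0 + \beta_T \bar{T}_{\mathrm{macro}} +
  \beta_L \, \mathrm{LAI} + \beta_N \, \mathrm{northness} +
  \beta_S \, \mathrm{STol} + \beta_P \, \mathrm{TPI},$$

where $\bar{T}_{\mathrm{macro}}$ is the monthly average of daily minimum
(minimum model) or maximum (maximum model) macroclimate temperature,
LAI the overstory leaf area index (m² m⁻²), northness the cosine of
aspect, STol the basal-area-weighted shade tolerance (1–5) and TPI the
topographic position index (m, elevation minus the mean within 500 m).
The coefficients ship at their published 4-decimal precision and are not
refit here. Predictions are population-level: the original fit included
a random study intercept whose standard deviation is retained as
metadata (`study_random_sd`) but set to zero for prediction — the model
is applied to new landscapes where no study level exists.

The sign structure carries the ecology: maximum offsets fall with LAI
and macroclimate temperature (dense canopies cool hot days, more so the
hotter it is), while minimum offsets rise with LAI and TPI (canopies and
ridges keep cold nights milder). The mean-temperature offset is defined
as the exact midpoint of the minimum and maximum offsets.

```{r}
co <- offset_coefficients("max")
p  <- predictor_vector(t_macro = 25, lai = 6, northness = 0, stol = 4,
                       tpi = 0, kind = "max")
predict_offset(p, co)   # a hot month under a dense canopy: about -4.5 °C
```

### Truncation bounds

Predictors are clamped to the range covered by the fitting data so the
linear models never extrapolate. The exact fitting ranges are not
published; the shipped defaults — `t_macro` ∈ [−15, 30] °C, LAI ∈ [0, 8],
northness ∈ [−1, 1], STol ∈ [1, 5], TPI ∈ [−150, 150] m — approximate
the reported predictor densities and are fully configurable
(`truncation_bounds()`, or the `offset_model$bounds` section of the
configuration). Truncation is applied to the monthly-averaged predictor,
i.e. after averaging, which is the natural reading of a model fitted on
monthly averages.

## From cells to daily series

Offsets are recomputed **monthly** for every 10 m cell from the current
canopy state (LAI and STol are refreshed annually by the simulation),
averaged at **100 m** resolution across *stockable* cells only (rock,
water and alpine cells are excluded; a 100 m cell with no stockable
cells gets offsets (0, 0, 0) — outside forest the open-air macroclimate
applies), and then **added to the daily** macroclimate series of the
month: the offset varies monthly, the resulting microclimate daily.

Three numerical details matter:

* *Ordering repair.* Because minimum offsets are typically positive and
  maximum offsets negative, an extreme combination can invert a day's
  range (`micro_tmax < micro_tmin`). Such days are collapsed to the
  midpoint of the two values and counted (`attr(x, "repaired")`); with
  the shipped coefficients and realistic weather this is rare.
* *Mean temperature.* `micro_tmean` is produced by adding the mean
  offset (the min/max midpoint) to macroclimate `tmean`, not by
  recomputing from the adjusted extremes.
* *Round trip.* Subtracting the macro from the micro series recovers the
  monthly offsets up to IEEE double rounding; the suite asserts recovery
  at 10⁻¹² absolute tolerance, since `(x + o) − x` is not bit-exact for
  general doubles.

The empirical models were fitted to snow-free sensor data; the simulator
applies offsets year-round. Users in deep-snowpack regions should treat
winter offsets as an approximation.

## Process couplings

**Decomposition.** Snags, downed wood, litter and soil organic matter
decay by first-order kinetics, `loss = C (1 − e^{−k \cdot m})`, with a
climate modifier `m` that multiplies the reference rates. The
temperature response is a Lloyd–Taylor-form exponential normalized to 1
at 10 °C (`e0` = 308.56 K, `t0` = −46.02 °C), averaged over the year's
daily mean temperatures; an optional saturating logistic in annual
precipitation/PET adds a moisture response (disabled by default — the
microclimate switch affects temperature only, so the water balance stays
macro-driven). The humified fraction of each non-soil pool's loss
(defaults 0.30/0.30/0.35) transfers to soil; the rest is respired; soil
losses are respired entirely. Mass balance is exact by construction and
asserted at 10⁻⁹ relative tolerance. The reference rates
(0.04/0.08/0.30/0.02 yr⁻¹) and humification fractions are plausible
temperate-forest values, clearly *not* fitted constants; both the rates
and the functional forms are configurable so users can match a host
model exactly.

**Bark beetle phenology.** Bark temperature is a linear map of daily
maximum air temperature (identity by default); development accumulates
degree-days between 8.3 and 38.9 °C of bark temperature; one generation
needs 557 °C·d; swarming starts at the first day from April 1 (day 91)
with a maximum of at least 16.5 °C; development ends at a fixed diapause
day (258). These constants follow the PHENIPS family of thermal-sum
models and are configurable; none is printed in the source study.
Completed generations are reported fractionally
(`dd_accumulated / 557`); sister broods are *not* counted — the
published fractional indicator values are consistent with either
convention, so the simpler one was chosen. Overwintering is a binary
rule: any winter day strictly below −22 °C kills the brood. Diapause by
fixed calendar day (not photoperiod) avoids a latitude input.

**Tree establishment.** Species-specific filters act as hard gates:
annual minimum temperature below the species' lethal threshold, chilling
days (dormant-season days with mean temperature in [−5, 5] °C,
inclusive; window Nov 1–Mar 31) below the requirement, or annual growing
degree days outside [gdd_min, gdd_max] each force probability 0.
Otherwise the probability is `p_max · frost_resistance^frost_days`,
where frost days are counted between budburst (first day cumulative GDD
reaches the species threshold) and the end of the growing season
(day 273). Bounding the frost window at the growing season is a
deliberate choice: counting ordinary late-autumn frosts against dormant
seedlings would zero establishment everywhere in a mountain climate.
The soil-water modifier of the host model is omitted (constant 1), since
the microclimate switch affects only temperature filters. Establishment
is a seeded Bernoulli trial per cell, species and year adding a fixed
number of stems to a regeneration cohort ledger; seed and light supply
are assumed non-limiting.

## The synthetic landscape

The fixture generator produces the *stated world* the experiment runs
in — a temperate mountain landscape analog:

* **Terrain**: a smoothed Gaussian random field plus a cross-valley ramp
  scaled to 600 m of relief above a 700 m base, at 10 m resolution;
  aspect/northness from the elevation gradients, TPI from the 500 m
  boundary-clipped disk mean; treeline at 1250 m and 5 % random rock
  cells define the stockable mask.
* **Weather**: daily means follow a seasonal cosine (half-amplitude 9 °C,
  peak July 20) around a mean annual temperature of 7 °C at the base
  elevation — the warm end of the 7 to −2 °C elevational gradient the
  study landscape spans — lapsed at 0.65 °C per 100 m, with AR(1)
  anomalies (coefficient 0.7, innovation SD 2 °C). Minima and maxima sit
  half the 8 °C diurnal range below/above the mean, so day ordering
  holds by construction. Precipitation is gamma-distributed at 4 mm
  day⁻¹ (≈1500 mm yr⁻¹).
* **Stands**: elevation-zoned types — dense shade-tolerant
  broadleaf–conifer mixtures below 950 m (LAI ≈ 5.5), spruce-dominated
  montane stands to 1100 m (LAI ≈ 5), sparser spruce–stone pine–larch
  subalpine stands below the treeline (LAI ≈ 3.5) — with per-cell LAI
  noise, so dense (LAI > 4) cells exist in every band.
* **Species**: six invented species (`*_syn`) covering the functional
  roles warm-preferring, cold-preferring and temperature-indifferent.
  Their GDD windows are positioned once along the landscape's GDD
  gradient (≈1430 °C·d at 700 m to ≈700 °C·d at 1300 m) so that warm
  species are GDD-limited at their upper edge and cold species excluded
  from the warmest sites. They are fixtures, not reproductions of any
  calibrated parameter set.

What the generator does **not** emulate: real DEMs, resampled station
weather, snow dynamics, light competition, seed dispersal, and any
calibrated vegetation dynamics. The simulation engine's canopy layer is
an acknowledged toy — logistic LAI regrowth, wind as random circular
patches removing 80 % of LAI and live carbon, and beetle-caused
mortality as a seeded Bernoulli event whose probability rises
logistically in completed generations × overwintering survival × spruce
share. A green direction-of-effect test therefore establishes that the
*microclimate coupling* shifts decomposition, beetle development and
regeneration in the documented directions under controlled conditions —
it does not reproduce any published effect magnitude, which would
require the full host model and a real landscape initialization.

## The paired experiment

Each replicate draws one climate-year sequence and one wind-event
sequence, then runs **both** modes (macro, micro) on them; the modes
differ only in the temperature series fed to the three processes.
Establishment and beetle-mortality uniforms are also shared across modes
through named, replicate-specific RNG streams, which yields a strong
contract: with both offset models zeroed, paired trajectories are
bit-identical. The per-process mode flags generalize the all-on/all-off
published design; `run_experiment()` runs the preset pair.

Annual order of operations: offsets → daily series → decomposition →
beetle phenology → establishment → wind → beetle mortality → regrowth
and canopy refresh. The annual carbon ledger
(ΔC = NPP − R_h, with disturbance transfers internal) is asserted at
10⁻⁶ relative tolerance every simulated year.

Analysis helpers mirror the study's three scales: `local_indicators()`
(annual means over dense, LAI > 4 stands), `disturbance_patch_deltas()`
(post- minus pre-disturbance means over 8-neighbor patches accumulated
in 10-year windows, post window 5–15 years after disturbance, truncated
patches dropped and counted) and `elevation_band_summary()` (relative
micro-vs-macro regeneration differences in 100 m bands centered on the
stems-weighted 5th, 50th and 95th percentiles of each species'
macroclimate regeneration elevation distribution; bands centered below
the landscape minimum are flagged excluded).

## Known limitations

* Offset coefficients are taken as printed; no uncertainty propagation,
  standard errors or prediction intervals.
* Year-round offset application ignores the snow-season exclusion of the
  underlying fit.
* The engine's vegetation, wind and outbreak dynamics are deliberately
  minimal; magnitudes are not comparable to a calibrated landscape
  model, only directions and mechanisms are.
* Grids are plain matrices with ESRI ASCII text I/O; georeferencing is
  limited to origin/cell-size metadata.
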