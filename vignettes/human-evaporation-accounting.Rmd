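---
title: "Accounting for human-body evaporation at city scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for human-body evaporation at city scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodyevap)
```

## The problem

Urban water budgets track rainfall, runoff, piped supply and the
evapotranspiration of soil and vegetation, but the people themselves are a
vapour source too: a resting adult loses tens of grams of water per hour
through skin diffusion and respiration, and far more when active or warmly
dressed. Summed over a megacity's population and a full year this flux is
of the same order as the annual water use of a small European city.
`bodyevap` makes that accounting reproducible: a per-person
thermophysiological model, a daily schedule, seasonal indoor-climate rules,
and population-raster upscaling, with every constant and interpretation
choice explicit and testable.

## The per-person model

The sweating rate is the piecewise (PW) regression
$m_{sw} = 147 + 1.527\,E_{req} - 0.87\,E_{max}$ in g·m⁻²·h⁻¹, driven by two
heat-balance quantities in W/m²:

* $E_{req} = M - W - C - R - Q_{res}$, the evaporative loss required to
  close the steady-state balance. $M$ is the metabolic rate (tabulated per
  activity; an indirect-calorimetry entry point
  `metabolic_rate_from_gas()` is provided, with the oxygen volume divided
  by body surface area as the W/m² units require). Mechanical efficiency is
  taken as zero by default for all three activity classes — everyday
  activities perform essentially no external work — but can be set up to
  0.10.
* $E_{max} = (P_{sk} - P_a)\,/\,(I_{e,cl} + 1/(f_{cl} h_e))$, the ceiling
  imposed by the skin-to-air vapour-pressure gradient across the clothing
  and boundary-layer evaporative resistances in series.

Dry losses use a linearised surface model: $C = f_{cl} h_c (t_{cl} - t_a)$
and $R = f_r h_r (t_{cl} - t_r)$ with $h_r = 4.7$ W/(m²·K), the standard
linearised radiation coefficient for indoor surfaces, configurable. The
mean radiant temperature defaults to the air temperature (indoor
assumption); both are caller inputs. Respiratory loss is
$Q_{res} = 0.0173 M (5.867 - P_a) + 0.0014 M (34 - t_a)$. Mean skin
temperature follows the linear regression $T_{sk} = 0.215\,t_a + 26.6$, and
skin vapour pressure is the saturation value at $T_{sk}$.

### Unit and grouping interpretations

Three conventions in the parameter set are genuinely ambiguous, so each is
an explicit flag on `model_constants()` with a documented default:

* **Saturation-curve unit** (`vp_unit`). The Antoine constants (18.6686,
  4030.183, 235) describe a curve native in mmHg — evaluated at 100 °C it
  gives 763.7 mmHg, i.e. one atmosphere to within 2 % — so the package
  converts ×0.133322 to kPa before use in the respiration and $E_{max}$
  terms, which are written for kPa. The native unit is selectable.
* **Clothing thermal-resistance unit** (`icl_unit`). The tabulated seasonal
  values 0.36–1.20 are physically plausible as clo (a light summer to a
  heavy winter ensemble) and implausible as m²·K/W (1.20 m²·K/W ≈ 7.7 clo,
  arctic gear). Default `"clo"`, converted at 1 clo = 0.155 m²·K/W;
  `"si"` reads them as printed.
* **Evaporative-resistance grouping** (`ie_grouping`). The standard
  clothing-science relation is $I_{e,cl} = I_{cl}/(i_{cl}\,\mathrm{LR})$
  (default `"quotient"`); the product reading $I_{cl} i_{cl}/\mathrm{LR}$
  is selectable. The quotient reading is also the one that reproduces the
  expected seasonal behaviour (heavier, less permeable ensembles suppress
  evaporative capacity and raise sweating).

Every run logs the flags in effect.

### The clothing-surface temperature

$t_{cl}$ is not an input: it is solved from the steady conduction balance
$(T_{sk} - t_{cl})/I_{cl} = C + R$. The residual is strictly monotone in
$t_{cl}$, so the root is unique; `clothing_surface_temperature()` brackets
it inside $[\min(t_a, t_r, T_{sk}) - 1, \max(t_a, t_r, T_{sk}) + 1]$ and
uses `stats::uniroot` at machine tolerance (residual required below
10⁻⁶ W/m², at most 200 iterations; non-convergence is an error, not a
warning). The test suite checks it against an independent bisection oracle
to 10⁻⁴ °C over 100 randomised states. The bare-skin limit
$I_{cl} \to 0$ returns $T_{sk}$ directly. A negative raw $m_{sw}$ is
clamped to zero with a `clamped` flag — mass flux cannot be negative, and
we prefer an explicit flag to an artificial floor.

## Day, season, year

The default day is 8 h sleep, 14 h light work and 2 h moderate work, all
indoors; hours must sum to 24 exactly. Seasons are meteorological
(Mar–May, Jun–Aug, Sep–Nov, and Jan–Feb plus December of the same calendar
year), so day counts always total 365/366. Indoor temperature follows a
per-season rule: winter uses a fixed 22 °C setpoint (district heating keeps
apartments warm regardless of the outdoor cold); the other seasons follow
the outdoor daily mean clipped to [16, 30] °C. Indoor relative humidity
defaults to 0.40/0.60/0.50/0.30 for spring/summer/autumn/winter — a humid
monsoon summer and a very dry heated winter. All of these are
configuration, not constants.

The schedule-sensitivity analysis perturbs sleep over 6–10 h and moderate
activity over 0.5–2 h (the ranges reported by national sleep and fitness
surveys), light work taking the remainder. Because the annual total is
exactly linear in the schedule hours, the implementation computes one
litres-per-scheduled-hour integral per activity over the year and evaluates
the 9×7 grid (0.5 h and 0.25 h steps, corners and baseline included) from
those three numbers; the tests verify the decomposition equals the direct
day-by-day evaluation and that the extremes sit at the predicted corners
(most-sleep/least-exercise minimises, least-sleep/most-exercise maximises,
since sleeping produces less vapour than light work and moderate work more).
The returned range therefore always brackets zero.

## Upscaling

Per-person rates are spatially uniform within a run — the model describes
one representative person, so spatial structure comes entirely from the
population raster (persons per cell, row-major, north-up; nodata cells are
treated as zero population with a warning). District volumes are
population × litres / 1000 m³; the intensity raster converts each cell's
annual volume to mm/year over the cell area (1 mm ≡ 10⁻³ m³/m²); city
averages in mm always take the reference area as an explicit argument,
because an areal average is meaningless without its denominator. The tests
assert mass conservation across all aggregation routes (cells → districts →
city, cells → city, intensity → volume) to 10⁻⁶ relative, exact linearity
in population, and zero intensity exactly where population is zero.

## Equivalence accounting

The comparison module converts an annual volume into the field's customary
equivalents: the evapotranspiration of a reference broad-leaved plantation
(15 cm diameter at breast height, 800 plants/hm², 1667.6 kg per plant per
year → 133,408 m³/km²/year, with water at 1000 kg/m³), the equivalent
forest area, green-space parity on a land-use grid (green space = tree
cover + grassland codes by default, configurable), the fraction of natural
urban evapotranspiration, and multiples of the annual water use of four
reference European cities. Each reported figure keeps its raw value
alongside a rounded one with explicit conventions: two decimals for
percentages, one decimal for km², nearest hundred for the
population-density equivalent.

## The synthetic city and weather

The generators exist so that every pipeline stage is exercised without
downloads, and they define the package's reference study conditions:

* `generate_city()` — a core-peaked density surface
  $w \propto e^{-d/\lambda}$ with lognormal cell noise, integerised by the
  largest-remainder rule so the raster sums to the requested population
  *exactly*; Voronoi districts around seeded cells (ties broken by cell
  index); a finer land-use grid whose green-cell count matches the
  requested fraction exactly. Defaults describe a 21.89-million-person,
  16-district city on a ~16,400 km² extent.
* `generate_weather()` — per season, mean + full-period sinusoid + Gaussian
  noise; the sinusoid averages to zero over the season, so with zero noise
  the seasonal sample mean equals the specification exactly. Defaults are a
  northern temperate monsoon climate (seasonal means 13.5/26/13/−1.5 °C,
  day-to-day noise 2 °C).

Both draw from a single seed and restore the caller's RNG state. What they
do **not** emulate: real geography, commuting, within-day temperature
cycles, person-level heterogeneity, or humidity time series — so passing
tests demonstrate correct accounting and model behaviour, not agreement
with any real city's microdata. Test problem sizes are deliberately small
(64×64 fixture city, 32×32 pipeline runs, one synthetic year); the model
chain is cheap enough that these sizes already exercise every code path.

## Known limitations of the published parameter set

The package implements the parameter set faithfully, and the test suite
reports honestly where the resulting calibration disagrees with classical
physiology. Three findings, all computed by the tests and the acceptance
script:

* **Resting rates are high.** Sweeping the sleep activity over 20–34 °C
  ambient (radiant = air, rh 0.5) across the four seasonal ensembles gives
  whole-body rates from 59 g/h (summer clothing, 20 °C) to 273 g/h (winter
  clothing, 34 °C), against the 20–50 g/h range classical insensible-
  perspiration studies report for sleeping adults. The width is structural:
  between 20 and 34 °C the dry losses collapse, raising $E_{req}$ by
  30–42 W/m² (a 47–64 g·m⁻²·h⁻¹ swing through the 1.527 coefficient), while
  the vapour-pressure physics lets $E_{max}$ move only a few W/m² in
  compensation. No positive clothing parameters can keep the band 30 g/h
  wide; no unit reinterpretation we examined changes this.
* **Daily totals are high.** At the package's reference mid-range indoor
  state (23 °C, rh 0.45, light summer ensemble, default schedule, 1.8 m²
  adult) the modelled daily total is 1.93 L, above the 1.25–1.71 L band of
  experimental daily averages. The regression intercept alone (147
  g·m⁻²·h⁻¹ ≈ 265 g/h whole-body) forces a high resting baseline unless
  $E_{max}$ is large.
* **Winter ranks first, not summer.** Under the default seasonal rules the
  per-person ordering is winter > autumn ≈ summer > spring, because heavy
  winter ensembles dominate through the clothing evaporative resistance,
  and dry winter air *lowers* predicted sweating in this model (it raises
  $E_{max}$) — the opposite sign to the intuition that dry air promotes
  evaporation. Reported seasonal orderings for heated monsoon-climate
  megacities place summer first; reproducing that here would require
  summer indoor temperatures near 29–30 °C.

These are properties of the model-plus-parameters, not implementation
artefacts: every closed-form component is verified against independent
single-expression oracles at machine precision, and the solver against
bisection. Users calibrating to a specific city should treat the clothing
evaporative parameters ($i_{cl}$, and the `icl_unit` flag) and the seasonal
humidity/indoor rules as the sensitive knobs.

## Other non-goals

Transient thermoregulation, multi-segment body models, sweat dripping
versus evaporated fraction, acclimatisation, outdoor exposure and
commuting microclimates, dasymetric population modelling, and coordinate
reprojection are all out of scope.
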