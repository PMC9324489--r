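# bodyevap

Humans evaporate water continuously — through skin diffusion and breathing
at rest ("insensible perspiration") and through active sweating when
radiative and convective losses can no longer dissipate metabolic heat. In a
megacity, tens of millions of people doing this around the clock constitute
a water-vapour flux that urban water-balance ("dualistic" natural–social
water cycle) studies usually ignore. `bodyevap` quantifies that flux: it
models per-person evaporation with a steady-state human heat balance feeding
a sweat-prediction regression, integrates it over a daily activity schedule
and a seasonal weather series, upscales it over a population-density raster
to district and city totals, and expresses the result in the units water
managers use — cubic metres, mm/year of evaporation intensity, equivalent
forest area, and multiples of municipal water use.

## The model

The core is the piecewise (PW) sweat-prediction equation

```
m_sw = 147 + 1.527 E_req − 0.87 E_max      [g m⁻² h⁻¹]
```

where `E_req` is the evaporative heat loss required to close the body's heat
balance and `E_max` the maximal evaporative capacity of the environment
(both W/m²):

```
E_req = M − W − C − R − Q_res
C     = f_cl h_c (t_cl − t_a)            convective loss
R     = f_r  h_r (t_cl − t_r)            radiative loss
Q_res = 0.0173 M (5.867 − P_a) + 0.0014 M (34 − t_a)
E_max = (P_sk − P_a) / (I_e,cl + 1/(f_cl h_e))
```

with `I_e,cl = I_cl / (i_cl · LR)` the clothing evaporative resistance,
`h_e = LR · h_c` (Lewis ratio LR = 16.5 °C/kPa), mean skin temperature
`T_sk = 0.215 t_a + 26.6`, and skin/ambient vapour pressures from an
Antoine-form saturation curve. The clothing surface temperature `t_cl` is
solved from the steady conduction balance
`(T_sk − t_cl)/I_cl = C + R`. A negative raw `m_sw` is clamped to zero and
flagged. Metabolic rate, convective coefficient and radiation area factor
are tabulated per activity (sleep / light work / moderate work), and
clothing parameters per season; both tables ship as CSV in
`inst/extdata/` and as built-in defaults.

Per-person rates are integrated over the representative day (8 h sleep,
14 h light work, 2 h moderate work) with seasonal indoor-climate rules
(winter heating setpoint, otherwise the outdoor daily mean clipped to a
comfort band), summed over meteorological seasons, and multiplied over a
persons-per-cell raster to district volumes and a per-cell mm/year
intensity raster. Seeded generators produce a synthetic city (core-peaked
population raster, Voronoi districts, land-use grid with an exact green
fraction) and synthetic seasonal weather, so the entire pipeline runs and
is tested without any external data.

## Worked example

```r
library(bodyevap)

# one person, light work, light summer clothing, 23 °C / 50 % rh indoors
hb <- heat_balance(environment_state(ta = 23, rh = 0.5),
                   default_activities()$light_work,
                   default_clothing()$summer)
sprintf("msw = %.1f g/m^2/h, whole-body %.1f g/h", hb$msw, hb$g_per_h)
#> "msw = 39.7 g/m^2/h, whole-body 71.4 g/h"
sprintf("Ereq = %.1f, Emax = %.1f W/m^2, tcl = %.2f C", hb$ereq, hb$emax, hb$tcl)
#> "Ereq = 22.1, Emax = 162.1 W/m^2, tcl = 28.98 C"

# a 2-million-person synthetic city, full year
cfg <- default_run_config(seed = 42, output_dir = "demo")
cfg$city <- utils::modifyList(unclass(cfg)$city,
  list(nrow = 64L, ncol = 64L, cellsize = 500, population = 2000000,
       n_districts = 8L, landuse_cellsize = 100))
cfg <- read_run_config(unclass(cfg))
cmd_generate(cfg)
res <- cmd_run(cfg)
#> annual city total: 2961851 m^3 (0.18 mm over 16411 km^2)
round(res$per_person, 1)
#> spring summer autumn winter annual
#>  298.4  346.3  363.7  472.5 1480.9
cmd_sensitivity(cfg)
#> schedule sensitivity: -11.34% to +1.30% of baseline
```

The per-person numbers are litres per season; the annual summary, the
district-by-season table, the mm/year intensity raster (ESRI ASCII grid)
and the equivalence report (forest-area, green-space, water-use
comparisons) are written to the output directory as plain text/CSV. The
sensitivity command re-evaluates the annual total over the plausible range
of sleep (6–10 h) and moderate-activity (0.5–2 h) durations.

A thin command-line wrapper for the four commands is installed at
`inst/scripts/bodyevap.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/bodyevap.R", package="bodyevap"))')" generate --seed 1 --out demo
```

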