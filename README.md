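# rosecanopy

Functional–structural simulation of light interception and photosynthesis
in cut-rose (*Rosa hybrida*) canopies with bent shoots.

In commercial cut-rose production, weak shoots are bent below the
horizontal so they keep assimilating without competing with the upright
flower shoots that are sold. How much of the bent shoots' photosynthesis
actually ends up in the flower shoots cannot be measured directly — the
canopy is too heterogeneous for layer-averaged photosynthesis models — but
it can be computed with an explicit 3-D plant model. `rosecanopy` is such a
model, aimed at crop physiologists and greenhouse researchers:

* **3-D canopies** — upright shoots built phytomer by phytomer from
  architecture databases; bent shoots as random leaf clouds with a
  spherical leaf-angle distribution; commercial double-gutter bed layout at
  7.5 plants m⁻²; treatments with 0, 1 or 3 bent shoots per plant
  (0B/1B/3B).
* **Monte Carlo radiative transfer** — a diffuse sky dome (standard
  overcast gradation) traced through the canopy with exact per-ray energy
  conservation, toroidal plot wrapping, leaf reflectance/transmittance
  0.08/0.06, and virtual line-sensor readings (Q/Q0 profiles).
* **Leaf photosynthesis** — the non-rectangular hyperbola

  A = [Φ·I + Amax − √((Φ·I + Amax)² − 4θ·Φ·I·Amax)] / 2θ − Rd,  θ = 0.8,

  with photosynthetic capacity following the canopy light gradient,
  Amax = A0 · (Q/Q0)^k (A0 = 21.0 upright / 16.9 bent, k = 0.09), Rd
  proportional to Amax and a common quantum yield Φ = 0.057.
* **Greenhouse light reconstruction** — inside PAR from outside global
  radiation with structure transmission 0.6, shading-screen hysteresis
  (close > 600 / open < 500 W m⁻²), and 150 μmol m⁻² s⁻¹ supplemental
  lamps with their own hysteresis inside the 02:00–21:00 photoperiod.
* **Growth-cycle budgets** — scenes rebuilt every 3 days over a 35-day
  cycle, daily and cumulative mol CO₂ per plant split into upright vs bent
  shoot classes, plus scenario variants (bent LAI 5, 4/6/8 upright shoots
  at mixed stages, ground reflectance, direct-light fraction).
* **Translocation accounting** — f_dwt = (d − d_0B)/d_0B,
  Upright_ass = (1 + f_dwt) · Upright_ass,0B,
  f_trans = (Upright_ass − Upright_photo)/Bent_photo.
* **Synthetic data generators** for architecture, light-response curves
  and weather, so the full pipeline runs and is tested without external
  data.

## Worked example

```r
library(rosecanopy)

# a synthetic 3B architecture database and one day-25 scene
db    <- generate_architecture_db("3B", n_shoots = 6, seed = 101)
scene <- build_canopy("3B", day = 25, db, bent_areas = rep(1600, 3),
                      layout = c(2, 3), seed = 11)
scene
#> <canopy_scene> treatment 3B day 25
#>   plants: 6 ( 600 effective with replication 10 )
#>   organs: 1668  triangles: 15948
#>   upright LAI 3.88, bent LAI 3.60

light <- trace(scene, n_rays = 2e5, seed = 12)
light
#> <light_result> 2e+05 rays, incoming PAR 360 umol m-2 s-1
#>   absorbed: leaves 79.4%, other organs 13.9%, ground 3.2%; escaped 3.5%

# 35-day growth cycle driven by calibrated synthetic weather
weather <- generate_weather(35, seed = 5)
run <- simulate_period(scenario("3B"), db, weather,
                       layout = c(2, 3), n_rays = 5e4, seed = 7)
run
#> <period_result> 3B - 35 days
#>   cumulative net photosynthesis: plant 4.27, upright 2.01, bent 2.27 mol/plant
#>   final bent fraction: 0.53
```

The scene print shows the plot (6 plants standing in for 600 via toroidal
replication) and the leaf-area indices of the two shoot classes. The light
result is the energy audit of one trace: at full canopy nearly 80 % of
incoming PAR is absorbed by leaves and only ~3 % reaches the ground. The
period result accumulates daily net photosynthesis per average plant over
the cycle; here bent shoots end up contributing 53 % of the plant's
cumulative carbon gain.

Derived harvest metrics from the built-in published organ-weight table:

```r
table1_derived()
#> # A tibble: 3 × 8
#>   treatment shoot_dwt_g dwt_increase_pct fwt_increase_pct stem_per_length_g_cm ...
#> 1 0B               12.4                0                0                0.063
#> 2 1B               16.7               35               28                0.085
#> 3 3B               19.7               59               47                0.101
```

`autoplot()` methods draw budget time courses and fitted light-response
curves; `tidy()`/`glance()` give tabular summaries of fits and runs. A thin
CLI for full simulations is available as `scripts/simulate.R`.

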