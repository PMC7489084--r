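---
title: "Modelling light and photosynthesis in a bent-shoot rose canopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light and photosynthesis in a bent-shoot rose canopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In cut-rose production, weak shoots are bent below the horizontal ("bent
shoots") so they keep photosynthesising without competing with the upright
flower shoots that are harvested. The canopy that results is strongly
heterogeneous — vertical flower shoots above a horizontal foliage layer —
so layer-averaged canopy photosynthesis models do not apply. `rosecanopy`
represents the canopy explicitly in three dimensions, traces diffuse sky
light through it, computes net photosynthesis leaf by leaf, and accumulates
carbon budgets separately for upright and bent shoots over a 35-day flower
growth cycle. A final accounting step attributes the observed extra biomass
of upright shoots in bent-canopy treatments to assimilate translocated from
the bent shoots.

The three treatments are 0, 1 or 3 bent shoots per plant (0B/1B/3B), always
with four upright shoots, at 7.5 plants m⁻².

## Canopy construction

Upright shoots are stacks of phytomers (internode + compound leaf) topped by
a flower. Per-rank dimensions come from an architecture database — tables of
internode lengths/diameters, leaf lengths/widths, leaflet counts,
inclinations and flower width per shoot and measurement day (days 6, 9, 14,
19, 25) — linearly interpolated between measurement days and frozen from
day 25, when expansion has essentially stopped. Leaf area follows the
allometric relation `area = c · length · width` (default `c = 0.7`,
configurable; only the fit quality of this relation is published, not the
coefficient).

Geometry choices the data do not constrain, declared once:

* leaflets are planar elliptical triangle fans (2:1 aspect), arranged
  pinnately with one terminal leaflet; per-leaflet area = leaf area /
  leaflet count, and the mesh is rescaled so triangle areas match the
  allometric area exactly;
* phyllotaxis 137.5° (configurable), leaf insertion angles as measured
  (drooping from horizontal);
* the flower is an octagonal cone with an effective silhouette of 60 % of
  the measured bloom width — petals are not a solid plate, and a full-width
  opaque disk would intercept an implausible fifth of all incoming light;
* upright shoots lean 15° outward (vase-shaped plant form).

Bent shoots cannot be measured organ by organ, so they are a cloud of
square leaves placed uniformly at random in the volume they occupy, with a
spherical leaf-angle distribution by default (all surface orientations
equally probable; mean projected-area fraction 0.5). Horizontal and
vertical angle models are provided as the contrasting extremes for
sensitivity analysis. Individual leaf areas are lognormal (mean 30 cm²,
σ(log) = 0.3) and rescaled so the total is conserved exactly.

Plants are laid out as commercial double-gutter beds: two gutters 0.5 m
apart per bed, beds repeating every 2 m, in-row spacing set by the overall
density (13.3 cm at 7.5 plants m⁻²), shoot bases at 0.7 m (gutter height).
Bent foliage occupies a 0.5 m-tall layer centred under the crown and
spreads 1.8 m across the bed — bent shoots are 0.8–0.9 m long and arch out
over the paths. The bed structure matters: a uniform plant grid without
light wells makes the bent layer far darker than the measured light
profiles suggest.

The traced domain is one bed segment with *toroidal wrapping* in x and y
(triangles protruding past a wall are duplicated shifted by the domain
period), which represents an unbounded stand; the `replication` argument is
metadata recording how many copies the plot stands for.

## Radiation

Diffuse sky light is a dome of discrete directions (default 72, in zenith
rings with azimuth-uniform weights). The default gradation is the standard
overcast sky, radiance ∝ (1 + 2 cos θ)/3, brightest at the zenith; an
isotropic sky is available, and a direct-beam fraction at a fixed elevation
is provided purely as a sensitivity knob (no solar ephemeris — the study
system is dominated by diffuse light).

The Monte Carlo tracer launches rays from a plane above the canopy
(positions uniform, directions sampled from the dome weights, which are
fractions of horizontal-plane flux). At each surface hit the event is
sampled: reflect with probability ρ, transmit with τ, absorb otherwise
(leaves ρ = 0.08, τ = 0.06 from spectrophotometry on the same cultivar;
stems and flowers ρ = 0.08, τ = 0). Scattering is Lambertian. The ground
reflects diffusely with configurable reflectance (default 0.5) or absorbs.
Sampling the event outcome means every ray's full weight ends somewhere —
a leaf, the ground, or escape upward — so the energy audit closes exactly,
and survival per interaction is ρ + τ ≈ 0.14, terminating paths quickly
without weight-window machinery. For fixed geometry the transported flux is
linear in the source strength, so one trace per canopy rebuild is reused
across the hours of a day by scaling (per-hour retracing is available but
changes nothing except Monte Carlo noise).

Virtual sensors are cosine-corrected horizontal receivers with a line-
sensor footprint (0.5 m × 0.1 m by default) that tally downward-crossing
ray weight; readings are reported relative to an above-canopy reference,
matching how field light profiles are expressed (Q/Q0).

Default rays per trace: 2 × 10⁵ for routine work and testing (per-leaf flux
densities are then stable to a few percent); 5 × 10⁶ reproduces
publication-scale smoothness.

## Leaf photosynthesis

Net photosynthesis follows the non-rectangular hyperbola: gross assimilation
is the lesser root of

θ A² − (Φ I + Amax) A + Φ I Amax = 0,

minus dark respiration Rd, with curvature θ fixed at 0.8. Fitted parameters
for the reference upper leaf: Φ = 0.057 mol mol⁻¹, Amax = 20.2, Rd = 1.25
μmol m⁻² s⁻¹.

Capacity varies through the canopy with relative light, `Amax = A0 ·
(Q/Q0)^k`, fitted in log–log space; k = 0.09 is shared between shoot
classes while A0 differs (21.0 upright, 16.9 bent — bending lowers
capacity). Each leaf's Q/Q0 is its incident flux density from the trace
divided by above-canopy PAR, clipped to (10⁻³, 1]; Rd is proportional to
Amax and Φ is common to all leaves.

Two calibration points deserve note:

* **Rd/Amax ratio.** The proportionality constant is not published. The
  upper-leaf ratio alone (1.25/20.2 ≈ 0.062) over-predicts the measured
  dark respiration of bent and lower leaves by roughly a factor two, so the
  package default is the least-squares slope through the origin over all
  eleven published (Amax, Rd) leaf-layer pairs: 0.046.
* **Stepwise curve fitting.** The published stepwise protocol for fitting
  light-response curves is not reproducible from the main text. A naive
  split — straight-line Φ/Rd fit below 200 μmol m⁻² s⁻¹, then Amax — is
  biased, because at Φ = 0.057 and Amax ≈ 20 the hyperbola is already ~15 %
  below the Φ·I line at I = 200. `fit_light_response()` therefore iterates
  the two steps (Φ, Rd given Amax on the low-light subset; Amax given Φ, Rd
  on the whole curve) to convergence, which recovers noiseless parameters
  exactly and keeps median |Amax bias| below 5 % at measurement-scale noise
  (σ = 0.5 μmol m⁻² s⁻¹). Monotonically falling curves are refused; flat
  curves are fitted but flagged degenerate.

## Greenhouse light

Inside PAR is reconstructed from outside global radiation at 5-min
resolution: `inside = outside × par_per_global × 0.6 [× 0.7 if the screen
is closed] + 150 if the lamps are on`. Lamps run only in the 02:00–21:00
photoperiod with hysteresis on outside radiation (on < 200, off > 300
W m⁻²); the shading screen closes above 600 and opens below 500 W m⁻².
The global-to-PAR conversion is not published; the default 2.1 μmol J⁻¹
(≈ 45–50 % PAR fraction × 4.57 μmol J⁻¹) is configurable, and no reported
quantity depends on it because the synthetic weather is calibrated to the
published *inside* mean. Hourly PAR is the mean of the 5-min values.

## The growth-cycle simulation

The scene is rebuilt every 3 days (days 1, 4, …, 25, then frozen), with
shoot parameter sets drawn at random from the database, as in the source
study. Days before the first measurement day reuse the earliest measured
set — nothing earlier exists to interpolate from. Each rebuild is traced
once; each day the 19 photoperiod-hour PAR values scale the per-leaf
fluxes, the hyperbola gives each leaf's net rate on its incident-light
basis, and sums over leaves × 3600 s yield daily mol CO₂ per plant by shoot
class. Night-time leaf respiration is excluded from the budgets, matching
the source accounting. Cumulative budgets are prefix sums; the bent
fraction is cumulative bent / plant.

Scenario variants cover the published what-ifs: bent LAI raised to 5;
plants with 4, 6 or 8 upright shoots at mixed developmental stages
(parameter sets drawn from different measurement days), computed
steady-state at the mean photoperiod PAR of 360 μmol m⁻² s⁻¹; ground
reflectance 0–1; direct-light fraction; bent-leaf angle models.

## Translocation accounting

With the 0B cumulative upright photosynthesis as baseline, the fractional
dry-weight gain of upright shoots `f_dwt = (d − d_0B)/d_0B` is assumed to
equal their fractional assimilate gain, so `Upright_ass = (1 + f_dwt) ×
Upright_ass,0B`, and the fraction of bent-shoot photosynthate translocated
to upright shoots is `f_trans = (Upright_ass − Upright_photo) /
Bent_photo`. Applied to the published relative quantities (plant
photosynthesis 1.73× and 2.17× the 0B level; bent contributions 43 % and
53 %; harvest dry weights 12.4/16.7/19.7 g), this yields f_trans ≈ 48.5 %
(1B) and 49.5 % (3B). Reported percentages round half-up to integers,
matching the published convention.

## Synthetic data

The generators reproduce the study's statistical structure so the whole
pipeline runs and is tested without the (unpublished) raw data:

* **Architecture**: per-shoot logistic growth (midpoint day 12, 95 % of
  final size at day 25, area basis) reaching the published per-treatment
  harvest means at day 25, with lognormal between-shoot variation scaled
  from the published standard errors (×√18 for the 18 replicate shoots).
  Leaves appear progressively (≈ 5 visible at day 6, all 14 by day 19);
  mid-shoot leaves and internodes are the largest (sinusoidal rank
  profile). Organ dimensions are independent given the shoot-level scale
  factor — the true within-shoot covariance is unknown.
* **Light-response curves**: hyperbola values at the nine measured light
  levels (1500 … 50 μmol m⁻² s⁻¹) plus Gaussian noise.
* **Weather**: half-sinusoid daily global radiation (daylight 06:00–21:00)
  with lognormal day-to-day amplitude, its scale calibrated by root finding
  through the full greenhouse chain so the photoperiod-mean inside PAR is
  360 μmol m⁻² s⁻¹, the published experiment mean.
* Bent-shoot leaf areas per treatment default to LAI 3.6 (3B, published)
  and 1.2 (1B, one shoot of the same size as each of the three 3B shoots;
  the 1B value is not printed numerically).

What passing tests on these data do **not** show: fidelity to the real
plants' covariance structure, to the actual spring weather record, or to
the absolute published simulation magnitudes — those depended on the
unpublished architecture and weather databases.

## Numerical choices and degenerate inputs

* Quadratic root: computed in closed form with the discriminant clamped at
  zero; the lesser root always satisfies gross ≤ min(Φ I, Amax).
* Q/Q0 floor 10⁻³ (avoids log 0 in the gradient); clipping at 1 never
  raises capacity above A0.
* Ray–triangle intersection: Möller–Trumbore, two-sided, 10⁻⁹ m minimum
  hit distance and 10⁻⁷ m scatter offset against self-intersection; a
  uniform grid (≈ 2 triangles per cell) accelerates traversal; rays that
  wrap more than 10⁴ times (near-horizontal paths) are terminated as
  escaped.
* Empty scenes send all flux to the ground; zero reference sensor readings
  and zero baseline weights raise errors rather than returning infinities.
* Hysteresis controllers derive their initial state from the first
  radiation value against the nearest threshold midpoint.

## Problem sizes

Routine runs and the test suite use desk-scale settings chosen once: plots
of 2 × 3 to 2 × 5 plants (the toroidal domain removes border effects at any
plot size), 3–5 × 10⁴ rays per trace for budget integration and 2 × 10⁵
where Monte Carlo precision is compared against closed-form oracles. These
give per-leaf fluxes stable to a few percent and class-level budgets stable
to ≈ 1 %, which is ample for the qualitative orderings the simulations are
asked to reproduce.

## Known limitations

* No carbon allocation or growth feedback: architecture is replayed from
  the database, photosynthate is not converted to structure.
* No stem or flower photosynthesis (their surfaces only intercept and
  scatter light); no night respiration, maintenance costs or conversion
  losses — the translocation fraction is therefore a lower bound, as in
  the source analysis.
* Light is broadband PAR; no spectral bands, no lamps as point sources, no
  greenhouse frame, gutters or bricks (the latter are the likely cause of
  the published overestimate of light below 1B bent shoots).
* The bent-shoot layer's interception saturates strongly near LAI 3.6 in
  this geometry: raising bent LAI to 5 adds only ≈ 4 % absorbed PAR and,
  net of the added leaf respiration, slightly *reduces* cumulative bent
  photosynthesis (≈ −4 %), whereas the source study reported a small gain
  (+6 %). The sign depends on how dark respiration is distributed over
  deeply shaded leaves; with the bent-leaf-only measured Rd/Amax ratio
  (≈ 0.03) the change is ≈ 0. The package keeps the single global ratio
  and reports the discrepancy rather than tuning it away.
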