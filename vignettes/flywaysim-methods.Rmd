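---
title: "flywaysim: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flywaysim: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywaysim)
```

## The model

`flywaysim` simulates the non-breeding season (1 September – 31 May,
273 or 274 days) of a mallard-like dabbling duck as a deterministic,
population-level Markov process on a grid of stopover nodes. The state
is a continuous abundance mass over (node × body-condition class),
plus a per-node forage pool; the only randomness in a run is the
seeded draw of the midwinter inflection day of the arrival-weight
schedule, so identical seeds give bit-identical output. Each day
applies forage → departure → arrival → mortality, in that order; the
accounting identity *abundance + cumulative deaths = N₀* holds exactly
every day (verified to relative error < 10⁻¹⁰ in the test suite).

Body condition is binned into `n_classes = 21` classes by fat
proportion of a reference mass *M* = 1.2 kg: class 1 is dead/starved
(fat 0, survivorship 0), and fat rises evenly to `f_max = 0.11`
(sensitivity alternatives 0.08 and 0.14 are accepted by the same
machinery). Daily survivorship interpolates linearly in class index
from 0.99620 (class 2) to 0.99984 (top class); interpolation shape is
a package choice — only the endpoints are empirically anchored.
Classes whose fat mass exceeds `fat_opt = 0.134` kg (the fat load of a
1.625 kg bird) are capped at the second-best survivorship, reflecting
optimal-body-mass theory (heavy birds evade predators less well). With
the default ceiling no class triggers the cap; with `f_max = 0.14`
the top classes do.

## Energetics

**Fuel deposition.** Intake capacity is `fdr_coef × M` of body mass
per day in fat (default 0.011, i.e. 524.04 kJ/day at 39,700 kJ/kg),
scaled by (1 − urban disturbance), gated to zero in unavailable nodes
(snow and ice impede access to calories), and rationed proportionally
when summed node demand exceeds standing forage. The deposition rate
is interpreted as a *net* rate: fuel deposition rates in the migration
literature are measured as realised mass gain in free-living birds,
which already forage for maintenance. Two consequences follow. First,
the default metabolic charge against the daily gain is only the
thermoregulatory surcharge below a lower critical temperature
(`t_lc = 10` °C, `therm_slope = 15` kJ/day/°C; the allometric basal
coefficient `bmr0_coef` defaults to 0 in `sim_config()` and to the
full non-passerine rate in the standalone `bmr()`). Second, the
default deposition rate equals exactly two class widths per day
(0.011 × 1.2 kg = 2 × 0.0066 kg), so a feeding bird climbs the
condition ladder cleanly despite the floor quantization described
below. Charging the full allometric basal rate against a *net*
deposition rate would double-count maintenance; in practice it leaves
the net gain (≈ 172 kJ/day) below one class width, the floor
quantization then discards every day's progress, and the population
starves wholesale — which is how this design choice was settled.

**Forage decay.** Each cover class retains a fraction *r* per day
(shoreline 0.9998, crops 0.9970, woody wetlands 0.9965, herbaceous
wetlands 0.9910), so without consumption *F*ᵢ = *F*₀·*r*ⁱ. The
per-day retention reading is deliberate: the alternative reading, in
which the *cumulative* quantity *E·r*ⁱ is subtracted each day, removes
essentially the whole pool on day one for *r* ≈ 0.99 and contradicts
the near-1 "weights" the decay rates are given as. Consumption is
applied before decay within a day (`decay_order` switches this).

**Initial forage.** *F*₀(class) = node area × cover proportion ×
energy density × accessibility, where accessibility decays
exponentially with distance to the nearest roosting habitat with a
16 km e-folding scale — the local-movement distance below which bird
displacement counts as within-node dispersal. Energy densities per
cover class are config inputs, not empirical anchors; the defaults
(shoreline 10⁶, crops 2.5 × 10⁶, woody wetland 1.5 × 10⁶, herbaceous
wetland 3 × 10⁶ kJ/km², chosen once as order-of-magnitude waterfowl
food-energy figures) give a 600-node demo landscape roughly four times
the full-season energetic demand of a population at the reference
density of ~990 birds per node — comparable headroom to a continental
grid. Demos that pack many times that density exhaust the static
landscape by spring, which is a property of the scenario, not of the
model.

## Weather severity and availability

WSI = *S*·0.394 + *S*days − *T* + *T*freeze, with snow depth *S* in cm
(0.394 converts to inches and is kept as a literal constant), streak
counters for days with *S* ≥ 2.54 cm and days with *T* strictly below
0 °C, both starting at 0 on 1 September (early-September streaks are
rare, so the initialisation bias is negligible). A node is available
iff WSI < 7.5, strictly. Air density is the ideal-gas value
*P*/(287.05·(*T*+273.15)). Missing weather is forward-filled up to
three days, then refused.

## Movement

**Departure** combines four pressures per node and class, each bounded
in [0, 1]: a Monod curve in WSI (exponent 3, half-saturation at the
7.5 threshold; the body-condition exponent is set near three times the
WSI exponent to make condition, not weather, the sharply switching
component), a Monod curve in the zero-based class index (exponent 8,
half-saturation *n*−3, so only the top three classes feel strong
pressure), a Monod curve in breeding-ground distance (exponent 5,
half-saturation at the cohort's flight range), and a linear
daily-gain term `1 − (DG + 1)/5` clamped to [0, 1]. The daily-gain
term defaults to DG in kJ/day (`dg_form = "kj"`): 0.8 where nothing
can be gained, 0 wherever at least 4 kJ/day can be deposited — an
almost binary "can I refuel here?" signal. The alternative
`"normalized"` form applies the same expression to the day's min–max
normalised gain; because it yields 0.6–0.8 for every bird every day,
it forces ≥ 0.15/day departure under the mean rule (~40 flights per
season against refuelling that supports ~7) and drives the population
to starvation; it is retained as a config switch, not as the default.
The four components combine by arithmetic mean by default — a sum of
four probabilities is not a probability — with a clamped sum
selectable (`combine_rule = "sum"`).

**Arrival** uses Cobb–Douglas attractiveness over five components,
each min–max normalised to [0, 1] and floored at 10⁻⁶ (the seasonal
weights go negative off-peak, so zero bases must be avoided): forage,
air density, roosting quality, breeding *proximity* (1 − normalised
distance, so attractiveness increases toward the breeding grounds),
and a gamma movement-kernel score — for each node, the mean gamma
upper-tail probability of covering the distance from everywhere else
(shape 2; scale defaults to half the top-class flight range; both are
free parameters with no empirical anchor). The component weights
follow quadratics in a shape sequence *c* that runs 1 → 0.1 → 1 with
its minimum at an inflection day drawn uniformly from 31 December –
31 January: forage, air density and roosting peak at 0.45/0.30/0.20
(with the kernel weight constant at 0.05) at the inflection, and the
breeding-distance weight is the remainder to 1, dominating early and
late in the season. Centring the quadratics on the inflection value
0.1 reproduces the stated peak weights exactly; the resulting negative
off-peak weights are kept, since they follow from those peaks and the
sum-to-one constraint.

Arrivals are restricted to available nodes within the departing
cohort's fat-limited flight range from its origin (renormalised per
origin); a cohort with no permitted reachable destination stays put —
it still pays any thermoregulatory deficit and, in an unavailable
node, ingests nothing. Flights decrement condition by distance ×
cost, and landing condition is floor-quantized to the class ladder;
birds falling below the class-2 fat mass starve into the dead class
(a `starvation = FALSE` switch floors transitions at class 2 for
analytic bound checks). Cohorts below 10⁻⁹ birds stay put rather than
fly, which bounds the per-day work without measurable effect at
simulated population sizes.

**Flight mechanics.** Chemical power is the published Pennycuick
(2008) formulation: induced power *k*(*Mg*)²/(2ρ*V*·π*b*²/4) with
*k* = 1.2, parasite power ½ρ*V*³·*S*b·0.1 with body frontal area
*S*b = 0.00813·*M*^0.666, profile power 8.4/aspect-ratio × the
absolute minimum power, all divided by conversion efficiency 0.23,
plus a basal add-on 3.79·*M*^0.723 W (switchable), times a 1.1
respiration/circulation factor. The maximum-range speed minimises
*P*(*V*)/*V* by golden-section search (tolerance 10⁻³ m/s) on the
evaluated true-air-speed domain 10–25 m/s; cost per km divides power
at that speed by the 39,700 kJ/kg energy density of fat. The season
engine uses a single reference-bird cost (1.2 kg, 0.95 m span,
0.1 m² wing area, air density 1.225 kg/m³ → 1.03 × 10⁻⁴ kg/km) for
all classes, since classes share the reference morphology and differ
only in fat load.

## Synthetic test bed

`synth_landscape()` builds a planar grid (km coordinates, y north)
with box-blurred Gaussian cover noise, a south-to-north decay in
shoreline/wetland cover, urban disturbance, and a northern breeding
band. `synth_weather()` generates *T* = base − severity·(lapse·northward
distance + amplitude·seasonal dip) + per-node AR(1) noise, with
stochastic snowfall below freezing, melt above, and a static per-node
pressure spread. The defaults — 22 °C south-edge baseline, 12 °C
seasonal dip centred on day 137 (mid-January), 2 °C/100 km lapse,
AR(1) sd 2.5 and coefficient 0.6, snow probability 0.35 with 4 cm mean
events — compress a continental transect onto the 644-km demo span:
the south edge stays above freezing in winter (a Gulf-coast-like
refuge that even the severe preset does not freeze over), the north
edge freezes reliably in midwinter, derived air densities stay inside
the observed 0.95–1.30 kg/m³ band, and WSI crosses 7.5 in both
directions over a season. The presets differ only in the severity
multiplier (mild 0.7, baseline 1.0, severe 1.4).

What the generator does *not* emulate: spatially correlated storm
systems (noise is independent across nodes), elevation and coastline
geometry, wind, real land-cover maps, and interannually varying
landscapes. Passing directional tests on this test bed therefore shows
that the model machinery responds to weather structure in the right
direction, not that it reproduces any particular continental year.

## Numerical choices

- Continuous-mass accounting, no integer rounding; exact conservation
  is enforced at initialisation (the float residual is pinned onto the
  largest cell) and preserved by every operator.
- Floor quantization on the class ladder (largest class at or below
  the new fat mass, with a 10⁻¹² fuzz so exact ladder values stay
  put); conservative, and exact at the starvation boundary.
- Min–max normalisations guard the degenerate constant field by
  returning 1 everywhere (a constant component is uninformative, so
  it must not distinguish nodes).
- Distances: Euclidean on planar grids; haversine with radius 6371 km
  on lon/lat grids. Per-class reachability masks and post-flight
  class tables are precomputed once per run (the distance matrix is
  static), giving O(nodes²) memory per class — fine to a few thousand
  nodes, the intended scale of this implementation.
- Mortality applies after arrival; the dead class is flushed into
  cumulative deaths daily, so class 1 is empty at each day's start.
- Leap seasons (274 days) shift the winter/spring reporting boundary
  by one day; period survivorships multiply exactly to the season
  survivorship.

## Problem sizes

The shipped checks use a 3-node toy against a brute-force one-day
enumeration (relative error < 10⁻¹⁰), a 600-node (20 × 30) grid over a
full 273-day season at N₀ = 10⁶ for conservation, a 160-node grid for
the five-point severity sweep, and a 1200-point morphometric ×
air-density sweep for flight performance. These sizes keep a complete
run of the suite within a few minutes on one CPU while exercising
every operator at population scale.

## Known limitations

- The landscape is static apart from forage decay and consumption: no
  regrowth, flooding, or land-use change, so very high bird densities
  exhaust the spring landscape by construction.
- Harvest mortality is not modelled (survival reflects weather and
  condition only); wind, disease and competition are likewise out of
  scope.
- The O(nodes²) precomputed movement tables trade memory for speed and
  would need a sparse or chunked redesign at true continental node
  counts.
- Center-of-mass on lon/lat grids averages coordinates directly,
  which is adequate at continental scale but not exact.
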