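---
title: "A spatial-epidemiological model of emergency ambulance provision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatial-epidemiological model of emergency ambulance provision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambusim)
```

## The question the model answers

A region is considering an emergency ambulance service for a
time-critical condition (the defaults are parameterised for severe
postpartum haemorrhage). Today, patients arrange informal transport:
they first spend time locating a vehicle and a driver, then travel to
hospital. An ambulance dispatched from a hospital-based hub skips the
search but must drive out and back. Whether the service saves lives
therefore depends on geography: how far people live from the hospital,
how dense the population is (dense places find informal vehicles
quickly), and how much faster an ambulance drives.

`ambusim` turns those ingredients into an annual lives-saved estimate
with a credible interval, and into maps showing *where* the service
helps or harms.

## Model structure and assumptions

For a cell at location $x$ with one-way travel time $t(x)$ minutes and
population density $\rho(x)$ persons/km²:

* Informal journey: $t_0(x) = t(x) + \tau(x)$.
* Ambulance journey: $t_1(x) = 2 s\, t(x) + \theta$, a round trip from a
  centralised hub at the facility, with speed multiplier $s$ and
  call-out delay $\theta$ (default 0, the model's simplifying
  assumption; the hook exists but is beyond the default model).
* Survival: $S(t) = e^{-\lambda t}$.
* Expected annual effect:
  $\Delta = I \int_A [p_1 S(t_1) - p_0 S(t_0)]\, \rho\, dx$, with the
  integral discretised over raster cells.

Standing assumptions: the ambulance is always available and leaves
immediately; no clinical care is delivered en route (the service acts
only through time); informal transport starts at the patient's location;
the region's rasters share one grid.

### The waiting-delay distribution

$\tau(x)$ is Rayleigh with mean $\beta / \sqrt{\rho(x)}$. The form
follows from a nearest-vehicle argument: if available vehicles form a
planar Poisson field with intensity proportional to $\rho$, the distance
to the nearest one is Rayleigh, and its mean scales as $1/\sqrt{\rho}$.
$\beta$ is then the mean delay where the density is one person per km².
The scale parameter is $\sigma = (\beta/\sqrt{\rho})\sqrt{2/\pi}$
(`rayleigh_scale()`), since a Rayleigh($\sigma$) has mean
$\sigma\sqrt{\pi/2}$. At the reference density of 137 persons/km² the
means are 5.1, 10.3, 15.4, 20.5 and 25.6 minutes for
$\beta = 60 \ldots 300$ — the anchor values the acceptance checks
recompute.

### Choice rules

With the service in place, `scenario_spec()` selects how patients pick a
mode:

* `fastest` — $S_1 = S(\min(t_0, t_1))$; never worse than baseline, an
  upper bound on benefit (perfect knowledge).
* `ambulance` — $S_1 = S(t_1)$; can cost lives where the round trip
  exceeds the informal journey.
* `random` — the $w$-mixture of the two. Because cells carry *expected*
  fractional cases, the mixture is implemented as the expectation rather
  than per-individual Bernoulli assignment: exact in expectation and
  lower-variance, and it makes the question of whether the random halves
  are redrawn per replication moot.

The probability-of-improvement map is
$q(x) = \Pr[\tau(x) > (2s-1) t(x)]$, the Rayleigh survival function at
the threshold; $q \equiv 1$ whenever $s \le 0.5$ (the round trip at
double speed is never slower than the one-way informal journey).

## Parameters, units, defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `beta` | mean waiting delay at density 1/km² | minutes | 60–300 (grid) |
| `s` | ambulance speed multiplier | — | 0.6–0.9 (grid) |
| `lambda_mean` | survival rate | per minute | 0.056 |
| `lambda_sd` | sd of the Normal draw of λ | per minute | 0.01 |
| `gamma_shape`, `gamma_scale` | incidence distribution | % of live births | 2, 0.5 |
| `birth_rate_per_1000` | crude birth rate | births/1000/yr | 27.5 |
| `p0`, `p1` | care-seeking without / with service | probability | 1, 1 |
| `theta` | ambulance call-out delay | minutes | 0 |
| `monte_carlo.n_reps` | replications | — | 10000 |

Three of these deserve comment:

* **Incidence is a percentage.** Gamma(2, 0.5) has mode 0.5; the draws
  are interpreted as percent of live births (mode 0.5%) and divided by
  100. The per-cell case load is
  $\rho \cdot \text{area} \cdot (\text{birth rate}/1000) \cdot I$.
* **λ's anchor is indirect.** 0.056/min corresponds to a survival of
  0.160 at roughly 33 minutes to care — consistent with an elicited
  24-hour survival of 0.16 for severe postpartum haemorrhage reached at
  the longest observed transfer times, but the anchoring arithmetic is
  not fully determined, so λ is treated as a direct input and should be
  re-elicited for other conditions.
* **λ's spread is a package default.** The rate is drawn from a Normal
  truncated to positive values; the sd is not pinned by the sources the
  defaults come from, so the package defaults to 0.01/min, which spans
  the elicited survival band without meaningful truncation. Truncation
  is by rejection, not clipping — clipping would put an atom at zero.
  A warning fires when more than a quarter of the Normal's mass lies
  below zero, the point where rejection visibly distorts the shape (a
  majority-negative Normal is impossible for a positive mean, so the
  threshold is set where the distortion becomes material).

## Travel times

`least_cost_travel_time()` runs a multi-source Dijkstra (via igraph)
over the friction raster: moving between adjacent cells costs the
distance in metres times the *mean* of the two cells' friction values
(min/m). The neighbourhood is 8-connected with $\sqrt{2}$ diagonal
scaling. Cost-distance implementations differ in these two dialects, so
both are exposed (`edge_cost = "mean" | "min" | "max"`,
`connectivity = 8 | 16`) rather than hidden; the defaults are the most
common convention. A hand-written Bellman–Ford oracle
(`brute_force_travel_time()`, refused above 5×5) verifies the Dijkstra
path in the test suite over randomised grids.

Facilities are snapped to the nearest cell centre and must not sit on
impassable cells. A precomputed travel-time raster can be supplied
instead of friction + facilities, bypassing this module entirely.

## Handling of degenerate cells

* nodata density, or density 0: no population, excluded from all
  integrals (not given an infinite delay).
* nodata friction: impassable wall for the path search.
* unreachable cells ($t = \infty$): survival 0 under both scenarios, so
  they contribute nothing to $\Delta$; their count is reported.

## Monte Carlo design

Each replication draws the incidence fraction and λ once (global
parameter uncertainty) and one Rayleigh delay per populated cell
(spatial stochasticity) — cell-level draws match the resolution of every
other input. The 95% credible interval is the equal-tailed 2.5/97.5
percentile of the replication deltas; the per-cell mean map accumulates
across replications and its regional sum equals the mean delta
(conservation, tested to 1e-9 relative).

Reproducibility: the top-level seed spawns one sub-seed per replication,
so results are bit-identical for a fixed seed and identical between the
vectorised main loop and the single-replication API
(`lives_saved_one_rep()`), which draw in the same order.
`results_grid()` reuses the same seed for every $(\beta, s)$ combination
— common random numbers — which makes the monotone trends in the grid
(benefit rising with $\beta$, falling with $s$ under `fastest`) exact
rather than statistical.

An alternative `tau_mode = "expectation"` replaces the per-cell delay
draw with its exact expectation over the Rayleigh distribution, using
the closed-form restricted Laplace transform
$E[e^{-\lambda\tau}\,;\,\tau \le b]$; useful for variance reduction and
as a deterministic cross-check. The independent verification route is
`quadrature_oracle()`, which integrates the survival difference against
the Rayleigh density numerically (`stats::integrate` over $(0,
38\sigma)$, a range that holds the full Rayleigh mass at double
precision and stays well-conditioned when $\sigma$ is tiny, with the
integral split at the kink where the ambulance overtakes informal
transport).

## The synthetic generator

`synthetic_spec()` emulates the structure the model cares about:

* population clustered in Gaussian "towns" (kernels truncated at 4 sd;
  mass beyond is negligible) over a thin background;
* a road network of straight low-friction corridors chaining the town
  centres, densest first, so facilities always sit on roads;
* facilities in the largest towns, as real hospitals are.

Default friction values are 0.001 min/m on roads (~60 km/h) and
0.012 min/m off-road (~5 km/h, walking pace) — the scale used by global
motorised-friction surfaces. The default region is 50×50 cells of 1 km,
5 towns peaking at 1000 persons/km² (sd 3 km) on a background of
5 persons/km², 6 roads and 4 facilities: a sparse rural region with a
few market towns, the setting where the ambulance question is sharpest.

What it does **not** emulate: realistic road topology (no graph
snapping, no loops or hierarchy), anisotropic or time-varying travel
costs, spatially varying incidence, and real population gradients.
Passing tests on synthetic data therefore validate the *machinery* —
path costs, distributions, integration, reproducibility — not the
realism of any particular region; applying the model to a real region
requires real density and friction rasters and locally elicited
parameters.

## Problem sizes

The test-suite simulations use the 50×50 default region (or a 25×25
variant) with hundreds to a thousand replications, and the single-cell
oracle comparison uses 10⁵ replications — sizes at which Monte Carlo
error is far below the effects being checked while the whole suite runs
in well under a minute of compute. Production runs at the default 10⁴
replications scale linearly in cells × replications.

## Known limitations

* The speed multiplier is a single constant; real ambulance advantage
  varies by road class, season and time of day.
* No call-out queueing: $\theta$ is a fixed scalar hook, default 0.
* No clinical (paramedic) effect on λ.
* Supply-induced demand enters only through scalar $p_0$, $p_1$.
* Equal-area cell geometry comes from the raster transform; users of
  geographic-CRS (degree) rasters must supply `cell_area_km2`
  explicitly.
* Friction-surface travel times are known to underestimate
  patient-reported journey times; the model inherits any such bias in
  its inputs.
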