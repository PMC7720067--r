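---
title: "Microplanning door-to-door SMC campaigns: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microplanning door-to-door SMC campaigns: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcplan)
```

## The problem

Seasonal malaria chemoprevention (SMC) reaches under-5 children door to
door: a pair of community health workers (CHWs) walks a village over a
4-day round, treating each household's eligible children. Where CHWs walk
without maps or itineraries, they cover longer distances, miss households,
and coverage falls far below the level at which SMC suppresses
transmission. `smcplan` models the round as a time-budget problem: how much
of a CHW pair's time does a village actually require, what fraction of
children does a given workforce reach, and how many CHWs would full
coverage take?

## Model

### Time ledger

One CHW pair has a budget of `chw_pairs × campaign_days` workdays of
`workday_hours` hours (defaults: 1 pair, 4 days, 8 h). Two activities
consume it:

* **Walking.** Distance converts to time at `walk_min_per_km` (default
  20 min/km — a wet-season village walking pace). 20 km is thus 0.83
  workdays.
* **Treatment.** Under current practice a CHW spends on average
  12.5 min per child (`current_fixed`). Standardised delivery is modelled
  either as a fixed 8.5 min/child (`optimal_fixed`, the 3-child household
  optimum 25 min/3) or stochastically (`optimal_draws`): U(10,15) min for a
  1-child household, U(15,20) for 2 children, U(20,25) for 3, and 8.5 min
  per additional child beyond the third (the fixed-rate extrapolation;
  households that large are rare under the family-size law below).

The simulation (`simulate_campaign()`) walks the itinerary in order. A
household is visited only if the leg to reach it plus its full treatment
fits the remaining budget — treatment is all-or-nothing because SMC doses
cannot be split between days — and the walk stops at the first household
that does not fit. Households without under-5 children cost walking time
only. Day boundaries are ignored: time is a continuous budget, which
matches how the component day-counts add up in practice. Fractional
`chw_pairs` scale the budget linearly, so workforce requirements can be
expressed as fractional pairs.

From the ledger follow the two summary quantities:

* coverage `= Σ nᵢ / N × 100`, the treated share of eligible children;
* unmet needs `= (t / T) × 2` CHWs, where `t` is the full-village
  treatment-plus-travel time in days and `T` the campaign duration. The
  result reports this from the complete ledger (all households, whole
  itinerary) regardless of where the budget truncated the walk, since it
  answers "what workforce would cover everyone".

### Itineraries

The visit itinerary is an open-path travelling salesman problem: visit
every household exactly once, no return to the start, both endpoints free.
`held_karp_path()` solves it exactly with the Held-Karp dynamic program
over vertex subsets, `O(2^N · N²)` time and `O(2^N · N)` memory, with the
path recovered by backtracking through the subset table. The default
`exact_limit` is 15 households (a few MB of table and well under a second);
beyond it the function refuses and `heuristic_path()` — multi-start
nearest-neighbour construction followed by 2-opt segment reversal to a
local optimum — takes over. The heuristic is never below the exact optimum
(it is a feasible path) and on small random instances, where both can be
run, it averages within a few percent of it; real villages of 100+
households are routed heuristically, and itineraries carry an `exact` flag
saying which solver produced them.

Distances are great-circle-faithful at village scale: the default
`euclidean_local` metric projects lon/lat onto a local equirectangular
plane centred on the village centroid and applies the Euclidean formula;
`haversine` (via geosphere, with the mean Earth radius 6371.0088 km) is
offered as a cross-check because raw degrees are not a metric. Below
~20 km extents the two agree to well under 1%, which the test suite
asserts.

Tie-breaking: among equal-cost optimal paths the backtracking prefers the
smallest vertex index at each step, and the returned direction is the
lexicographically smaller of the path and its reverse — a path and its
reverse have identical length, so the choice is pure convention, made for
reproducibility.

### Constrained clustering

Villages split by barriers (water streams, in the motivating settings) are
subdivided before routing: `constrained_kmeans()` partitions households
into `k` clusters, cluster `h` containing at least `τ_h` households,
minimising `Σᵢ Σₕ T_{i,h} · ½‖xᵢ − C_h‖²`. The iteration alternates

1. **assignment** with centres fixed — a linear program with
   transportation structure, solved exactly by successive shortest
   augmenting paths (`solve_assignment()`). The reduction: each cluster
   gets a quota column of capacity `τ_h`; a free column of capacity
   `m − Στ` with per-point cost equal to its nearest-centre cost absorbs
   the rest, and free points map back to that nearest centre. Because the
   transportation polytope has integral vertices, the exact LP optimum is
   reached with hard (0/1) assignments;
2. **centroid update** — each non-empty cluster's centre moves to the mean
   of its members; an empty cluster (possible only with `τ_h = 0`) keeps
   its centre.

Both steps weakly decrease the objective, so the algorithm converges to a
local optimum; it stops when no centre moves more than `tol` (default
1e-6 km) or after `max_iter` (default 100) iterations. Initialisation is
seeded k-means++; with all `τ_h = 0` the procedure reduces exactly to
Lloyd's k-means, which the tests verify against `stats::kmeans`. Defaults
for real use: `k` is user-supplied (barrier structure is not auto-detected)
and `τ_h = floor(0.8 · m / k)`, i.e. clusters of roughly equal size.
Degenerate ties in the assignment resolve to the lowest cluster index.

### Scenario comparison

Deployment modes are contrasted as 2×2 proportions (visited households out
of total; treated children out of eligible) with the χ² test. The Yates
continuity correction is the default: at these denominators (a few hundred)
the corrected and uncorrected statistics differ visibly, and the corrected
form is the one under which the reference village contrasts reproduce; an
`correct = FALSE` escape hatch is provided. Uncertainty on per-day optima
(children treated per day, km walked per day) uses t-distribution
confidence intervals (`mean_t_ci()`).

The pipeline's three scenarios: `current` walks a seeded random order at
12.5 min/child — an *emulation* of un-mapped walking, not a claim about any
real CHW's route; `microplan_a` uses the optimised itinerary and 8.5
min/child with the workforce unchanged; `microplan_b` additionally raises
`chw_pairs` to `unmet_needs / 2`, the exact level at which the full village
fits the window (an integer ceiling is a caller-side choice; the fractional
value is reported because workforce needs are meaningfully fractional when
pairs can split time across villages).

## Inputs

### Population rasters

High-resolution settlement layers store estimated persons per ~30 m pixel.
`extract_households()` adopts the pixel = household equivalence: every
pixel holding at least `min_persons` (default 1) becomes one household at
the pixel centre, with family size the pixel value rounded to the nearest
integer, floored at 1 (households cannot be empty; sub-1 values are density
artefacts). Whether neighbouring populated pixels should merge into one
compound is an open question of the source data; the package does not
merge. Under-5 counts then follow the allocation rule below. The raster
interface reads and writes the plain-text ESRI ASCII grid format and
in-memory `population_grid` objects (north-up, square pixels, WGS84
pixel-centre convention); `rasterize_village()` inverts the extraction for
round-trip validation.

### Under-5 allocation

A fraction `under5_fraction` (default 0.18) of the population is under 5.
Per household that expectation (`0.18 × family_size`) is fractional, so
integer counts are produced village-wide by largest remainder: floor every
household's expectation, then give one extra child to the households with
the largest fractional parts until the village total equals
`round(0.18 × population)`, ties broken by household order. This preserves
the village-level denominator exactly (the quantity the coverage formula
divides by) while giving simulatable per-household integers.

### Synthetic villages

`generate_village()` emulates the three dispersion regimes seen across
rural study villages, in a square footprint of `extent_km` (default 2 km):

* **uniform** — jittered grid (evenly spaced compounds): grid cells of
  `extent/⌈√n⌉`, jitter ±15% of a cell;
* **random** — homogeneous uniform placement (Poisson-like spacing);
* **clumped** — `n_clumps` centres on a ring of radius `0.35 × extent`
  (guaranteed mutual separation — the implicit stand-in for groups divided
  by a river; no barrier geometry is modelled, matching how such villages
  are handled operationally: by clustering, not by routing around water),
  households Gaussian-scattered around them with sd `0.08 × extent`.

Family sizes are zero-truncated Poisson with mean parameter 6 (small
positive integers resembling per-pixel person counts; the draw is by
inverse CDF, so it is exact and the realised mean sits slightly above 6).
Coordinates are generated in a local km frame and anchored to WGS84 at a
configurable origin (default in centre-west Burkina Faso), so both the
metric and the geographic distance paths get exercised.

The tests assert the dispersion ordering on the *relative* variance (CV²)
of nearest-neighbour distances — uniform < random < clumped, averaged over
20 seeds. The relative form is used because aggregation shrinks the mean
spacing and with it the absolute variance: raw NN-distance variance of a
tight clumped pattern is *smaller* than random, and the scale-free
statistic is the standard way spatial point-pattern analysis expresses
regularity vs aggregation.

What the generator does **not** emulate: real settlement rasters' spatial
autocorrelation of family sizes, compound structure (multiple households
per courtyard), roads and footpath networks, or barrier geometry. Passing
tests on synthetic villages therefore validate the algorithms and the time
accounting, not predictions for any particular real village — real-village
results additionally depend on the fidelity of the household extraction.

## Numerical choices

* Distances in km throughout; times in minutes at the interface, workdays
  internally.
* Held-Karp backtracking uses a relative tolerance of 1e-9 when matching
  subset-table entries (floating-point sums of distances are not exactly
  associative).
* The budget check in `simulate_campaign()` admits a household within
  1e-12 days of the remaining budget, so staffing a village at exactly its
  unmet-needs level yields exactly 100% coverage under deterministic
  timing.
* 2-opt uses first-improvement sweeps with a 1e-12 improvement threshold;
  nearest-neighbour and which-min ties take the smallest index.
* Report tables round times to 2 decimals, coverage to 1, CHW needs to 2;
  internal arithmetic is full precision.
* Degenerate inputs: single-household villages route trivially (length 0);
  an all-empty raster extracts an empty village with a warning, not an
  error; a 2×2 comparison with a zero margin (e.g. both scenarios at 100%)
  is defined as χ² = 0, p = 1.
* All randomness (placement, family sizes, treatment draws, heuristic
  starts, k-means++ seeding) flows through explicit integer seeds, and
  seeded operations restore the caller's RNG state.

## Problem sizes in the test suite

The suite validates exactness by enumeration where enumeration is
feasible: routing against brute force on 100 random instances of 4–8
households (and path ≤ cycle on 7-household instances), the heuristic
against the exact solver on 50 instances of 6–10, constrained assignment
against exhaustive label enumeration at m ≤ 8 and against an independent
LP solution at m = 12, and campaign properties on villages of 15–50
households. These sizes make every oracle exact and keep the default test
run fast; the algorithms themselves run comfortably at real-village scale
(a few hundred households) through the heuristic path.

## Limitations

* Walking distances are straight-line; road- and trail-network routing
  (and hence urban settings with excessive clustering) are out of scope.
* Only day-1 delivery is modelled; adherence to the day-2/3 doses
  administered by caretakers is assumed, and refusals, vomiting and
  absences are not modelled.
* The pixel = household equivalence inherits any error in the settlement
  raster, and census-grade validation of extracted population sizes is
  outside the package.
* Cluster counts for barrier-split villages are user-supplied; barriers
  are not detected from map data.
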