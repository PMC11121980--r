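---
title: "Methods: wind-borne trajectory simulation and trap-catch phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wind-borne trajectory simulation and trap-catch phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothtrack)
```

## The problem this package addresses

Nocturnal moths such as the common cutworm (*Spodoptera litura*) migrate
hundreds of kilometres per night by climbing to a few hundred metres above
ground and drifting downwind. Where a trapped population came from
(backward question) and where an emigrating population will land (forward
question) can be inferred by integrating virtual insects through gridded
wind fields, constrained by the insects' biology: they take off shortly
after sunset, must land by dawn, fly at roughly fixed heights within the
100–1000 m band, and do not initiate flight in air colder than a species
threshold. `mothtrack` implements that biologically gated Lagrangian
simulation together with the statistics used on multi-year searchlight-trap
records: monthly catch summaries, sex-ratio chi-squares, optimal
segmentation of the seasonal catch curve into migration periods, and
ovarian development summaries.

## Trajectory model

A trajectory at altitude $h$ is the sequence of positions
$\mathbf{x}_{i+1} = \mathbf{x}_i + \mathbf{V}(\mathbf{x}_i, h, t_i)\,
\Delta t$, where $\mathbf{V} = (u, v)$ is the horizontal wind interpolated
from the grid and $\Delta t$ is 10 minutes by default. Key assumptions,
each of which is a deliberate simplification:

* **Passive drift.** Displacement equals the wind vector; the moth's own
  airspeed and heading are not modelled. Radar studies show migrating
  moths align with the flow, but self-powered flight of 3–5 m/s means
  real tracks can deviate; results are transport envelopes, not exact
  paths.
* **Fixed flight layers.** One trajectory per altitude in
  `trajectory_params()$altitudes_agl` (default 100–1000 m every 100 m,
  metres above ground level); no vertical motion. Layer-to-layer spread
  substitutes for unmodelled climb/descent behaviour.
* **Flat-earth step conversion.** Metres convert to degrees via
  111,320·cos(latitude) m/° longitude and 110,574 m/° latitude. At the
  ≤700 km nightly scales involved the great-circle correction is far
  below the wind-field uncertainty.
* **Temperature gate.** Flight is initiated only when the air temperature
  at the release point and time is at least the threshold (default
  13.1 °C, the critical flight temperature of the congeneric fall
  armyworm, used for lack of a species-specific value). The published
  description is ambiguous about whether the threshold applies
  continuously in flight; `temp_gate = "takeoff_only"` is the default and
  `"continuous"` is available. The gate is strict: air at 13.0 °C grounds
  the moth, at 13.2 °C it flies.
* **Termination.** `window_end` when the nightly flight window is
  exhausted; `boundary_exit` the first time the next proposed step would
  leave the grid hull (the last inside point is kept — endpoints
  accumulating along the domain edge are a known artefact of
  boundary-stopping, not landings); `temperature_stop` for gated runs.
  The endpoint of a trajectory is its latest point.

Backward runs answer "where did tonight's arrivals take off?": time runs
from the landing deadline back toward take-off with the velocity sign
flipped, sampling the same stored fields. In a steady field a backward run
exactly retraces the forward run; the tests assert this symmetry.

Euler integration with the 10-minute step is the default and the
configuration used for all headline numbers; a midpoint integrator is
included only for sensitivity checks. With hourly fields and 10-min steps
the Euler error is negligible against field uncertainty.

## Flight windows from the solar ephemeris

Take-off is sunset + 20 min and the landing deadline is next sunrise −
10 min, the observed peak take-off and landing times for migrating
noctuids; both offsets are parameters. Sunrise/sunset use the NOAA
closed-form solar position at zenith 90.833° (refraction plus solar disc)
with two refinement passes, accurate to well under a minute against a
numerical ephemeris; the test suite checks ≤2 min agreement with an
independently implemented almanac-based root-finder on a 50-case grid.
Published window times for the study site (20:04/06:38 spring peak night,
18:59/07:15 autumn) derive from a third-party almanac with an unknown
reference convention (possibly a different reference point or elevation
correction); our computation lands about 10 min later consistently, so the
published values are treated as fixtures at a documented ±15 min, not
exact oracles. Site elevation correction is off by default. The published
site coordinate string uses minute values above 59, so it is read as
decimal degrees (23.98° N, 97.83° E).

## Atmosphere data model

`wind_grid` holds $u$, $v$ (m/s) and temperature (°C) on a regular
time × height × lat × lon grid; heights are metres above ground level so
the flight layers match the biology directly (terrain-following conversion
from pressure levels is upstream preprocessing, out of scope). Sampling is
quadrilinear — linear in each axis over the 16 enclosing corners — the
simplest scheme consistent with hourly, ~10 km data, and exactly testable
against a brute-force corner-sum oracle. I/O is CF-style NetCDF; Kelvin
temperatures and descending axes are normalised at read time. Longitudes
live in [−180, 180) with no antimeridian wraparound (the study region is
far from it).

Two synthetic generators make the engine testable without mesoscale-model
output: `make_uniform_field()` (closed-form displacement) and
`make_monsoon_field()`, an idealised seasonal monsoon — southwesterly in
spring, northeasterly in autumn, linear lapse rate, optional smooth seeded
perturbation bounded to 40% of the mean flow so component signs never
flip. These emulate the *directional* structure that carries the
migration; they deliberately lack fronts, terrain channelling, diurnal
boundary-layer cycles and vertical shear, so passing tests validate the
machinery, not any real-world attribution.

## Region attribution

Endpoints are classified with even-odd ray casting (east-pointing ray;
vertices at the query latitude nudged by 1e-12° so the ray never hits a
vertex; points exactly on an edge count as inside). Multi-part regions and
holes fall out of even-odd membership over all rings. A point on a shared
boundary belongs to the first region in priority order; everything
unclaimed is `"other"`. The shipped four-rectangle fixture is synthetic —
real national borders must be supplied by the user as GeoJSON.

Attribution tables count endpoints per region within direction × season
cells; percentages are rounded half-up to one decimal, matching how such
tables are printed. Aggregation (e.g. a combined South Asia share) sums
the rounded percentages, which is how the derived shares in the source
tables are arithmetic-consistent. Attribution defaults to trajectory
endpoints only; `trajectory_points()` supports the all-points variant
since published tables do not state which convention was used, and the
table metadata records the mode.

Season labels follow the segmentation of the observed catch curve:
April–May spring migration, October–December autumn migration, all other
months transition.

## Trap-catch statistics

* **Monthly summary:** per calendar month, the mean over years of the
  monthly female total ± SE, the mean female percentage, and the pooled
  1:1 chi-square. The grand total is the sum of the monthly means.
* **Sex ratio:** the two-cell Pearson statistic $(F-M)^2/(F+M)$ on 1 df,
  no continuity correction by default (a Yates flag exists). Reconstructed
  published rows match only approximately because printed female
  percentages are rounded.
* **Optimal partitioning of ordered samples** (`fisher_partition()`):
  exact dynamic programming over contiguous partitions minimising total
  within-class sum of squared deviations, with z-score standardization by
  default. Ties break toward the leftmost boundaries (candidate cuts
  scanned in ascending order, strict improvement required), which also
  fixes the documented behaviour for constant series. The published
  segmentation software's normalisation of the error function is
  undocumented, so published error values are not oracles; correctness is
  established against exhaustive enumeration of all contiguous partitions
  (n ≤ 12, k ≤ 5, 100 random series). `segmentation_scan()` reports the
  error curve over k and suggests the k with the largest relative drop.
* **Ovary summaries:** per period, the mated rate (≥1 spermatophore),
  matured rate (ovarian development level > 2 on the 5-level scale), mean
  level and mean mating count. Periods may be daily or monthly upstream;
  the summary only needs a date → period map.

Routine inferential machinery (ANOVA, Tukey, normality tests) is
deliberately left to base R and is not re-implemented here.

## Synthetic trap-catch generator

`generate_catches()` draws nightly totals from a negative binomial
(overdispersion is the norm for light-trap counts; `dispersion = Inf`
recovers Poisson) around a seasonal mean of baseline plus two Gaussian
day-of-year bumps with year-end wraparound. Defaults encode the study
conditions: five years of nights, a dominant spring peak centred in late
April (day 118, width 16 d, amplitude 120) and a smaller autumn peak in
early November (day 310, width 22 d, amplitude 35), monthly female
fractions set to the observed monthly percentages (peaking at 0.604 in
April), and period maturity/mating parameters set to the observed spring
vs autumn contrasts (matured 0.923/0.742, mated 0.833/0.629; transition
values chosen between them). Amplitudes and widths are not published;
these choices give April–May mean catches above 100/night against a
single-digit winter baseline, the qualitative shape reported. Twenty
females per night (or all, when fewer are caught) receive dissection
records, mirroring the field protocol's cap. Mating counts for mated
females are zero-truncated Poisson with rate 1.6, giving a mean mating
frequency near the observed 1.5–2.2.

The generator emulates seasonal structure, overdispersion and the
dissection protocol; it does not emulate weather-driven night-to-night
correlation, moonlight/trap-efficiency effects, or interannual trend, so
recovery tests demonstrate the statistics' correctness, not field
realism.

`generate_endpoint_cloud()` inverts the attribution: given a percentage
table it samples exactly the implied counts inside each fixture polygon
(columns printed to one decimal that sum to 99.9 are completed to the full
point count with points outside every region), so published tables
round-trip exactly through the classifier at n = 1000 per column.

## Numerical and design choices

* Problem sizes in the tests and the acceptance script: interpolation
  oracle on 50 random queries; 50-case solar grid; segmentation oracle on
  100 random series (n ≤ 12, k ≤ 5); 100-seed spring-block recovery on
  5-year daily series; 1000-point attribution clouds; 20-seed × 1000-point
  geometry oracle. These sizes give stable verdicts in seconds per suite.
* Percentages round half-up (base `round()` is half-to-even and would not
  reproduce printed tables).
* All instants are UTC `POSIXct` internally; site clock times come from a
  fixed UTC offset, never the OS timezone database, so results are
  identical across machines.
* Seeds: every stochastic entry point takes an explicit seed and records
  it; identical configs give byte-identical CSV output.
* Degenerate inputs: constant series skip standardization with a warning
  and report zero error; empty attribution groups are dropped with a
  warning; per-run batch failures are collected, not fatal.

## Known limitations

Real attributions need real meteorology: the monsoon generator cannot and
does not attempt to reproduce published percentage tables from simulation
— those enter only as round-trip fixtures for the attribution arithmetic.
No multi-night trajectory chaining, no landing-probability model beyond
the hard dawn deadline, no self-powered flight vector, no lunar or trap
efficiency modelling. The even-odd classifier assumes polygons that do not
self-intersect.
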