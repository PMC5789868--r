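---
title: "Rule-based quality control for acoustic telemetry detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based quality control for acoustic telemetry detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagqc)
```

## The screening problem

Passive acoustic telemetry records a detection whenever a coded transmitter
is heard by a receiver. At network scale these archives are contaminated by
tag-collision "false detections", duplicate historical transmitter IDs, and
metadata errors (wrong release dates or positions). None of these can be
caught by looking at a single record: the evidence is in the *pattern* of a
tag's detections — how often it was heard at an installation, how far and how
fast it would have had to travel between consecutive receivers, and whether
the positions make ecological sense for the species. `tagqc` encodes those
patterns as seven per-detection tests and one composite grade per detection.

Flags follow a common convention: 1 = passed, 2 = failed, 3 = test not
performed (only for the two tests that need an expert species distribution).
`Detection_QC` counts passes among the five detection-level tests (FDA,
Distance, Velocity, DetectionDistribution, DistanceRelease): 5 passes → 1,
4 → 2, 3 → 3, ≤ 2 → 4. A flag of 3 counts as "not passed" in the composite:
a tag whose species has no distribution map can be at best "likely valid",
which matches how unresolved distributions are treated operationally.
`ReleaseDate_QC` and `ReleaseLocation_QC` are reported alongside but not
composited.

## Tests, parameters and defaults

All tunables live in `qc_config()`:

| parameter | default | meaning |
|---|---|---|
| `fda_long_interval_s` | 12 h | "long" absence between consecutive detections at an installation |
| `fda_short_interval_s` | 30 min | "short" interval typical of a resident animal |
| `distance_threshold_m` | 1,000 km | neighbour-distance cutoff (strict >) |
| `velocity_threshold_ms` | 10 m/s | swim-speed cutoff (strict >), from the fastest tracked species |
| `distribution_buffer_m` | 500 km | geodesic buffer on species distributions |
| `release_radius_m` | 500 km | inclusive radius around the release point |
| `release_date_grace_s` | 24 h | pre-release grace, absorbing time-zone slack in reported release dates |
| `simultaneous_dt_s` | 1 s | interval substituted for simultaneous detections |

Decisions worth spelling out:

* **FDA counting.** Intervals are computed within each installation;
  intervals in [30 min, 12 h] count for neither side, and a group fails only
  when long intervals strictly outnumber short ones (a tie passes). The
  single-detection rule is applied per installation, not per deployment.
* **Endpoints and vacuous cases.** The first/last detection of a deployment
  has one neighbour and is judged on it alone; a deployment's sole detection
  passes the distance and velocity tests vacuously (its implausibility is
  already captured by the FDA single-detection rule).
* **Strictness.** Distances exactly at 1,000 km and speeds exactly at
  10 m/s pass; a detection exactly 500 km from release passes (inclusive
  radius).
* **Release-date grace.** The 24 h default is a deliberate, configurable
  choice: release timestamps are frequently entered in local time, so up to
  a day of apparent pre-release detection is treated as clock slack, not
  evidence of error.
* **Release-location test.** Two checks feed it (release inside the
  buffered distribution; release within 500 km of the first detection,
  taken as the chronologically first record regardless of its own flags).
  If neither check is evaluable the flag is 3; if any evaluable check passes
  it is 1; otherwise 2 — including the case where only one check is
  evaluable and fails.
* **Distribution buffer.** The allowance for range shifts and mapping error
  is implemented as a uniform 500 km geodesic buffer around the distribution
  polygons (distance to the polygon boundary), rather than an extension of
  the latitudinal extent only; the uniform reading is symmetric and
  direction-free, and the buffer distance is configurable.
* **Dual-sensor tags.** A physical tag can carry two transmitter IDs with
  separate sensor calibrations. The two detection streams are aggregated
  into one chronological series for all movement tests, while sensor
  conversion (`slope × raw + intercept` on the 0–255 ADC payload) is applied
  per transmitter. Output files are still written per transmitter ID.
* **Deployment assignment.** When a tag is re-deployed, a detection is
  assigned to the latest release dated at or before it; detections that
  precede every release go to the earliest release, so pre-release
  screening can flag them.

## Over-water distances

"How far did the animal travel?" is only meaningful through water. The
seascape module rasterises land polygons over a lon/lat bounding box (cells
whose centre falls on land are land; default resolution 0.05°, configurable)
and connects water cells into a graph whose edge weights are great-circle
distances between cell centres.

* **Straight vs least-cost.** For each unique station pair ("trip"), 200
  positions are linearly interpolated in lon/lat between the stations,
  endpoints included. If all are over water the trip distance is the
  haversine distance; otherwise it is the shortest path through the water
  graph (Dijkstra, implemented in C++), never less than the great-circle
  distance.
* **Connectivity.** The default graph uses 16 neighbours (the 8 adjacent
  cells plus knight's moves), which caps the grid-metric inflation of
  shortest paths at roughly 8% worst case — in practice ~3–4% around the
  test fixtures; 4- and 8-neighbour graphs are available.
* **Snapping and ties.** Stations on coarse rasters can fall on land cells;
  they snap to the nearest water-cell centre, with equidistant candidates
  resolved to the lowest (row, column). The same tie-break applies to
  nearest-coastline queries.
* **Rivers.** Rasters adequate for the open coast are too coarse for small
  river systems, so river geometry is handled explicitly: two river stations
  on the same installation use the straight-line distance; a river station
  paired with any other installation is routed by a straight leg to its
  nearest coastal cell (a water cell with a land 8-neighbour), and the
  over-water rule is applied between the coastal points; the trip distance
  is the sum of the legs.
* **Disconnected basins.** If no over-water path exists between two snapped
  cells, the trip distance is infinite and the distance test fails: a
  detection demanding travel between unconnected water bodies is
  implausible.
* **Caching.** Trips are memoised per unordered station pair (distances are
  symmetric by construction), because tags revisit the same trips many
  times. The cost surface itself is built once per run and kept in memory —
  at the raster sizes this package targets the build takes well under a
  second, so no on-disk cache is maintained.

All spherical computations use a 6,371 km sphere; at the 10–1,000 km scales
of these tests the difference from ellipsoidal geodesics is far below every
threshold. True geodesics, currents and bathymetry-aware costs are
non-goals.

## The synthetic generator

`simulate_scenario()` exists so every QC behaviour has a test fixture with
known ground truth. It emulates: an analytic seascape (all-water box, a
1°×1° square island in a 10° box, a bay with one mouth, a coast pierced by a
one-cell river channel) whose rasterisation is exactly predictable; a
deterministic station network (installations as north–south curtains of
stations 800 m apart, the spacing used in real gate designs); one animal per
deployment following a correlated random walk (fixed 60 m step per 60 s,
turning s.d. set by a concentration parameter, resampled until the step
lands on water) with home attraction beyond 2 km of its installation;
Bernoulli-per-step detection (p = 0.8) at the nearest station within a
300 m detection range (inside the 60–950 m envelope of field receivers);
and injected contamination carrying hidden truth labels in a sidecar file,
never in the detection data.

The geometry is chosen so recovery is provable, not lucky:

* station spacing (800 m) exceeds `2 × range + 2 × step` (720 m), so two
  different stations can never detect the animal on consecutive steps; with
  the 1 m/s swim speed this bounds every clean between-station speed well
  below 10 m/s;
* teleport stations sit in the opposite corner of a 45°×35° open-water box,
  > 3,000 km from the clean cluster, and each teleport is sandwiched
  mid-gap between two interior clean detections, so both its neighbour
  distances exceed 1,000 km by construction; far injections are kept at
  least two gaps apart so no clean detection ever has far records on both
  sides;
* pre-release detections are placed 10 days before release at a dedicated
  station next to the release point (beyond any grace window, but too close
  and slow to trip the movement tests);
* single-hit false detections get a new one-station installation each and
  prefer long gaps, so they fail the FDA and nothing else.

What the generator does **not** emulate: detection-range variability with
environment, home ranges and migration phenology, receiver outages, clock
drift, and multi-animal tag collisions as a physical process. Passing the
recovery tests therefore demonstrates that the *rules* are implemented
correctly and recover planted violations under realistic scales — not that
the thresholds are optimal for any particular real network.

Problem sizes in the shipped tests: seascapes up to 100×100 cells
(least-cost oracle), default scenarios of 6 deployments × 3,000 one-minute
steps (~1,800 detections, 40 injected records), chosen as comfortable
desk-scale analogues of the statistics the procedure targets.

## Determinism

Every random draw in a scenario derives from its single seed; identical
seeds give byte-identical interchange files. The QC run itself is
deterministic: detections are canonically ordered (transmitter, time,
station — the station tie-break fixes simultaneous detections), ties in
snapping are resolved by grid order, and re-running on identical inputs
reproduces every data output byte for byte (the manifest differs only in
its wall-clock fields).

## Known limitations

* GeoJSON is the only polygon interchange format (no shapefile reader), and
  polygon holes are ignored.
* The land/water raster is lon/lat-regular, so cell geometry is anisotropic
  at high latitudes; at the mid-latitudes of the intended use this only
  mildly varies the grid inflation of least-cost paths.
* The FDA is the rule-based screen described above, not a statistical
  false-positive model; sentinel-tag and detection-efficiency analyses are
  out of scope.
* `crosses_land()` interpolates linearly in lon/lat (not along the great
  circle), matching the definition of the 200-point test; over ~1,000 km
  the two lines can diverge by a few kilometres, which the raster resolution
  absorbs.
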