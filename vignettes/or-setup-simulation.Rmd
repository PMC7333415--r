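---
title: "Simulating and comparing operating-room setups for arthroplasty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and comparing operating-room setups for arthroplasty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsim)
```

## The problem

In joint-replacement surgery (total hip and total knee arthroplasty, THA and
TKA), the arrangement of instrument tables and staff around the OR table is
usually set by habit or personal preference, yet it determines how far the
scrub nurse and surgeon must twist for every instrument handover, how long
each handover takes, and how far the circulating nurse walks for supplies.
`orsim` provides a desk-scale simulation of exactly these three quantities so
that alternative setups can be compared objectively before anything is moved
in a real OR. The package bundles seven setups used or proposed at a
university orthopedic department (four TKA, three THA; each in a left-side
and a mirrored right-side variant) and a synthetic surgery-log generator
matched to the summary statistics recorded intraoperatively around those
setups.

## Geometry

Everything is planar (schematic top view), in metres, with the origin at the
room's south-west corner. A `floor_plan` holds the *room-fixed* world:
axis-aligned rectangular obstacles (wall desks, supply racks, anesthesia
equipment) and named destination points (working places `WP1`/`WP2`, racks
`R1`/`R2`, supply stocks `ST1`/`ST2`, the anesthesia room `AR`, doors).
Obstacles are rectangles only; the source schematics contain nothing that
needs polygons, and rectangles keep rasterization and validation exact. A
`layout_setup` adds the movable part: the OR table (whose long axis defines
the mirror line), three or four instrument tables, each with an angular
position relative to the scrub nurse's neutral facing (the conventional 0,
45, 90 and 180 degree positions), and staff poses.

`mirror_layout()` reflects furniture and staff across the OR-table axis and
toggles the side flag, while the floor plan stays put. This asymmetric
treatment is deliberate: the room does not move when the team switches from a
left-side to a right-side operation, and it is precisely what makes circulator
travel differ between sides (the mirrored table cluster can seal a passage
that is open on the other side) even though handover times and ergonomics are
mirror-invariant.

The bundled fixtures are scale reconstructions: the source material publishes
schematics and qualitative statements (which passages are tight, which table
blocks which working place), not coordinates. Fixture coordinates were
authored once, in `data-raw/layouts.R`, to a 6.5 m x 6.5 m room such that
those qualitative statements hold; absolute distances are therefore
reconstruction choices, and only orderings and mirror relations should be
interpreted.

## The TRM ergonomics score

For one instrument table, a handover cycle involves three torso rotations:
the nurse turns to the table (angle $\alpha$), turns back to the surgeon
($\beta$), and the surgeon turns to the nurse ($\gamma$). Each rotation is
executed $i, j, k \in \{0, 1, 2\}$ times (two in the normal case - out and
back), giving the per-table score

$$\mathrm{TRM}_{table} = i\alpha + j\beta + k\gamma,$$

and the setup score is the sum over its instrument tables; lower is better.
`derive_rotation_specs()` takes $\alpha$ from the table's angular position
and computes $\beta$ and $\gamma$ as unsigned viewing angles from the staff
poses, so the score needs no measured angles. Unsigned angles make the score
mirror-invariant by construction. The published per-setup totals (1890 to
900 degrees) are not reproducible without the per-table angle tables, which
were not published; what the package reproduces - and what the tests
assert - is the *ranking*, in particular that the redesigned Setup 3 is
minimal for both procedures. A `turn` parameter selects whether off-axis
tables are reached over the shorter direction or always over one shoulder,
mirroring the a/b variants of the published assessment.

## Handover times

The per-handover duration is a reconstruction of a human-motion simulation
whose internals are not public:

$$\mathrm{iht} = \frac{\alpha + \beta + \gamma}{\omega}
  + \frac{d_{pass}}{v} + t_{grasp} + t_{transfer},$$

with torso rotation speed $\omega$ (default 180 deg/s, a comfortable
standing half-turn per second), arm speed $v$ (1.0 m/s), grasp and transfer
constants (0.3 s and 0.2 s) and the nurse-surgeon distance clipped to an arm
reach of 0.8 m. The defaults were chosen once, for plausibility; they
reproduce the measured *ordering* (the 0-degree table is fastest, the
far/180-degree table slowest) but not the measured seconds, and
`calibrate_motion()` exists precisely to fit $\omega$ and the additive
constant to measured per-table times by least squares. Within one layout the
model is linear in $(\alpha+\beta+\gamma)$, so the calibration is solved in
closed form and polished numerically only when the closed-form solution
leaves the feasible (all-positive) region.

Total handover time per surgery is the count-weighted sum over tables,
scheduled sequentially on a monotone clock (recorded handovers never
overlap). Counts may be fractional because recorded studies report
per-surgery means; the total is then an expected value.

## Circulator travel

Travel is simulated on a rasterized floor plan: cells intersecting any
obstacle or furniture footprint inflated by the agent radius are blocked
(defaults: 0.10 m cells, 0.30 m radius). Paths are optimal 8-connected grid
paths (straight moves cost one cell, diagonals $\sqrt2$ cells), which
overestimate true Euclidean shortest paths by at most ~8.3 %. Rather than a
per-node heap search, the planner computes the full distance field by
vectorized label-correcting relaxation (a Dijkstra fixed point evaluated as
repeated `pmin` over shifted matrices) - in R this is both faster and easier
to audit than an explicit priority queue, it gives bit-for-bit deterministic
results, and one field serves all destinations of a trip profile. Paths are
extracted by backtracking the field with a fixed neighbour order.
Line-of-sight smoothing is deliberately absent so lengths are reproducible.

Trips are independent round trips from `WP1` (the circulator's working
place), because recorded data are per-destination counts, not tour
sequences. `ST1` lies outside the OR; it is modelled as the OR door plus a
fixed corridor allowance (4 m each way, configurable) since no drawing of
the corridor exists. A destination with no collision-free path raises an
error naming it - silently substituting a detour constant would hide a
modelling problem. `rasterize()` warns when a passage wide enough for the
agent (width $> 2r$) is within one cell of closing, the regime where grid
resolution can spuriously seal a corridor.

## Requirement lint

Four of the design requirements collected for arthroplasty setups are
geometric enough to check mechanically: a table within the surgeon's reach
(1.0 m), no table behind the surgeon (viewing angle at most 90 + 10 degrees),
circulator corridors keeping 1.0 m clearance from instrument tables (the walk
up to the scrub nurse is excluded - handing supplies to her is necessarily
close), and tables within 2.5 m of the OR table's protected air field. The
thresholds are package defaults chosen from the narrative descriptions
("less than 1 m distance" being flagged as a problem); findings are
advisory pass/warn records with the measured value, never errors, because
the historically used setups violate several requirements by design.

## The synthetic surgery-log generator

No per-surgery records are deposited; published are means and SDs of
per-table handover counts, per-destination circulator trip counts, and the
incision-to-begin-of-closure time (IBCT), for cohorts of 7-15 surgeries.
`surgery_log_preset()` carries exactly those printed values; redesigned
setups without recorded counts of their own reuse the initial setup of the
same procedure and table count, which is also how the original simulation
experiments were fed.

Counts are generated as `round(max(0, N(mu, sigma)))` and IBCT as a normal
floored at 10 minutes. One subtlety matters: several presets have SDs close
to or above their means (e.g. 5.7 +/- 7.3 handovers), and for those, flooring
a normal drawn directly at the printed mean/SD would inflate the generated
mean by up to ~0.9 events - the generated cohorts would then *not* have the
printed statistics, defeating the generator's purpose. The generator
therefore moment-matches: it solves for the pre-floor $(\mu, \sigma)$ such
that the floored-and-rounded variable has exactly the printed mean and SD,
using exact censored+rounded normal moments (CDF sums over the integer
support) and a multi-start Nelder-Mead solve. For well-separated presets
this reduces to the identity. The THA trip preset to `ST1` is printed as
0.3 +/- 6.6 - an SD 22 times the mean, almost certainly a misprint; it is
kept verbatim (the moment match represents it as rare large excursions) but
flagged `suspect` and excluded from recovery tests.

What the generator emulates is the first two moments and non-negativity of
integer counts - nothing more. Real logs have correlations (long surgeries
have more handovers), day effects, and heavier tails; none of that is
represented, so tests passing on synthetic cohorts demonstrate that the
pipeline's arithmetic and statistics are correct, not that the package has
clinical predictive validity.

## Comparing setups

`summarize_sample()` and `t_test_two_tailed()` follow the reporting
conventions of the evaluation study (mean +/- sample SD; two-tailed t-test).
Welch's test is the default because the compared cohorts have unequal sizes
and no variance-homogeneity argument exists; Student's pooled variant is
selectable. Zero-variance corner cases follow a documented convention
(p = 1 for equal means, p = 0 otherwise) instead of failing.
`run_pipeline()` assembles the full comparison: the scenario inventory
(setups x sides - 6 THA and 8 TKA models for the bundled fixtures),
per-table handover times, TRM totals, travel distances, IBCT summaries,
pairwise tests, lint findings, and sim-vs-measured deltas when reference
measurements are supplied. The setup *ranking* uses the TRM total (tie-break:
simulated total handover time): TRM depends only on the layout, whereas
per-surgery handover totals also inherit each setup's historical count
profile, which would confound layout quality with case mix.

```{r pipeline, eval = FALSE}
report <- run_pipeline(c("THA1", "THA2", "THA3"), seed = 1)
report$scenarios
report$ranking
write_report(report, "tha_report.json", tables = "tha_report.txt")
```

## Numerical choices and problem sizes

* Grid: 0.10 m cells, 0.30 m agent radius; a 6.5 m room rasterizes to a
  65 x 65 lattice, on which a full distance field takes a few milliseconds.
* Path backtracking breaks ties in the fixed neighbour order E, W, N, S, NE,
  SE, NW, SW, so identical inputs give identical waypoints.
* Validation treats rectangles that merely touch as non-overlapping
  (strict-interior test); rasterization blocks cells with positive-area
  intersection.
* The test suite generates cohorts of up to 5000 surgeries and checks the
  path planner against a brute-force uniform-cost search on one hundred
  random 20 x 20 grids; both finish in seconds.
* Angles are compared and reported in degrees; all distances in metres,
  times in seconds (IBCT in minutes, following the clinical convention).

## Known limitations

* Fixture coordinates are reconstructions; absolute simulated seconds and
  metres are not comparable with the published absolute values, only
  orderings, deltas and mirror relations are.
* The handover decomposition ignores instrument-specific handling, bimanual
  transfers and anticipation by the nurse.
* Round-trip travel ignores trip chaining and any interaction between the
  circulator and the sterile team.
* The generator draws fields independently; no within-surgery correlation.
* OWAS posture scoring, hygiene/airflow assessment and satisfaction surveys
  of the original evaluation are out of scope.
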