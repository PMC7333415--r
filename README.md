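# orsim: simulation-based design and assessment of operating-room setups

`orsim` compares operating-room (OR) table setups for joint-replacement
surgery — total knee and total hip arthroplasty (TKA/THA) — the way a
workflow engineer would: encode the floor plan and the candidate setups,
score their ergonomics, simulate the instrument handovers and the
circulating nurse's supply trips, and test the differences statistically.
It is aimed at surgical-workflow and healthcare-operations researchers who
want a reproducible, scriptable alternative to commercial 3D simulation
suites for the *planar* part of the problem.

## What it computes

**Total Rotational Movement (TRM).** For each instrument table a handover
cycle costs three torso rotations — the scrub nurse turns to the table
(α), back to the surgeon (β), and the surgeon turns to the nurse (γ) —
each performed *i, j, k* ∈ {0, 1, 2} times:

    TRM_table = i·α + j·β + k·γ        TRM_setup = Σ_tables TRM_table

Lower totals mean less twisting per handover cycle. α comes from the
table's angular position (0°/45°/90°/180° relative to the nurse's neutral
facing); β and γ are computed from the staff poses.

**Instrument handover time (IHT).** A calibratable motion decomposition
`iht = (α+β+γ)/ω + d/v + t_grasp + t_transfer`, with per-surgery totals
formed from handover counts per table.

**Circulator travel.** Obstacle-aware shortest paths (8-connected grid,
octile metric, deterministic) for round trips from the working place to
supply racks, stocks, the anesthesia room and the scrub nurse; mirrored
(right-side) setups can seal passages that are open on the left, and the
travel model reproduces that asymmetry.

**Statistics.** Mean ± SD summaries, two-tailed Welch/Student t-tests,
setup rankings, and a synthetic surgery-log generator whose cohorts
reproduce the recorded per-surgery means ± SDs (handover counts, trip
counts, incision-to-begin-of-closure time) exactly, so every pipeline
stage is testable without the clinical recordings.

Seven setups are bundled as editable YAML fixtures (four TKA, three THA,
each left and right side), reconstructed to scale from published
schematics.

## Worked example

```r
library(orsim)

ly <- layout_fixture("TKA3", "left")      # redesigned TKA setup
ly
#> <or_layout> TKA3 (TKA, left side)
#>   room: 6.5 x 6.5 m, 5 obstacles, 9 destinations
#>   instrument tables: T1(0°), T2(45°), T3(90°), T4(90°)
#>   staff: SU, SN, A1, A2, AN, CIRC

trm_setup(derive_rotation_specs(ly))
#> <trm_result> total 581 deg
#>   T1: 33 deg
#>   T2: 123 deg
#>   T3: 213 deg
#>   T4: 213 deg
```

581° of torso rotation per full handover cycle — the lowest of the four
TKA setups (the initial setup scores 1390°), which is why this layout was
adopted. Handover and travel simulation, driven by a synthetic cohort
matched to the recorded counts:

```r
cfg <- surgery_log_preset("TKA", "TKA1", n_surgeries = 5000, seed = 1)
coh <- generate_cohort(cfg)
summarize_sample(coh$ibct)
#> <sample_summary> n = 5000, 71.05 +/- 21.22     # recorded: 71.1 +/- 20.7 min

counts <- colMeans(coh[paste0("handovers_", c("T1", "T2", "T3", "T4"))])
names(counts) <- c("T1", "T2", "T3", "T4")
total_handover_time(ly, counts)
#> <handover_sim> total 173.9 s over 121 events

trips <- trip_profile(c(R1 = 4.0, R2 = 2.7, ST1 = 2.7, ST2 = 3.0,
                        AR = 2.2, SN = 7.6))
total_travel_distance(ly, trips)
#> <travel_result> total 204.6 m
#>   R1: 28.2 m
#>   R2: 42.4 m
#>   ST1: 34.9 m
#>   ST2: 15.6 m
#>   AR: 37.2 m
#>   SN: 46.3 m
```

So one average surgery in this setup costs the circulator about 205 m of
walking; per-table handover times (1.39–1.89 s) rise with the table angle.
How close is such a motion simulation to the real OR? The bundled
reference table compares published simulation results with intraoperative
measurements for the final setups:

```r
ref <- iht_reference()
tka <- ref[ref$procedure == "TKA", ]
compare_sim_measured(setNames(tka$sim, tka$table),
                     setNames(tka$measured, tka$table))
#>   T1   T2   T3
#> 0.05 0.10 0.20
```

— deviations of 0.05–0.20 s per handover. The full comparison (scenario
inventory, per-table IHTs, TRM, travel, IBCT, pairwise t-tests, lint
findings) comes from one call:

```r
report <- run_pipeline(c("TKA1", "TKA2", "TKA3", "TKA4"), seed = 1)
report$ranking    # "TKA3" first
write_report(report, "tka_report.json")
```

See `vignettes/or-setup-simulation.Rmd` for the model assumptions,
parameter choices and limitations.

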