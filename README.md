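# redoxhcs

Analysis pipeline for ratiometric roGFP high-content screening of
mitochondrial damage.

Redox-sensitive GFP (roGFP) shifts its excitation spectrum with the local
thiol redox state: oxidation raises emission under 405 nm excitation and
lowers it under 488 nm excitation, so the **405/488 emission ratio**
reports oxidation independently of expression level or gain. Targeted to
the mitochondrial matrix and imaged alongside a nuclear H2B marker (a
segmentation seed) and TMRM (membrane potential), the probe turns
mitochondrial damage into a quantitative, plate-scale readout: mock-treated
cells sit at a ratio near 0.5, and pro-apoptotic drugs raise per-cell
ratios three- to five-fold.

`redoxhcs` is for screeners and imaging scientists who want that readout
as an open, testable pipeline:

* **synthetic plates** — a fully ground-truthed generator for the
  mt-roGFP / H2B / TMRM assay (dual-excitation photophysics, crowding,
  Poisson + read noise), so every stage is testable without any download;
* **segmentation** — intensity thresholding on the roGFP channel, and
  nuclear-marker-seeded **perinuclear ring** ROIs (exact Euclidean
  dilation bands), the strategy that keeps working on confluent
  monolayers;
* **quantification** — masked ratio images, per-cell features
  (area, means, granularity, ratio), per-well summaries;
* **screen statistics** — the screening-window factor
  `z' = 1 − 3(σp + σn)/|μp − μn|`, fold-change hit calls against
  mock-treated controls, and a head-to-head Z′ comparison of the two
  segmentation modes;
* **kinetics** — nucleus tracking, biphasic change-point detection of the
  single-cell redox trajectory (BIC-selected piecewise-constant fit), and
  TMRM-loss vs ratio-rise event ordering;
* **flow** — per-event 405/488 ratios and quadrant gating against a
  second marker.

## Worked example

Simulate a small crowded screen (4 mock + 4 maximum-response wells,
45 cells per field), quantify it through perinuclear rings, and call
hits:

```r
library(redoxhcs)

cal <- probe_calibration()
cal
#> roGFP probe calibration
#>   405 nm: reduced 1, oxidized 3.5
#>   488 nm: reduced 4, oxidized 1.6
#>   baseline oxidized fraction 0.2703 (ratio 0.500)
#>   dynamic range: ratio 0.250 (reduced) to 2.188 (oxidized)

plate  <- demo_screen_plate("crowded", seed = 1, n_wells_per_arm = 4)
rec    <- analyze_fields(plate, mode = "nuclear-ring")
wells  <- well_summary(rec, attr(plate, "layout"))
screen <- call_hits(wells, attr(plate, "layout"))
screen
#> Screen result
#>   z' (per-well): 0.593
#>   negative controls: mean 0.496, sd 0.00454, n 4
#>   hits: 3 of 4 wells at fold >= 3.00
```

Mock wells recover the control-cell convention (ratio mean ≈ 0.5, e.g.
B01–B04: 0.493, 0.503, 0.494, 0.494), treated wells rise towards the
probe's ceiling with the expected cell-to-cell heterogeneity (C01–C04
means 1.36–1.65, i.e. ~3-fold over control), TMRM drops as the ratio
rises, and the assay window is excellent (z′ ≈ 0.59 with only four wells
per arm). Re-running either mode on the same images —
`compare_segmentation_zprime(plate, attr(plate, "layout"))` — shows why
the nuclear marker matters: on crowded plates intensity-only segmentation
merges touching cells and drops dim ones, and its z′ falls below the
nuclear-ring z′.

A command-line front end wraps the same functions:

```sh
Rscript exec/redoxhcs simulate --n-wells 4 --out-dir plate --seed 3
Rscript exec/redoxhcs run --plate-dir plate --layout plate/layout.csv \
        --out-dir results --seed 3
```

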