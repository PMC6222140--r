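---
title: "Methods: ratiometric roGFP high-content screening with redoxhcs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric roGFP high-content screening with redoxhcs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxhcs)
```

## The assay and its readout

Redox-sensitive GFP (roGFP) shifts its excitation spectrum with the thiol
redox state of its chromophore environment: oxidation raises emission under
405 nm excitation and lowers it under 488 nm excitation. The 405/488
emission ratio therefore reports oxidation in a gain- and
expression-independent way. Targeted to the mitochondrial matrix
(mt-roGFP) and combined with a nuclear H2B marker for segmentation and
TMRM for membrane potential, the probe supports plate-scale screening for
mitochondrial damage: mock-treated cells sit at a ratio near 0.5, and
pro-apoptotic treatments raise per-cell ratios three- to five-fold.

`redoxhcs` implements the computational side of that assay: a
ground-truthed synthetic plate generator, two segmentation strategies,
per-cell ratio quantification, plate statistics (Z′, fold-change hits),
single-cell kinetics, and flow-style quadrant gating.

## Probe model and calibration

The probe is modeled as a two-state linear blend. For oxidized fraction
$f \in [0,1]$:

$$\mathrm{em}_{405}(f) = (1-f)\,a^{red}_{405} + f\,a^{ox}_{405}, \qquad
  \mathrm{em}_{488}(f) = (1-f)\,a^{red}_{488} + f\,a^{ox}_{488},$$

with ratio $R(f) = \mathrm{em}_{405}/\mathrm{em}_{488}$, strictly
increasing in $f$ whenever $a^{ox}_{405} > a^{red}_{405}$ and
$a^{ox}_{488} < a^{red}_{488}$ (the validity condition enforced by
`probe_calibration()`).

No instrument-level calibration of the probe is published for this assay,
so the default coefficients are a stand-in constrained by two printed
anchors: the control-cell ratio of 0.5 and the three- to five-fold dynamic
range. We use $a^{red} = (1.0, 4.0)$ and $a^{ox} = (3.5, 1.6)$, which give
a fully-oxidized ratio of about 2.2 — a 4.4-fold window, comfortably
inside the envelope and away from its boundaries. The resting oxidized
fraction is found by root-finding so that $R(f_{baseline}) = 0.5$ exactly
(`uniroot`, tolerance $10^{-12}$; $f_{baseline} \approx 0.27$). The
closed-form inverse `oxidized_fraction_for_ratio()` lets the generators
specify kinetics on the ratio scale the assay reports.

## The synthetic plate generator

The generator is first-class, tested code: every downstream stage is
validated against its ground truth.

**Geometry.** Nuclei are filled ellipses (radius 7 ± 1 px by default,
mild eccentricity); the mitochondrial signal is a perinuclear annulus of
width `cyto_extent_px` (6 px) around each nucleus, textured with
per-pixel gamma speckle (shape 4, mean 1) to mimic mitochondrial
granularity; 30% of the annulus emission leaks over the nuclear footprint
(out-of-focus light). Cell centers are rejection-sampled with a minimum
spacing `crowding_px`; nuclei stay fully inside the field while cytoplasm
may clip at borders, as in real fields. Contested pixels (overlapping
cells) are assigned to the nearest nucleus center. Per-cell expression
gain is lognormal (sdlog 0.3) — even clonal lines retain expression
spread, and this spread is what makes naive thresholding hard.

**Photophysics and noise.** Expected counts are
`background + photon_scale × emission` (photon_scale 150, background 100);
pixels are Poisson-sampled at that expectation, Gaussian read noise
(sd 3) is added, and values are rounded and clipped to the detector bit
depth (16). A `noiseless = TRUE` render returns expectations with
identical geometry, which the monotonicity tests rely on.

**Kinetics.** Single-cell death follows the biphasic trajectory the
assay observes in cisplatin-treated cells: ratio constant at 0.4, step to
0.65 at `t_surge` (the moderate pre-permeabilization surge), linear ramp
to 1.2 during reporter release, and a post-release plateau (default 2.0,
within the probe's dynamic range). TMRM decays as a logistic crossing 50%
at `tmrm_half_loss_time`, before the surge by default — membrane-potential
loss is the early event. The lag between the surge and release onset and
the secondary-rise rate are not quantified in the source assay; the
defaults (20/35/50 frames) are artifact choices.

**Study conditions.** `demo_screen_plate()` freezes the two conditions
used in validation. *Crowded*: 45 cells per 256×256 field at 17 px
spacing — confluent cytoplasm with still-separable nuclei, the regime of
tight adherent epithelial monolayers — with heterogeneous positive wells
(80% responders at $f \approx 0.9$, 20% non-responders; screens show
exactly this cell-level heterogeneity). *Sparse*: 16 cells at 36 px
spacing with homogeneous maximum response. The sparse condition is
deliberately homogeneous: the claim it tests is that the two pipeline
variants agree when segmentation is unchallenged, and a mixed-brightness
well breaks that premise for reasons unrelated to crowding (dim,
405-weak cells are intrinsically harder for intensity thresholding).
Ten wells per arm are used for the crowded comparison because a Z′
difference estimated from a handful of wells is dominated by the sampling
noise of the standard deviations.

**What the generator does not emulate.** Optics (no PSF convolution;
speckle stands in for sub-resolution mitochondria), photobleaching,
illumination flatness beyond a planar gradient, cell division and
migration beyond rigid stage drift, and reporter-release imagery (release
enters only through the kinetic model). Passing tests therefore show the
pipeline is correct and robust under a faithful noise/crowding model —
not that it is validated on real microscopes.

## Segmentation

Two strategies mirror the assay's comparison:

* `segment_intensity()` — threshold the 405 nm channel, fill holes,
  8-connected labeling, minimum-area filter (50 px). On crowded
  monolayers touching cells merge into single objects; on dim cells the
  threshold fails — the documented failure modes that motivate nuclear
  seeding.
* `segment_nuclei()` + `ring_rois()` — threshold the H2B channel, fill
  holes, split touching nuclei by watershed on the Euclidean distance
  transform (peaks closer than `split_min_peak_distance_px` merge), then
  build a perinuclear ring per nucleus as the readout plane.

**Thresholding.** "Otsu" mode is the two-threshold (three-class) Otsu
variant with the middle class counted as foreground, after Gaussian
smoothing (`smooth_sigma_px = 1.5`). With realistic expression spread the
intensity histogram is multimodal, and classic two-class Otsu places its
cut *between dim and bright cells*, silently dropping dim ones; assigning
the middle class to foreground is the standard remedy. Thresholds are
computed on the image's own `[0, max]` range, so segmentation is invariant
to any positive gain. A fixed-threshold mode is kept for reproducibility
experiments.

**Rings.** The vendor vocabulary of "polygon band" segmentation is
reinterpreted morphologically: ring $k$ is the set of non-nucleus pixels
within exact Euclidean distance `ring_dilation_width_px` of nucleus $k$
(optionally eroded first by `nucleus_erosion_px`, whose vendor meaning is
unpublished; default 0). Dilation by the Euclidean disc is computed by
exact integer distance enumeration in compiled code, so the result equals
a brute-force per-pixel oracle bit for bit. Rings exclude *all* nucleus
pixels (not just their own), so every ring pixel's nearest nucleus is its
own label; contested pixels go to the nearest nucleus, exact ties to the
lower label. Connectivity is 8-connected throughout; watershed ties are
resolved by the underlying EBImage implementation deterministically, so
all maps are bit-reproducible across runs.

## Quantification

The ratio image is per-pixel 405/488 wherever the 488 denominator is at
least `intensity_floor` (default 9 counts = 3 read-noise sd); other
pixels are masked invalid, never zero or infinite. The per-cell ratio is
the mean of valid per-pixel ratios in the ROI — robust to intra-ROI
brightness variation; the ratio-of-ROI-means alternative is available via
`ratio_of_means = TRUE` since the vendor's choice is unknown, with
cell-level averaging the default at the well level for the same reason.
Granularity is the coefficient of variation of 488 nm pixel intensities
in the ROI — a simple scale-free texture statistic standing in for the
vendor's unpublished definition. The high-ratio gate defaults to the
negative-control cell mean + 3 sd, recomputed per plate; the same
convention supplies the flow-cytometry ratio gate.

## Plate statistics

Z′ follows the standard screening-window formula
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ with sample standard
deviations. Wells are the replicate unit (per-well ratio means feed the
formula); fold change is a well's ratio mean over the pooled,
cell-weighted negative-control mean, with hits at fold ≥ 3 — the typical
treated/control effect size of the assay.
`compare_segmentation_zprime()` runs the full pipeline twice on identical
images to quantify what nuclear seeding buys: on crowded plates the
intensity mode merges neighbours and drops dim cells, which biases and
destabilizes well means, and its Z′ falls below the nuclear-ring Z′ in
9 of 10 seeded replicates (sign test p ≈ 0.01), while on sparse plates
the two agree within 0.05.

## Single-cell kinetics

Nuclei are tracked by greedy nearest-neighbour linking of centroids
(links beyond `max_displacement_px` rejected; no gap closing — dying
cells do not divide). Ring trajectories are mean valid-pixel ratios per
frame. Change points are found by exhaustive least-squares
piecewise-constant fitting with 0, 1 or 2 change points and BIC model
selection ($n\log(\mathrm{RSS}/n) + p\log n$, $p = 2m+1$; an RSS floor of
$10^{-10} n \max|y|^2$ keeps exact fits comparable, and the floor tracks
the data scale so selection is shift-invariant and scale-equivariant).
A change point is the first frame of the new level; least-squares ties
break toward the earliest change point; segments are at least
`min_segment_len = 3` frames. Piecewise-constant segments (rather than
ramps) are the simplest model that separates "surge" from "drastic
secondary increase"; ramps are a possible extension.

Event ordering uses two debounced threshold crossings: TMRM loss at 50%
of the initial (baseline-window) level, ratio rise strictly above the
baseline mean + 3 baseline sd, each required to persist two consecutive
frames — with the baseline sd estimated from five frames, single-frame
noise excursions otherwise fire the gate spuriously. The signed lag
(ratio time − TMRM time) is positive when potential loss comes first; at
default noise ≥95% of simulated dying cells give a positive lag, with a
median of about 7 frames.

## Numerical conventions and degenerate inputs

Pixel coordinates are 0-based (row, col) with row 0 at the top. Blank
images segment to empty label maps, not errors; empty directories read as
empty collections; a cell with no valid ratio pixels carries a missing
ratio (empty CSV field, never a sentinel). Z′ is an error when the arms'
means coincide, and correlation is an error at zero variance — silent
zeros would masquerade as results. All generators are pure functions of
(spec, seed): one master seed yields per-field sub-seeds through a fixed
derivation, so any field can be regenerated independently.

Validation problem sizes (chosen to exercise the claims at desk scale):
256×256 fields, 16–45 cells per field, 6–10 wells per control arm,
200-replicate Monte-Carlo studies for change-point accuracy, 10,000-event
flow tables, and a 96-well determinism check at 160×160.

## Known limitations

The generator's realism bounds what green tests mean: real plates add
focus drift, vignetting, debris and segmentation-relevant morphology
changes in apoptosis (blebbing, nuclear condensation) that are not
modeled. The probe calibration is a documented stand-in, not a fitted
instrument model; absolute oxidized fractions are therefore
interpretable only within the simulation. FCS binary parsing, dose-response
fitting, multi-plate normalization, and machine-learned segmentation are
out of scope.
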