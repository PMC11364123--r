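---
title: "Methods: plan complexity, gamma analysis and the synthetic verification study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plan complexity, gamma analysis and the synthetic verification study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices
behind them: the plan model and leaf kinematics, the complexity-metric
registry, the gamma engine, the synthetic cohort and its two error
channels, and the statistics stage. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The plan model

A sliding-window IMRT plan is a set of beams; each beam is an ordered
control-point (CP) sequence: cumulative meterset fraction (0 at the first
CP, 1 at the last, strictly increasing — a zero-MU interval has no elapsed
time at fixed dose rate, so leaf speeds would be undefined; such inputs
are rejected rather than patched), per-leaf-pair positions of the two MLC
banks in mm (bank A is the larger-coordinate side; `bank_b <= bank_a`,
with a 1e-6 mm tolerance absorbing vendor round-off into exactly closed
pairs), and jaw openings. Leaf boundaries (pair edges orthogonal to
travel) follow the 120-leaf Millennium pattern in the generator: 10 outer
pairs of 10 mm and 40 central pairs of 5 mm per side. The dose rate is
stored per beam and defaults to 400 MU/min — the fixed delivery rate of
the study conditions — which makes MU proportional to beam-on time and
gives the kinematics their time axis:
`dt_n = dcmf_n * meterset / dose_rate`.

Only dynamic (sliding-window) beams are modelled. The DICOM-RT reader
excludes setup and static beams and rejects plans with no dynamic MLC
beam; arc delivery is out of scope.

## Leaf kinematics and the dynamics metrics

Speeds are `|dx|/dt` per bank leaf (cm/s); accelerations are centred
differences of consecutive interval speeds, so `n` CPs give `n-1` speeds
and `n-2` accelerations per leaf. A leaf-interval counts as *moving* above
1e-4 cm/s, preventing parked closed pairs from diluting the mean-speed
statistics. Leaf travel is reported in two variants — the mean over leaves
that move at all (`LT`) and the sum over leaves (`LT_sum`) — because
published usage is split between the two conventions; both feed the
registry, and `LT/MU` is carried separately.

The modulation indices integrate the exceedance profile of *speed
variations* — the interval-to-interval speed changes `|s_(n+1) - s_n|` —
against multiples of `sigma_s`, the standard deviation of moving-leaf
speeds:

`MI_s = ∫ Z(f) df`, `Z(f) = Σ w(v) · 1[v > f·sigma_s] / Σ w(v)`,

with `w(v) = 1 + c·v/sigma` (default `c = 1`) weighting large variations
more heavily: with a typical `sigma` of 0.2 cm/s a variation of 0.5 cm/s
receives roughly double the weight of one of 0.1 cm/s. `MI_a` repeats the
construction one derivative up. The variation-based form matters: an
index built on raw speed values is *maximal* for near-constant motion
(every speed exceeds any multiple of a vanishing sigma) and loses all
monotonicity in modulation, which we verified empirically on the
generator's complexity gradient before fixing the definition. The `f`
grid is `[0, 1]` with 1000 nodes by default; all parameters live in
`pcm_config()`.

## The metric registry

All 53 metrics are plugins over shared per-plan features; each records its
family (aperture / MU / dynamics), whether its definition is a documented
fallback, and a declared *orientation* — the sign of its association with
plan complexity. Aggregation is uniform: per-CP values are combined with
trapezoidal MU weights (`w_i = (dcmf_(i-1) + dcmf_i)/2`), which are
symmetric under time reversal and stable under splitting a CP's weight
across identical entries; beams combine into plans by meterset weighting.
Zero-area CPs are excluded with weight renormalisation.

Notable definitions and fallbacks:

* **MCS** follows the canonical interval form
  `Σ mean(AAV)·mean(LSV)·ΔMU/MU`, with the aperture-area variability
  normalised by each leaf's union opening over the beam. For a genuine
  sliding window this denominator spans the whole swept field, so even an
  unmodulated sweep sits near 0.27 rather than near 1; a truly static
  field still gives exactly 1.
* **EAM** (edge-area metric) and the **CAM** fallback are raster-based:
  the aperture is rasterised at 0.5 mm (1 mm is adequate for cohort-scale
  runs), an exact Euclidean distance transform gives each open cell's
  distance to the nearest closed cell, and `d_cc - res/2` converts
  centre-to-centre distances to edge distances (exact for axis-aligned
  edges; corner error is bounded by the raster and checked against a
  0.25 mm direct-distance oracle within 2%). EAM is the open-area fraction
  within 5 mm of an edge; the CAM fallback averages `exp(-d/5 mm)` and is
  flagged as a fallback, as is the MAD fallback (mean |pair midpoint −
  aperture centroid|).
* **Beam irregularity** is the isoperimetric quotient `P²/(4πA)` of the
  exact staircase outline. Because MLC apertures have axis-aligned edges,
  the staircase perimeter of a disc converges to the Manhattan length
  `8r`, so the disc-limit of BI is `16/π² ≈ 1.62`, not 1; the tests assert
  this staircase limit.
* Orientation is declared only where the metric has a defensible
  complexity direction on fixed unidirectional sweeps. Travel- and
  speed-magnitude metrics (LT, LT/MU, LS_mean, LA_*) are deliberately
  left undeclared: with forward-only leaf motion their magnitude is set
  by field width and delivery time, not by modulation, so their sign
  flips with conventions the registry should not bake in.

## The gamma engine

Global 3-D gamma of *reference points* (detector readings for the
measurement channel, planned-dose samples for the calculation channel —
reference doses are never interpolated) against an *evaluated* grid.
Candidates are trilinear samples of the evaluated grid on one shared
offset lattice whose step is `0.1 × min(DTA)` — at most DTA/10 for every
criterion — visited in order of increasing distance with exact pruning
(a criterion retires once its spatial term alone exceeds its current
best). Because all criteria draw from nested candidate sets, passing
rates are *exactly* monotone from 3%/3 mm to 1%/1 mm on every dose pair —
not just statistically. A local refinement stage (step/5 over a one-step
window around each criterion's best candidate, candidates shared across
criteria so the nesting survives) brings gamma values within 0.02 of an
exhaustive dense search at DTA/30 with its own fine second pass, which the
suite verifies on randomised cases at all four criteria.

Gamma values are reported capped (default 2; the cohort runs use 1.1
since only pass/fail enters a passing rate), the search radius is
3×DTA, normalisation is global to the reference maximum, and points below
the 10% dose threshold are excluded from the denominator.

## Detector geometries

The helical array places 66 diodes per ring (10 mm arc pitch at radius
105 mm) on 21 rings spanning the 210 mm device length, with consecutive
rings staggered by half a pitch — 1386 diodes; count and radius are the
construction's asserted facts, the vendor's exact stagger is not. The
cross arrays are two orthogonal 200 × 200 mm planes through the cylinder
axis at 5 mm pitch in the central 60 × 60 mm and 10 mm outside, axis
duplicates removed; the oblique variant is rotated 45° about the axis.

## The synthetic study and its two error channels

The generator is the package's study design: per-plan complexity dial
`m ~ U(0, 1)`, split into aperture and dynamics sub-dials by adding
independent N(0, 0.35²) jiggle (clipped to [0, 1]) so the two error
channels are only loosely coupled across the cohort; site-stratified
counts default to the two-linac structure 46/32/65/9 and 122/64/59/7
(head-and-neck / chest-and-abdomen / pelvis / limbs); 2–9 beams per site
profile, ≥50 CPs, unidirectional sweeps with smooth per-leaf increment
modulation (variance grows with the dynamics sub-dial) and a smooth
log-normal gap process whose mean falls from 36 mm to 4 mm and whose
spread grows with the aperture sub-dial. Leaf speeds are kept under
2.5 cm/s by increment clamping; a residually infeasible draw regenerates
(at most 5 attempts). Limbs are generated for cohort fidelity but excluded
from site-stratified statistics — their per-site samples are too small to
rank.

The toy dose engine accumulates interval fluence (aperture indicator ×
interval MU, anti-aliased in the leaf-travel direction) on the grid,
convolves with a 3 mm Gaussian penumbra, applies a gentle exponential
depth profile along the beam axis and scales to the prescription at the
grid centre. It is deliberately not a physical dose calculation — no
heterogeneity, no scatter kernels, a single beam axis — so passing tests
demonstrate the *analysis chain*, not dosimetric realism.

The two error channels are designed to be mechanistically orthogonal:

* **Calculation channel** (algorithm-mismatch surrogate): the planned
  grid is blurred by an extra sigma proportional to the plan's SAS_5 and
  scaled by a small gap-dependent output offset (6 mm and 0.04 per unit
  SAS_5; ×1.6 for the second linac's collapsed-cone-like system, which
  the source study found less able to absorb small-aperture effects with
  a single leaf-gap correction).
* **Measurement channel** (delivery surrogate): leaf positions are
  perturbed per interval by a 0.05 mm systematic gap offset plus noise
  proportional to the *speed change* into the interval (0.5 mm per cm/s),
  and each beam's output wanders with sigma proportional to its
  MU-weighted mean absolute speed change (0.15 per cm/s), reflecting that
  abrupt speed changes stress both the MLC and the output servo; 0.5%
  i.i.d. detector noise is added to the readings.

The speed-*change* driver is a deliberate design decision. A channel
driven by per-interval positional noise proportional to speed *level*
produces relative dose errors scaling with 1/gap, which collapses the
measurement channel onto the aperture channel: in calibration runs the
aperture sub-dial dominated the measurement GPRs (Spearman ≈ −0.8) and
the two channels cross-correlated above 0.5, while the modulation indices
carried no signal. Driving the channel by speed variation — the quantity
the modulation indices measure — restores the intended structure:
negative dynamics-metric correlations that strengthen toward 1%/1 mm,
aperture-metric correlations confined to the calculation channel, and
pooled cross-channel correlations below the moderate cut. Coefficients
were frozen after one calibration pass targeting pooled GPR distributions
spanning roughly 50–100% at 2%/2 mm and are never adjusted per run.

## Statistics

Spearman correlation uses mid-ranks (tie-corrected) with the two-tailed
t-approximation `t = r√((n−2)/(1−r²))`; n is in the hundreds here, where
the approximation is standard. Strength grades partition |r| as
[0.7, 1] strong, [0.5, 0.7) moderate, [0.4, 0.5) weak, [0, 0.4) none —
the published wording overlaps at the cut points; we take each boundary
with its upper interval. No multiple-testing correction is applied,
matching the reporting style the analysis mirrors. PCA for the
principal-component regression is computed on z-scored metrics (the
correlation matrix — metrics have incommensurate units), zero-variance
columns are dropped with a warning, the smallest k with cumulative
explained variance ≥ 0.90 is kept, and GPR is regressed on the k scores
by ordinary least squares with the overall F-test p-value. The report
stage runs PCR per system × criterion and per site stratum and writes
plain CSV plus a Markdown summary; on a fixed cohort the report is
byte-reproducible.

## Problem sizes

The simulated study runs at a 5 mm dose grid with a 23 cm cubic extent,
60 CPs per beam and gamma capped at 1.1 — sizes chosen so the full
404-plan cohort (1112 dose pairs, 4448 gamma analyses) completes in a few
minutes while preserving every structural property under test; the
per-plan defaults elsewhere in the package use the 2.5 mm grid of the
study conditions. The acceptance script uses the same 5 mm analysis
scale.

## Known limitations

* The dose engine is a toy: detector readings inherit its geometry, so
  absolute GPR levels are not comparable to clinical systems; only the
  injected ordering/sign structure is meaningful.
* The synthetic cohort cannot reproduce clinical effect magnitudes — the
  generator makes no claim about the real-world strength of any
  metric-GPR correlation, only about signs and orderings built into its
  error channels.
* CAM and MAD ship as flagged fallback definitions; EAM's raster form is
  resolution-dependent (documented, oracle-checked).
* DICOM support covers explicit-VR little-endian RT Plan / RT Dose — the
  subset the plan model needs — not the full standard.
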