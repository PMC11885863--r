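---
title: "Temporal root-system-architecture phenotyping: models, estimators, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal root-system-architecture phenotyping: models, estimators, validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roottrack)
```

## The measurement problem

Plate-grown seedlings imaged every 15 minutes produce, after segmentation,
a time series of binary masks per plant. `roottrack` turns each series into
a quantitative description of root system architecture (RSA): one main root
(MR), a set of lateral roots (LRs) with stable identities over time, the
standard scalar feature catalogue, and two gravity-referenced angles that
summarize how each lateral's growth direction responds to gravity:

* the **base–tip angle**, the unsigned angle between the vector from an
  LR's base to its tip and the gravity vector. As gravitropism bends the
  root downward this angle declines;
* the **emergence angle**, the same construction but taken at a fixed arc
  length along the skeleton from the base (2 mm by default, adjustable).
  It captures the initial growth direction, set before graviperception
  dominates, and is stable over time.

Angles are computed as `acos(dy / |v|)` in degrees with gravity along +y
(image rows increase downward because plates are imaged upright). For a
tip below its base this reduces to the familiar right-triangle
`atan(|dx| / dy)`; the arccos form extends it continuously to tips level
with or above their base, which a right triangle cannot express. Angles
are unsigned because left/right symmetry carries no meaning across a
cohort; a signed variant (`signed = TRUE`) is available.

## From mask to measurements

Each frame passes through a fixed chain:

1. **Component selection.** The 8-connected foreground component at (or
   nearest, within 20 px) the seed point is kept; other components are
   ignored with a warning.
2. **Thinning.** Guo–Hall homotopic thinning produces a 1-px-wide
   skeleton (the contract is the width invariant, not the algorithm; a
   cleanup pass removes residual 2×2 blocks).
3. **Spur pruning.** Endpoint-terminated chains shorter than
   `prune_len_mm` (default 0.3 mm) are removed iteratively, as are
   sub-threshold parallel-chain cycles left where thinning crosses small
   bumps. Spurs whose free end lies near the seed are protected: when a
   lateral emerges right at the seed, that stub is the top of the MR.
4. **Endpoint anchoring.** Thinning retracts open line ends by 2–5 px
   (we verified the same retraction in the common Zhang–Suen and Lee
   variants); each endpoint chain is therefore extended along its local
   tangent while it remains inside the original mask, restoring the
   measurable root length.
5. **Graph building.** Pixels with ≠ 2 skeleton neighbours become nodes
   (endpoints and junctions); maximal degree-2 runs become edges with arc
   length `Σ(1 or √2) × px_mm`. The root node is the node nearest the
   seed; if a chain-interior skeleton pixel is closer — which happens
   when a lateral emerges right at the seed, making the seed a V apex of
   degree 2 — the chain is split there and the pixel becomes a node of
   kind `seed`, so the MR top cannot be absorbed into a lateral's chain.
6. **MR extraction.** The MR is the root-to-endpoint path of maximal arc
   length; exact ties go to the candidate with the smallest mean angular
   deviation from gravity. Paths are routed by *minimal accumulated
   turning* (Dijkstra over directed half-edges): where roots cross in the
   2-D projection the skeleton graph contains cycles, and a plain
   shortest path would cut from the MR onto a lateral, while the MR in
   fact continues almost straight through the crossing.
7. **LR extraction.** Every maximal subtree hanging off the MR becomes
   one LR; its polyline is the longest base-to-endpoint path in the
   subtree; LRs shorter than `min_lr_len_mm` (default 0.5 mm) are
   discarded.
8. **Sub-pixel corrections.** Chains are converted to mm polylines and
   smoothed by a centred moving average (window 5 vertices, endpoints
   fixed) — raw 8-connected chains overestimate length by up to ~8 %
   through staircase jitter, smoothing reduces this to ≲ 1 %. The LR
   attachment point is then refined: thinning displaces the Y-junction
   branch point along the lateral by up to about a stroke width, so the
   lateral's initial direction is extrapolated backwards onto the local
   MR axis and the intersection prepended.

Tracking matches LR observations frame to frame by greedy
nearest-neighbour assignment on the current base pixel (radius 10 px by
default), the base being re-read each frame to tolerate slow drift.
Labels are assigned in order of first appearance, ties within a frame
broken basal-first; tracks seen in fewer than 4 frames are dropped as
segmentation flicker.

## The scalar feature catalogue

Per frame: MR, LR (sum) and total root TR = MR + ΣLR lengths in mm; LR
count; LR density = LR length / MR length (mm mm⁻¹); discrete LR density
= 10 × count / MR length (LRs cm⁻¹); MR/TR ratio. Frames are averaged to
one value per clock hour (missing hours stay missing — no
interpolation). Growth speeds are central finite differences of the
hourly lengths (one-sided at the ends); negative differences are clipped
to zero — root length cannot shrink, dips are segmentation noise — with
the raw differences retained. Spectral features detrend a speed series
by a centred 24-h moving average, normalize to unit variance,
interpolate missing points (count logged) and take the DFT amplitude
spectrum on the grid k/(N·Δt). Convex-hull metrics (area by the
shoelace formula over `chull` vertices, bounding-box width and height,
aspect ratio = height/width, and length-per-area densities) are
evaluated once per day at a configurable hour, by default the first hour
of the photoperiod, since hull geometry changes slowly.

## Cohort statistics

Genotype comparison is per feature and per hour: each treatment line is
tested against the control with a Mann–Whitney rank-sum test (midranks;
exact p by enumeration when the combined n ≤ 12 without ties, otherwise
the normal approximation with tie and continuity corrections — the
p-value itself comes from `stats::wilcox.test`, with the exact/approx
switch applied as stated). A line is flagged at α = 0.05 and a
feature-hour gets the *both-lines* flag only when every treatment line
is individually significant. No multiple-testing correction is applied
by default, mirroring per-hour reporting practice in this field;
Benjamini–Hochberg adjustment per feature is available behind `fdr =
TRUE` because hourly tests are many and strongly autocorrelated.

Superposition maps summarize a cohort visually: each plant's final mask
is rotated about its MR start so the start-to-end chord points straight
down, translated so MR starts coincide, resampled nearest-neighbour (so
masks stay binary; bilinear would create fractional counts) and summed.
A pixel's value is the number of plants whose root occupies it.

## The synthetic-data generator

No reference image cohort is distributable, so validation rests on a
parametric generator (`sim_params()`, `simulate_root_system()`,
`render_frames()`) that emulates a vertically grown Arabidopsis
seedling and retains exact ground truth. The MR elongates at `mr_speed`
(default 0.25 mm h⁻¹ ≈ 6 mm day⁻¹, a typical seedling primary root)
with a small per-step heading wobble (sd 2°). LRs emerge as a Poisson
process (`lr_emergence_rate`, default 0.1 h⁻¹) along MR tissue older
than `maturation_lag_h` (default 24 h), with a minimum 0.5-mm spacing
between emergence sites — primordia are spaced along the pericycle, and
coincident sites would be unresolvable in any segmentation. Each LR
starts at an angle drawn from N(75°, 10°) (clipped to [0, 180]) on a
random side, and its **tip heading** then relaxes exponentially toward
an asymptote:

θ(t) = final_angle + (θₑ − final_angle)·exp(−κ·(t − tᵢ)),

with defaults final_angle = 40° (a non-vertical gravitropic set-point
angle, as laterals maintain) and κ = 0.0385 h⁻¹ (18-h half-life). The
tip advances at `lr_speed` (default 0.15 mm h⁻¹) along the current
heading. These numbers are modelling choices made for plausibility and
controllability — the quantities the package *measures* are defined
independently of them.

One consequence matters for interpretation: because the law governs the
tip heading, the **base–tip chord** angle is the speed-weighted time
average of the heading, not itself an exponential. Ground truth
therefore records both the true heading and the true chord per frame;
measured decay curves are validated against the true chord series, and
`fit_decay_curve()` recovers κ by fitting the integrated chord forward
model (numerical quadrature of the heading law) rather than a bare
exponential, which would be biased toward smaller rates.

Rendering rasterizes every polyline with an anti-alias-free disc stroke
(default 3 px at 0.04 mm px⁻¹) and binarizes, so masks are strictly
binary as the pipeline expects. Frames can be written as numbered PNGs
with a ground-truth CSV and a parameter JSON sidecar.

**What the generator does not emulate:** segmentation errors (holes,
fragmentation, over-segmentation), agar texture or reflections,
root-width variation along the organ, root hairs, plant-to-plant
occlusion, and — most importantly — it renders crossings as merged
foreground. Passing validation on these fixtures therefore demonstrates
correctness of the geometry estimators and statistics on clean
single-plant segmentations; it does not certify performance on masks
whose upstream segmentation is poor, and crossing-heavy architectures
are resolved upstream by learned multi-class labels, not by this graph
decomposition (see Limitations).

## Validation design and problem sizes

The test suite and `scripts/acceptance.R` run two benchmark cohorts of
20 plants each, rendered at 0.04 mm px⁻¹ with a 3-px stroke, simulated
at a 60-min cadence over a compressed observation window (12-h
maturation lag, 0.25 LRs h⁻¹, 48–72 h): estimator validity depends on
the measurement geometry, not the absolute time axis, and these sizes
keep a full run in minutes on one CPU.

* **Recovery cohort** (κ = 0, σ = 0, θₑ = 60°): laterals are straight
  lines, so roots cannot cross and the 2-mm chord estimates θₑ without
  model bias. Observed: every true lateral ≥ 1 mm detected; MR length
  within 2 % per plant; cohort-mean LR length error ≈ 0.7 % (roots
  ≥ 2 mm); cohort-mean emergence angle within 2° of 60° (single-root
  errors are pixel-bounded: ~3 px of length quantization, so relative
  length error can exceed 2 % only for roots shorter than ~6 mm, and
  the worst single-root angle error sits at the 2-mm traversal limit).
  With bending switched on, the first 2 mm of a lateral is curved, and
  the 2-mm chord is then a *biased* estimator of θₑ by construction —
  a property of the measurement definition, shared with any fixed-arc
  protocol, not an estimator defect.
* **Decay cohort** (θₑ = 90°, final 30°, κ = 0.0385 h⁻¹): per-hour
  cohort-mean measured base–tip angles match the true chord series
  within 2°, and the fitted κ lands within a few percent of truth
  (acceptance bound 15 %).

Statistical calibration uses constructed feature tables (no imaging):
100 null cohorts × 24 hourly tests at n = 15 per group give a false-flag
rate inside the binomial 95 % CI of α = 0.05; power against a 20°
emergence-angle offset (sd 10°, n = 15) exceeds 90 % and is monotone in
the offset. Exact Mann–Whitney p-values are checked against full
permutation enumeration; convex hulls against a brute-force O(n³)
hull-edge oracle on 200 random point sets.

## Numerical choices, degenerate inputs, tie-breaks

* Chain smoothing window: 5 vertices (endpoint-preserving); `0`
  disables it. Window 3 leaves ~2–3 % staircase inflation, 5 brings it
  under ~1 % without rounding real curvature at these scales.
* Emergence angle of a root shorter than the traversal distance is
  `NA`, never extrapolated; it equals the base–tip angle exactly when
  the length equals the distance.
* A zero-length base-to-tip vector yields `NA` (logged), a zero-length
  input to `gravity_angle()` is an error.
* MR tie-breaks: candidates within 1e-9 relative arc length are split
  by mean absolute angular deviation from gravity.
* Empty masks, seeds farther than the attachment radius from any
  foreground, and all-plants-failed pipelines raise errors; single
  failing plants are excluded with a logged warning, and frames whose
  skeleton has no measurable path (the first dot-like frames of a
  series) are skipped per plant.
* All-constant speed series produce a zero spectrum without division by
  zero; collinear point sets have hull area 0 and undefined densities;
  zero hull width leaves the aspect ratio undefined.
* Determinism: the simulator seeds its own RNG stream and restores the
  caller's; identical configuration yields byte-identical pipeline CSVs.

## Design decisions on open points

* *Which definition of the emergence angle?* The measurement is
  gravity-referenced with an adjustable traversal distance (2 mm
  default); an MR-referenced variant is exposed through the `reference`
  argument, since descriptions of the first-millimetre angle relative
  to the MR also circulate. The figures produced by this package state
  the reference used.
* *Matching by initiation pixel.* "The position where the root
  initiated" could mean the first-seen base or the current base; we
  match on the current base so that slow drift of the junction (as the
  MR thickens and settles) does not break identity, and note the
  alternative here.
* *Hull width/height* are bounding-box extents of the hull, not
  diameters; *daily hull hour* defaults to the first hour of the
  photoperiod.
* *Greedy matching* (not optimal assignment) mirrors the per-pair
  nearest-base rule and is replaceable behind `match_frames()`.

## Known limitations

* Crossing roots merge in a binary mask. Minimal-turning routing
  carries the MR through isolated crossings, but when the MR tilts far
  enough to run near-parallel with bending laterals (heading separation
  ≲ 15–20°), merged chains can defeat continuity routing and truncate
  the MR. Resolving such architectures requires upstream multi-class
  (MR vs LR) segmentation; the graph decomposition here is a stated
  reinterpretation that assumes it.
* Per-root length accuracy is bounded by ~3 px of quantization; at
  0.04 mm px⁻¹ that is 0.12 mm.
* Second-order laterals are not modelled or separated: subtrees hanging
  off an LR are absorbed into that LR's subtree.
* The null calibration of the 3×-median spectral flatness heuristic is
  sensitive to the detrender's frequency response (a 24-h moving
  average depresses low/mid bins); the spectrum module therefore
  validates by dual-route equivalence and peak localization, and users
  should judge periodicity against a simulated null of their own
  series length.
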