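---
title: "Quantifying planar cell polarity in the zebrafish heart tube: methods and design"
author: "cardiomorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar cell polarity in the zebrafish heart tube: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

During early zebrafish development the linear heart tube (LHT) remodels
into a two-chambered heart. The ventricular myocardium is a single-layered
epithelium whose cells exchange neighbours through *transition states* —
junction vertices where four (a T1 state) or more (a rosette) cells
transiently share a single boundary point. The frequency of these states,
together with regional cell shape (area, circularity) and the orientation
of each cell's elongation axis relative to the organ outline, quantifies
how planar cell polarity (PCP) signalling organises chamber formation.
Alongside the morphometric readouts, membrane fluorescence line profiles
quantify whether actomyosin activity accumulates on the apical or the
basal membrane, and the looping angle (AVJ line vs. embryo midline)
summarises looping progress.

cardiomorph implements this quantification stack as a reproducible,
tested pipeline, and pairs it with a synthetic-epithelium generator whose
ground truth lets every estimator be validated by parameter recovery.

## The cell-junction mesh

Segmentations enter as integer label rasters (one label per cell, 0 =
background) or as polygon collections. Cells from rasters are polygonised
along pixel edges, so that every cell's polygon area equals its pixel
count times the pixel area exactly — area bookkeeping is closed under this
choice and the junction-vertex definition has an exact oracle (the
exhaustive 2x2-block scan). Sub-pixel smoothing is applied only where a
shape measure requests it, never to the stored geometry.

A junction vertex is a pixel corner whose surrounding 2x2 block contains
at least three distinct nonzero labels. Rasterisation splits a true
four-cell contact into two 3-fold corners about one pixel apart, so
corner clusters within `merge_tol_um` (default: one pixel diagonal) are
merged by single linkage; the merged vertex carries the union of incident
cells. This merge rule is what makes "four cells sharing a single
boundary point" operational on rasters, and it is deliberately shared
between the analysis and the generator's verification step.

All geometry lives in one y-up mathematical frame in micrometres, fixed at
ingestion (raster row r maps to y = (nrow − r + 0.5) · pixel size). Angles
are therefore reported in standard mathematical convention everywhere with
no downstream conversions.

## Morphometrics

Per cell we report area (shoelace, raw boundary), perimeter, circularity,
the orientation axis, and elongation.

* **Circularity** is the isoperimetric quotient 4piA/P^2 (1 for a circle).
  Pixel-edge boundaries inflate P by up to sqrt(2), so before circularity
  and orientation the boundary is smoothed by a window-3 closed moving
  average and then rescaled about its centroid to restore the raw area
  (circularity is invariant under that rescaling; the documented property
  "smoothing preserves area" holds exactly by construction). Raw-boundary
  mode remains available via `measure_cells(..., smooth = FALSE)` because
  it is unknowable which mode an interactive tool used; defaults use the
  smoothed mode.
* **Orientation and elongation** come from the eigen-decomposition of the
  exact area-weighted second central moment tensor of the polygon
  (Green's-theorem closed forms), not from vertex scatter, which would be
  biased by uneven vertex spacing. The major-axis angle is axial, folded
  to [0, 180); elongation is 1 − lambda_min/lambda_max. Tensors whose
  eigenvalue ratio exceeds 1 − 1e−6 are treated as isotropic: elongation
  0, axis undefined (NA), excluded from angle statistics with a logged
  count.

## The local anatomical model

The ventricular circumference is supplied as a manual trace (>= 8 ordered
points). It is interpolated by a closed composite cubic Bezier whose
control points come from neighbouring-point chords (Catmull–Rom
construction, tension 0.5): C1, parameter-free beyond the sampling
density (20 samples per span, recorded), and faithful to the trace. The
cardiac centre is the arithmetic mean of the curve samples — deliberately
the mean of samples, not the polygon area centroid, because the samples
are near-uniform in parameter and this matches how the centre is defined
in the field. One known consequence of an interpolating spline is a small
overshoot at sharp corners (about 2 % extra arc length on a square
trace); manual ventricle traces are smooth enough that this is
immaterial.

Four anatomical landmarks are given (1: AVJ–IC, 2: IC–OFT, 3: OFT–OC,
4: OC–AVJ); they snap to the nearest curve sample (tolerance 5 µm,
violations are errors naming the landmark). Points 5 and 6 are computed
at exactly one-third and two-thirds of the outer-curvature arc from 3 to
4, travelling counter-clockwise; because they are placed by arc-length
interpolation, the three OC sub-arcs are equal to machine precision. A
flag flips the travel direction for mirrored hearts. The six landmarks
define six angular sectors about the centre (counter-clockwise: IC, OFT,
OC near OFT, OC middle, OC near AV, AV). Sector membership uses one
shared reference angle and cumulative breaks, so the sectors are a true
partition — every point falls in exactly one half-open sector, with no
floating-point double assignment on boundary rays.

### Axial angles and their statistics

Each cell's axis Psi is compared with the outline at the sample nearest
the cell centroid: the tangent is a central difference, the outward
normal is the tangent rotated 90 degrees away from the centre. Two
conventions are computed because the verbal definition (angle to the
normal) and the figure semantics (OFT cells "at 90 degrees") cannot both
hold under one convention for circumferentially elongated cells. The
default, `"normal"`, reports fold(Psi − normal angle) on the half-open
axial scale (−90, 90], ties at ±90 mapped to +90; under it a radially
elongated cell scores 0 and a circumferential cell 90, reproducing the
published figure semantics. The `"tangent"` convention is the complement.
The convention used is stamped into every output row.

Axial statistics double the angles (Davis's method): phi = 2 theta. We
report the mean resultant length R̄ of the doubled angles, circular
variance 1 − R̄, the mean axis atan2(S, C)/2 in [0, 180), Rayleigh
Z = nR̄², and the classical series p-value
p ≈ exp(−Z)[1 + (2Z − Z²)/(4n) − (24Z − 132Z² + 76Z³ − 9Z⁴)/(288 n²)],
clamped to (0, 1]. A Monte-Carlo p (simulated null of Z, fixed seed) is
available for small n. We never print a bare "Rayleigh's R": the field's
literature uses that label ambiguously (sometimes a concentration,
sometimes the p-value), so the three quantities are always reported under
their own names.

## Transition-state counting

`detect_transition_states()` lists vertices of order >= 4
(position-lexicographic order, deterministic); `ts_frequency()` reports
100 · n_TS / n_cells. By default cells at the image edge or tissue rim are
excluded from the denominator and transition states all of whose incident
cells are boundary cells from the numerator, because image borders create
artificial vertices; the flag is echoed into every report. For synthetic
band tissues, where every cell touches the band rim by construction,
analyses run with `exclude_boundary_cells = FALSE`. A convenience one-way
ANOVA with Bonferroni-adjusted pairwise comparisons (base R `aov` and
pooled-variance pairwise t tests) mirrors the group-level testing style
used for per-heart rates; it is a classical procedure, not a contribution
of this package.

## Intensity analysis

Line profiles resample a path at one-pixel arc spacing and average
`width_px` (default 10) bilinear samples placed symmetrically along the
local perpendicular. Min–max normalisation maps the selection to [0, 1];
for apical-vs-basal comparisons the two profiles are normalised jointly
(one min–max over both selections) so the sides stay comparable — the
per-selection variant is used only for single-profile display. The
apical-accumulation call is `mean(apical) − mean(basal) > margin` inside
the outflow-tract window on the jointly normalised scale. The margin
(default 0.2) is a config knob: the published calls were visual per
heart, and a fixed logged threshold is the reproducible operationalisation;
an amplitude-sweep experiment in the test suite locates the decision
boundary at the configured margin within noise.

Presence of a channel at a transition state is a disc statistic: mean
intensity within `radius_um` (default 1.5 µm) of the vertex above the
channel's background mean + 2 s.d. (background ROI explicit, never
guessed). Co-localisation means presence in both channels; percentages
are rounded half-up to integers, matching how such counts are reported.
Ventricular mean intensity is background-subtracted, divided by ventricle
area, then divided by the cohort mean.

## The synthetic epithelium generator

The generator emulates a bean-shaped single-layered epithelium in
projection: a Fourier-perturbed ellipse outline (<= 3 harmonics), an
annular band of width `band_width` inside it (measured radially; the
outline is star-shaped about its centre by construction), and 100–300
polygonal cells with region-dependent statistics. Defaults are the
wild-type-like two-chamber-stage regime: outer-curvature cells at
107 µm² / circularity 0.53, inner-curvature cells at 83 µm² / 0.60,
IC/OC axes radial (0 deg to the outline normal), OFT/AV axes
circumferential (90 deg), 5.5 transition states per 100 cells; the
`wt26` preset raises the rate to 9.0 and `fzd7a` emulates the
PCP-deficient contrast (8.8 per 100, OFT orientation shifted to ~118 deg
with s.d. 35 deg). Pixel size is 0.2 µm throughout.

Mechanically: seeds are placed per segment with density area_band /
area_mean (so regional mean areas are density-controlled, which makes
them essentially unbiased by construction; cells straddling a segment
border are counted by centroid, which pulls a region's mean a few
percent toward its neighbours' targets), relaxed by six isotropic
Lloyd iterations on a coarse grid, then grown into an anisotropic
power-diagram partition: each seed carries an area-preserving metric
diag(1/λ, λ) rotated to an axis drawn from its segment's axial
orientation distribution (mean relative to the local outline normal,
Gaussian spread), and per-seed power weights adapt over six iterations so
realised areas track per-seed targets drawn from N(mean, sd). The
stretch λ for a requested circularity is read from a calibration curve
measured once on reference simulations of this generator followed by the
package's own morphometrics (λ 1.0 → circularity 0.762 down to λ 2.5 →
0.512, linearly interpolated); the curve is resolution- and
cell-size-dependent, and a residual bias of up to ~0.04 remains for the
smallest, roundest cells — inside the recovery tolerance used in the
tests. Fragmented labels are repaired (largest component kept, fragments
reassigned), and cells below ~6 µm² are absorbed into neighbours.

Transition states are injected by edge contraction realised as a radial
disc remap: the disc spanned by a junction edge is remapped so that every
interior pixel takes the label found just outside the disc along its own
ray, which contracts the edge to the disc centre and pulls the four
incident cells onto one point (chains of two edges yield order-5
rosettes). Every injection is verified with the detector itself (exactly
one new vertex of the intended order, all cells still connected) and
rolled back otherwise; conversely, when the target rate is below the
number of incidental near-degenerate vertices, the excess is dissolved by
the inverse operation. The ground-truth manifest records per-cell region,
drawn axis and target area, the final transition-state table, landmark
positions, the seed and a spec hash; everything is deterministic under
(spec, seed).

Channels paint membrane-localised intensity (Gaussian cross-section,
σ = 1 px) with per-segment amplitudes plus Gaussian noise, clipped to the
bit depth; channel B can be silenced around a chosen fraction of
transition states to inject a known co-localisation rate. The
mid-sagittal fixture draws two nested membrane arcs whose amplitude
profiles differ by a controlled normalised step inside the outflow-tract
window — the quantity the apical-accumulation call estimates — with the
basal profile shaped to anchor the joint min–max normalisation outside
the window.

### What the generator does and does not emulate

It reproduces the statistical structure the estimators assume:
region-dependent shape and orientation distributions, a controllable
transition-state rate, membrane-localised two-channel intensity with
additive noise. It does not emulate mechanical vertex-model dynamics,
time-lapse sequences, 3-D tube geometry, anisotropic pixels, uneven
illumination, or segmentation errors. Passing recovery tests therefore
demonstrates that the estimators are unbiased and correctly calibrated on
data satisfying their assumptions — not that they are robust to real
segmentation artefacts.

## Numerical choices and degenerate inputs

* Vertex merge tolerance: one pixel diagonal by default, exposed
  everywhere, logged in reports.
* Axial folds use the half-open interval (−90, 90] with −90 mapped to
  +90: deterministic tie-breaking.
* Duplicate trace points are dropped with a warning; self-intersecting
  traces, landmarks off the outline, landmarks out of counter-clockwise
  order, degenerate polygons, flat profiles, empty ROIs and empty OFT
  windows are errors with specific messages.
* Reports are regenerate-identical: fixed column orders, deterministic
  vertex ordering, full-precision JSON.
* Percentages for reporting are rounded half away from zero
  (`round_half_up`), not banker's rounding.

## Problem sizes used in the shipped experiments

The recovery experiments in the test suite and the acceptance script use
the default tissue (about 90–100 cells per seed, 0.2 µm pixels) pooled
over 20 seeds for shape recovery (>= 200 cells per pooled region), an
OFT-dominant ring of ~75–86 outflow-tract cells per seed for orientation
recovery, 1000 replicates of n = 50 for Rayleigh type-I calibration, and
50–100 random label rasters up to 64x64 for the detection oracle. These
sizes give standard errors comfortably inside the stated tolerances while
keeping a full run in the range of a few minutes on one core.

## Known limitations

* Circularity recovery carries the calibration's residual bias (up to
  ~0.04 for small round cells); area and orientation recovery are
  unbiased by construction.
* The polygon-ingestion overlap check is a vertex/centroid heuristic, not
  an exact polygon intersection (no computational-geometry dependency);
  pathological overlaps that hide every vertex inside the tolerance band
  would pass it.
* The band is defined by radial depth from the outline, which for
  strongly non-circular outlines is slightly wider than a true Euclidean
  offset band near high-curvature regions.
* Rosette injection supports order 5; higher orders would need chains of
  three or more contracted edges.
* `kind` distinguishes T1 from rosette by vertex order only; forming vs.
  resolving transitions are indistinguishable in a snapshot and out of
  scope.
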