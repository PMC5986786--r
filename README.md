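# cardiomorph

Quantification of epithelial remodelling and planar cell polarity (PCP)
in the early zebrafish heart tube.

During cardiac chamber formation the ventricular myocardium — a
single-layered epithelium — remodels by cell neighbour exchange. The
intermediates of that exchange are **transition states**: junction
vertices where four (T1 state) or more (rosette) cells share a single
boundary point. Their frequency per 100 cells, together with regional
cell shape and the orientation of each cell's elongation axis relative to
the organ outline, quantifies how PCP signalling organises chamber
formation; membrane line profiles quantify apical-versus-basal actomyosin
accumulation, and the looping angle summarises looping progress.

cardiomorph is for developmental biologists and image analysts who have
segmented heart-tube epithelia (label rasters or polygon meshes) and want
these readouts as a reproducible, scriptable pipeline rather than a chain
of interactive tools.

## What it computes

* **Cell-junction mesh** from an integer label raster (boundaries traced
  along pixel edges, exact areas) or a polygon collection; junction
  vertices from the 2x2-block rule with a merge tolerance that makes
  rasterised four-cell contacts detectable.
* **Morphometrics** per cell: area, perimeter, circularity
  (isoperimetric quotient `4*pi*A/P^2`), orientation axis from the exact
  polygon second-moment tensor, elongation
  `1 - lambda_min/lambda_max`.
* **Transition states**: detection (`order >= 4`), frequency per 100
  cells with explicit boundary-cell handling, and a convenience one-way
  ANOVA with Bonferroni-adjusted pairwise comparisons for per-heart
  rates.
* **Local anatomical model**: a traced ventricular circumference is
  smoothed with a closed Catmull–Rom/Bezier curve; four given landmarks
  plus two computed outer-curvature trisection points partition the
  ventricle into six named segments (IC, OFT, OC near OFT, OC middle,
  OC near AV, AV) about the centroid.
* **Axial angles**: per cell, the angle between the elongation axis Psi
  and the local outline normal, folded to the axial scale (−90, 90];
  circular statistics on doubled angles (mean axis, mean resultant
  length R-bar, Rayleigh `Z = n*R_bar^2` and its series p-value).
* **Intensity**: width-averaged membrane line profiles, min–max
  normalisation, apical-accumulation calls at a configurable margin,
  background-subtracted ventricular mean intensity with cohort
  normalisation, and two-channel presence/co-localisation calls at
  transition states.
* **Looping angle**: acute angle between the atrio-ventricular-junction
  line and the embryo midline.
* **Synthetic epithelium generator** with a ground-truth manifest: a
  bean-shaped band of polygonal cells with region-dependent area,
  circularity and orientation, a controllable transition-state rate
  (injected by verified edge contraction), and synthetic membrane
  channels — the substrate for the package's parameter-recovery tests.

## Worked example

Generate a wild-type-like synthetic ventricle, measure it, and print the
report:

```r
library(cardiomorph)

spec <- preset_spec("wt")          # 107/0.53 OC, 83/0.60 IC, 5.5 TS/100
tis  <- generate_tissue(spec, seed = 1)
rep  <- run_pipeline(run_config(exclude_boundary_cells = FALSE),
                     inputs = tis)
print(rep)
```

```
== cardiomorph report ==
Cells measured: 94
Transition states: 5 (5 T1, 0 rosette) over 94 cells -> 5.32 per 100 cells
  (boundary cells included)
Region shape summary:
      region  n area_mean area_sd circ_mean circ_sd
          AV 16    107.56   61.10    0.5024  0.1301
          IC 19     80.04   29.39    0.6603  0.1284
   OC_middle 14    115.91   61.39    0.5530  0.1312
  OC_near_AV 17     92.89   46.33    0.6056  0.1280
 OC_near_OFT 17    109.28   31.53    0.5250  0.1076
         OFT 11    102.14   57.05    0.5198  0.1186
Axial angles (normal convention):
      region  n mean_axis_deg  R_bar rayleigh_p
          AV 16        88.264 0.8024  3.301e-06
          IC 19       162.377 0.6487  1.446e-04
   OC_middle 14         1.228 0.6466  1.700e-03
  OC_near_AV 17         8.315 0.7878  2.991e-06
 OC_near_OFT 17         7.151 0.8305  8.863e-07
         OFT 11        96.536 0.7349  1.215e-03
```

Reading the output: the band holds 94 cells; the transition-state
frequency (5.32 per 100 cells, all T1) tracks the injected rate of 5.5
(whole transitions are injected, so single seeds land on the nearest
feasible count). Inner-curvature cells are small and round (80 µm²,
circularity 0.66 for this single seed), outer-curvature cells larger and
more elongated; pooling across seeds tightens these to the injected
83/0.60 and 107/0.53. The axial angle table shows inner/outer-curvature
cells oriented near 0° (radial; 162° is the same axis as −18°) and
outflow-tract / atrio-ventricular cells near 90° (circumferential), each
with concentrated distributions (high R-bar, small Rayleigh p) — the
wild-type polarity pattern.

The same pipeline runs from files (`labels.tif`, `outline.csv`,
`landmarks.csv`) via `run_config(...)` paths or the thin CLI:

```sh
Rscript inst/scripts/cardiomorph.R generate --preset wt --seed 1 --out demo/
Rscript inst/scripts/cardiomorph.R all --labels demo/labels.tif \
    --pixel-size 0.2 --outline demo/outline.csv \
    --landmarks demo/landmarks.csv --include-boundary --out demo_report/
```

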