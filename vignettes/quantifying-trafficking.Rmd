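---
title: "Quantifying endosomal trafficking and front-rear polarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endosomal trafficking and front-rear polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traffickr)
```

## The measurement problem

Cells on the epithelial–mesenchymal spectrum differ in how fast endocytosed
cargo moves through the cell.  In epithelial-like cells, internalized cargo
(transferrin, surface-biotinylated proteins, ligand-bound receptors such as
MET) lingers near the plasma membrane; in mesenchymal-like cells it is
rapidly transported to a perinuclear compartment, recycled back to the
membrane, routed to the Golgi, or degraded in lysosomes.  The same
trafficking machinery positions the Golgi and focal adhesions (FAs) toward
the leading edge of a migrating cell, establishing front-rear polarity.

traffickr implements the image- and plate-based quantifications used to
measure these processes:

* **radial linescan profiles** — intensity sampled along lines drawn from
  the plasma membrane (PM) inward toward the nucleus;
* **compartment scores** — background-corrected maximal intensities in a
  perinuclear and a peripheral band, a per-cell classification
  (perinuclear / peripheral / ambiguous), and the per-condition
  "% perinuclear cells" statistic;
* **Manders colocalization** — M1/M2 overlap coefficients and
  cargo-vs-marker colocalized fractions over time;
* **FA morphometrics** — particle count, area, and sector-based polarity
  scoring ("polarized" when the majority of structure signal lies inside
  the front sector);
* **trajectory statistics** — speed, net displacement, path length, and
  directionality of vesicle or cell tracks;
* **kinetics** — endocytosed percentage and recycled fraction from in-cell
  ELISA plates, endosomal-maturation intensity series, and degradation
  half-lives from densitometry.

Because the raw micrographs behind such studies are rarely available, the
package ships a synthetic-scene generator that emits images, movies, track
tables and plate tables *with known ground truth*; every estimator is
validated by recovering the generator's parameters.

## Geometry: masks, lines and sectors

All measurements share one spatial scaffold built from a cell outline and a
nucleus outline (drawn manually in the original workflow; supplied as
polygons here).  Conventions: 0-based pixel coordinates, `(x, y)` =
(column, row), and half-open rasterization — a pixel belongs to a region
iff its center is inside the polygon.

The perinuclear/peripheral boundary is not standardized anywhere in the
imaging literature, so the package makes it explicit and scale-free: with
`R` the mean distance from the nucleus boundary to the cell boundary, the
perinuclear band is the region within `perinuclear_band * R` of the
nucleus (default 0.25) and the peripheral band within
`peripheral_band * R` of the PM (default 0.15).  Bands are fractions of
`R` so the same settings adapt to cells of different sizes.  Two
degenerate situations are handled explicitly:

* band fractions summing to ≥ 1 guarantee a collision and raise
  `bands-overlap`;
* a nucleus that locally approaches the cell edge squeezes the bands
  together; there the peripheral band takes precedence and the perinuclear
  band locally thins to zero width, so the masks are disjoint by
  construction.

```{r}
roi <- cell_roi(circle_polygon(100, c(110, 110)),
                circle_polygon(30, c(110, 110)))
masks <- build_compartment_masks(roi)
masks
```

Linescans default to 3 lines per cell (matching the common practice of
averaging three linescans per cell), evenly spaced in angle, pointing from
the PM toward the nucleus centroid, with intensity averaged over a 3-px
perpendicular slab.  The line length and width in the original studies are
unreported; both are exposed as configuration with no claim of matching
the original values.  Intensities are bilinearly interpolated; within the
outer half-pixel border the edge gradient is extrapolated so that linear
intensity fields are sampled exactly.

Front sectors have their apex at the nucleus centroid and are given either
as a direction plus angular half-width or as two leading-edge points (the
minor arc between them).  The migratory front direction is an *input*
(from wound geometry or simulator ground truth); the package deliberately
does not infer it from images.

## Classification and its tie margin

Published scoring of "perinuclear vs peripheral" cells is typically done
by eye.  The package operationalizes it through the same quantity the dot
plots report — the per-cell maximal intensity in each compartment — with a
relative tie margin (default 10%): a cell is perinuclear when
`perinuclear_max > 1.1 * peripheral_max`, peripheral in the converse case,
and ambiguous otherwise (ambiguous cells stay in the denominator of
"% perinuclear").  Background is subtracted before the maxima; the default
estimate is the median intensity outside the cell mask, which is robust
and parameter-free.

## Colocalization

Manders coefficients are computed inside the cell mask after per-channel
thresholding.  The default threshold is a masked Otsu (between-class
variance on a 256-bin histogram restricted to the mask, since whole-image
Otsu implementations cannot be restricted to a region); fixed thresholds
are accepted and recommended for sparse punctate images, where Otsu
between-class variance is known to be unstable.  Both a `pixel-count` mode
(fraction of suprathreshold pixels of one channel that are also
suprathreshold in the other — the default, matching the common phrase
"fraction of red or green pixels overlapping") and an
`intensity-weighted` mode are provided.  The numerator is restricted to
pixels suprathreshold in *both* channels, which keeps M1/M2 in [0, 1] and
makes the swap symmetry `m1(A,B) = m2(B,A)` exact.  Costes randomization
and object-based colocalization are out of scope.

## Morphometrics

FA particle analysis thresholds within the cell mask, labels 8-connected
components, and discards components below `min_size` (default 4 px²,
standard particle-analysis practice).  "Size" is implemented as area;
particle centroids are intensity-unweighted pixel-center means.  Polarity
uses intensity as its default basis — the fraction of total suprathreshold
structure intensity inside the front sector — because intensity is robust
to fragmented segmentation; a centroid-count basis is available.
"Majority" is implemented as strictly greater than 0.5, with a tie
(exactly 0.5) scored not polarized.

## Dynamics and kinetics

Track statistics take tracks as tables (tracking/linking itself is out of
scope; the simulator emits ground-truth track tables so the statistics
layer is fully testable).  Speed is path length over elapsed time — the
per-step semantics of tracking software — while net displacement is
reported separately; directionality is net/path, defined as 0 for a track
that never moves.

Maturation series average background-corrected intensity over
suprathreshold vesicle pixels per frame, with the threshold recomputed per
frame (default Otsu) so that a probe brightening with vesicular
acidification keeps a comparable suprathreshold fraction; frames without
vesicle pixels are recorded missing and dropped pairwise rather than
imputed.

Plate kinetics follow the in-cell ELISA arithmetic: every well is divided
by its total-protein (BCA) readout to correct for cell number, internalized
signal is expressed as a percentage of surface-bound total measured in
parallel wells, and the recycled fraction is the fraction of internalized
cargo lost after the final strip, clamped to [0, 1] with a flag when
measurement noise pushes it outside.  Degradation curves divide band
densitometry by the loading control, set T = 0 to 100%, and optionally fit
`A·exp(-kt)` by unweighted least squares on that normalized scale (T = 0
included) — the simplest defensible default; the half-life is `ln 2 / k`.
Because the forced T = 0 normalization propagates the T = 0 noise draw to
every point, a single 9-point curve at 5% multiplicative noise estimates
the half-life with ~6% sampling sd; replicate curves (n = 3 is the usual
design) should be fitted and averaged, as the package's own validation
does.

## The synthetic-scene generator

`simulate_scene()` renders each cell in its own tile: an elliptical cell
with low-order Fourier boundary perturbation (ellipses keep the radial
bands analytically tractable for oracle checks), a concentric scaled
nucleus, cargo puncta as isotropic Gaussians (PSF σ default 2 px — no
optics simulation, sufficient to exercise every measurement operator),
a DAPI nucleus fill, a Golgi disk just outside the nucleus, and optionally
FA disks along the cell margin.  Noise is additive Gaussian read noise
(default sd 5 counts on a background of 10) plus optional Poisson shot
noise.

The generative knobs map one-to-one onto the quantities the estimators
recover:

* `p_perinuclear` — each cargo punctum falls in the perinuclear band with
  this probability, else in the peripheral band.  Punctum amplitudes are
  log-normal (sdlog 0.35), so the cell-level maximal-intensity
  classification tracks the punctum-level mixture.
* `fa_count`, `fa_mean_area` — FA disks are placed in the lamellipodial
  margin (a band ~20 px deep) by sequential rejection with a >1.5 px gap,
  so rasterized particles never 8-connect and particle analysis sees
  exactly the generated count and areas.
* `fa_front_bias` / `fa_polarized_prob` — punctum-level or cell-level
  control of front-sector placement for polarity calibration.
* `overlap` — cargo puncta land inside the Golgi marker with this
  probability (colocalization ground truth).
* directed tracks step `v·dt` plus Gaussian jitter; Brownian tracks step
  `N(0, σ²)` per axis, whose mean step length is the Rayleigh mean
  `σ√(π/2)` — the closed form the recovery tests check against.
* plates and densitometry tables apply multiplicative log-normal noise
  with a stated CV, plus a shared per-well cell-number factor (10% CV)
  that the BCA normalization is designed to remove.

What the generator does **not** emulate — and what passing recovery tests
therefore do not establish about real data: optical aberrations and depth
effects, deconvolution artifacts, organelle texture, touching cells,
segmentation error in hand-drawn outlines, bleaching, and stage drift.
The generator validates the *measurement operators*, not an end-to-end
claim about microscope data.

Determinism is a contract: the same config and seed reproduce every image,
table and CSV bit-exactly, and each `run_analysis()` writes a manifest
from which `run_from_manifest()` re-derives all outputs byte-for-byte.

## A worked two-condition comparison

The `demo` analysis contrasts an epithelial-like (`p_perinuclear = 0.2`)
with a mesenchymal-like (`p_perinuclear = 0.8`) scene, scores every cell,
and applies the standard unpaired two-tailed t-test:

```{r, eval = FALSE}
res <- run_analysis(list(analysis = "demo", outdir = "demo_out",
                         seed = 1, n_cells = 30))
read.csv(res$tables[["demo_comparison"]])
```

Mesenchymal-like cells show higher perinuclear maxima, epithelial-like
cells higher peripheral maxima — the front-rear trafficking dichotomy the
measurements are designed to expose.

## Statistical surface

`compare_groups()` wraps the three tests used for such readouts: unpaired
two-tailed Welch t-test for two groups, one-way ANOVA for more (post-hoc
comparisons out of scope), and Spearman rank correlation for paired
observations, reporting group means ± SEM as in dot-plot figure legends.
The unit of analysis is the cell (or track, or well), pooled across
replicates, with per-replicate fractions preserved where aggregation
functions accept an `experiment` id.  No multiple-testing adjustment is
applied by default; `p.adjust` can be applied downstream for multi-marker
time courses.  Two-way ANOVA (condition × time) is noted as an extension
and deliberately left off the default surface, as the factor structure of
such designs varies.

## Problem sizes used in validation

The shipped validation suite simulates 50 cells per mixing-weight level
(five levels), 100 cells per condition for the two-condition contrast, 12
cells for FA morphometrics, 200 cells for the polarity null calibration,
100 + 100 tracks of 100 frames for motion statistics, 6-replicate plates,
3 replicate densitometry series, and 10,000 null repetitions for t-test
calibration — sizes chosen to put Monte-Carlo error comfortably inside
each check's tolerance.

## Known limitations

* ROIs are inputs; there is no automatic segmentation of real micrographs.
* Otsu thresholds on sparse punctate images are unstable; prefer fixed
  thresholds there (the colocalization API takes them directly).
* The radial-band geometry assumes a roughly convex cell with an interior
  nucleus; extremely concave outlines will make the mean nucleus-to-edge
  distance `R` less interpretable.
* Track linking, spot detection, MSD/diffusion modelling, photobleaching
  correction and 3D stacks are out of scope.
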