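# traffickr

Quantitative analysis of endosomal trafficking and front-rear polarity in
fluorescence micrographs.

Cells on the epithelial–mesenchymal spectrum traffic endocytosed cargo at
different speeds: in epithelial-like cells internalized transferrin or
surface-labeled proteins linger near the plasma membrane (PM), while in
mesenchymal-like cells cargo is rapidly moved to a perinuclear compartment,
recycled, routed to the Golgi, or degraded — and the same machinery points
the Golgi and focal adhesions (FAs) toward the leading edge of a migrating
cell.  traffickr implements the measurement side of such studies as tested,
reusable R functions:

* **Linescan profiles** — intensity along lines from the PM inward
  (`radial_lines()`, `linescan_profile()`).
* **Compartment scoring** — background-corrected maximal intensity in
  perinuclear vs peripheral bands, per-cell classification with a tie
  margin, and "% perinuclear cells" (`build_compartment_masks()`,
  `compartment_max()`, `classify_cell()`, `percent_perinuclear()`).
  A cell is perinuclear when
  `perinuclear_max > (1 + margin) · peripheral_max` with bands defined as
  fractions of the mean nucleus-to-membrane distance *R*.
* **Manders colocalization** — M1 = Σᵢ w₁ᵢ·1[ch2ᵢ > t₂] / Σᵢ w₁ᵢ over
  suprathreshold channel-1 pixels inside the cell mask (pixel-count or
  intensity weights), M2 symmetric; plus colocalized-fraction time courses
  (`manders()`, `fraction_colocalized_over_time()`).
* **FA morphometrics and polarity** — 8-connected particle analysis
  (count, area), Golgi area, and sector scoring: polarized ⇔ more than
  half of the structure signal lies inside the front sector
  (`segment_puncta()`, `golgi_area()`, `polarity_score()`,
  `percent_polarized()`).
* **Track statistics** — speed = path length / elapsed time, net
  displacement, and directionality = net/path ∈ [0, 1]
  (`track_stats()`, `track_stats_table()`).
* **Kinetics** — in-cell ELISA arithmetic
  (% internalized = 100·internalized/surface-total after BCA
  normalization; recycled fraction = (internalized − remaining)/internalized),
  endosomal-maturation series, and degradation half-life ln 2/k from an
  `A·e^(−kt)` fit of control-normalized densitometry
  (`endocytosis_fraction()`, `recycled_fraction()`, `maturation_series()`,
  `degradation_curve()`).
* **Synthetic scenes with ground truth** — cells, puncta, Golgi, FAs,
  movies, tracks, plates and densitometry tables generated from a seeded
  config so every estimator can be validated by parameter recovery
  (`scene_config()`, `simulate_scene()`, `simulate_tracks()`,
  `simulate_plate()`, `simulate_densitometry()`).
* **Orchestration and statistics** — config-driven runs with JSON
  manifests and byte-exact reproducibility, plus the standard comparisons
  (Welch t, one-way ANOVA, Spearman) (`run_analysis()`,
  `run_from_manifest()`, `compare_groups()`).

It is aimed at cell biologists and image analysts who want these standard
trafficking readouts scripted, parameterized and testable instead of
embedded in interactive image-analysis sessions.

## Worked example

An end-to-end two-condition experiment: 30 epithelial-like cells
(perinuclear mixing weight 0.2) against 30 mesenchymal-like cells (0.8),
scored and compared:

```r
library(traffickr)
res <- run_analysis(list(analysis = "demo", outdir = "demo_out",
                         seed = 1, n_cells = 30))
read.csv(res$tables[["demo_comparison"]])
#>           readout mean_epithelial mean_mesenchymal t_statistic      p_value
#> 1 perinuclear_max        316.0713         509.2213   -7.514956 3.997001e-10
#> 2  peripheral_max        455.7509         284.0703    6.951976 3.590460e-09
read.csv(res$tables[["demo_percent_perinuclear"]])
#>          condition fraction_perinuclear
#> 1  epithelial_like           0.06666667
#> 2 mesenchymal_like           0.86666667
```

Mesenchymal-like cells carry significantly brighter perinuclear maxima,
epithelial-like cells brighter peripheral maxima (both p < 1e-8), and the
fraction of cells classified perinuclear rises from 7% to 87% — the
front-rear trafficking dichotomy these measurements are designed to
expose.  `demo_out/manifest.json` records the config, seed and output
hashes; `run_from_manifest()` reproduces every CSV byte-for-byte.

A single-cell example of the underlying geometry:

```r
roi <- cell_roi(circle_polygon(100, c(110, 110)),
                circle_polygon(30, c(110, 110)))
build_compartment_masks(roi)
#> <compartment_masks> 212 x 212 px; cell 31388, perinuclear 4300,
#>   peripheral 6344 px; R = 70.0 px
```

A command-line wrapper with verbs `simulate`, `profile`, `coloc`,
`morpho`, `polarity`, `tracks`, `kinetics`, `stats` and `demo` is
installed at `inst/scripts/traffickr`.

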