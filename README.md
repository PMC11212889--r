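# bundlekit3d

3D reconstruction and morphometry of cochlear stereocilia bundles, in R.

Cochlear hair cells carry V-shaped bundles of stereocilia whose heights,
orientations and actin content follow the tonotopic organization of the
cochlea and are disrupted by many deafness mutations. Quantifying them in 3D
confocal stacks of phalloidin-stained tissue is laborious: bundles must be
segmented per z-plane, stitched into 3D instances, and measured one by one.
`bundlekit3d` implements the computational core of that workflow for anyone
who already has per-frame 2D instance masks (from any segmenter — deep
learning or otherwise) and wants reproducible, scriptable 3D measurements:

* **Reconstruction** — greedy overlap tracking turns per-frame 2D masks into
  3D instances: a detection joins the eligible track with the largest pixel
  overlap (`≥ min_overlap`), contested tracks go to the largest-overlap
  detection, everything else seeds a new track.
* **Morphometry** — tip-to-base bundle height
  `D = √((sₓΔx)² + (s_yΔy)² + (s_zΔz)²)` from the topmost projection pixel
  to the base found by tracing down from the projection centroid, with the
  deepest occupied plane fixing z; fifteen 2D/3D region measurements
  (volume, exposed-face surface area, centroid, projection shape metrics).
* **Orientation** — planar-cell-polarity angles from the V geometry: left
  and right base points and peak, with `atan2`-derived baseline, axis and
  apex angles; two endpoint strategies ("height only" and
  "height and distance") for regular and irregular bundles.
* **Intensity** — per-layer fluorescence sums per bundle with optional
  background subtraction, three depth-aggregation modes (all layers / common
  depth n = min depth / pad to max depth with the weakest layer), and max
  normalization.
* **Row identity** — IHC / OHC1 / OHC2 / OHC3 assignment by clustering base
  y-coordinates (k-means or Gaussian mixture), labels ordered bottom-up.
* **Evaluation** — IoU-based instance matching with TP/FP/FN across the
  19-threshold sweep 0.10–1.00, `F1 = 2TP/(2TP+FP+FN)`,
  `accuracy = TP/(TP+FP+FN)`; agreement statistics (Pearson, paired t,
  Wilcoxon, Mann–Whitney) for validating against human observers.
* **Frame-level stack logic** — z-stack zone selection (PCZ/CCZ/NSZ) with
  the "switches" stability count, 72-class rotation-score aggregation with
  largest-inscribed-rectangle cropping, and the 13-frame tonotopic majority
  vote.
* **Texture** — GLCM scalars (contrast, correlation, energy, homogeneity)
  and 10-bin uniform LBP histograms per bundle crop, with two-sided
  Mann–Whitney group comparison.
* **Phantoms** — a seeded generator of synthetic stacks of V-shaped bundles
  in four rows with complete ground truth (labels, heights, angles, depths),
  so the entire pipeline is testable without any imaging data.

Everything tabular flows through tibbles, so results chain with the pipe;
`autoplot()` / `plot_*()` give ggplot2 figures and `tidy()` / `glance()`
summarize fitted comparison objects.

## Worked example

Simulate a stack with ground truth, degrade it into per-frame masks,
reconstruct, measure, and evaluate:

```r
library(bundlekit3d)

ph     <- generate_stack(phantom_config(bundles_per_row = 4, seed = 7))
series <- degrade_to_frame_masks(ph$labels, dropout_rate = 0.1, seed = 8)
tracks <- assign_tracks(series, max_gap = 1)
labels <- filter_components(
  tracks_to_label_volume(tracks, series, n_frames = 12,
                         voxel_size = c(0.110, 0.043, 0.043)))

heights <- measure_heights(labels)
rows    <- row_assign(heights, method = "gmm", seed = 7)
dplyr::left_join(heights, rows[c("bundle_id", "row")], by = "bundle_id")
#> # A tibble: 17 × 9
#>   bundle_id    x1    y1    z1    x2    y2    z2 height_um row
#>       <int> <int> <int> <int> <dbl> <dbl> <int>     <dbl> <fct>
#> 1         1   227    29     3   227    63     7      1.53 OHC3
#> 2         2    95   179     3    95   213     8      1.56 IHC
#> 3         3    29    33     3    29    67     8      1.56 OHC3
#> # …
```

Each row is one reconstructed bundle: tip voxel `(x1, y1, z1)`, base voxel
`(x2, y2, z2)`, physical height in µm (here ≈1.5 µm, a typical neonatal
mouse bundle at 0.043 µm xy / 0.110 µm z voxels), and its hair-cell row.

Detection quality against the known ground truth:

```r
match_instances(ph$labels, labels, iou_threshold = 0.5)
#> # A tibble: 1 × 8
#>   iou_threshold    tp    fp    fn precision recall    f1 detection_accuracy
#> 1           0.5    15     2     1     0.882  0.938 0.909              0.833
```

The 10% per-frame dropout split one bundle across a gap: 15 of 16 true
bundles matched at IoU ≥ 0.5, one split remnant counts as a false positive
and the lost bundle as a false negative. `autoplot(sweep_thresholds(...))`
draws the full 19-threshold curve.

Observer agreement on the built-in 18-bundle height benchmark (automated
pipeline vs two human experts):

```r
tab <- height_agreement_data()
glance(agreement(tab$vascilia, tab$observer1))
#> # A tibble: 1 × 5
#>       n mean_x mean_y pearson_r paired_t
#> 1    18   3.14   3.03     0.943     1.87
```

A strong correlation (r = 0.94) with no significant paired difference:
the automated heights are statistically interchangeable with the human
measurements.

A thin command-line front end over the same functions lives at
`inst/cli/bundlekit3d.R` (subcommands `simulate`, `reconstruct`, `measure`,
`intensity`, `rows`, `evaluate`, `batch`).

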