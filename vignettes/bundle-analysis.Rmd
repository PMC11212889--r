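---
title: "Methods: 3D stereocilia-bundle reconstruction and morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D stereocilia-bundle reconstruction and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlekit3d)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## The measurement problem

Cochlear hair cells carry stereocilia bundles — V-shaped arrays of
actin-rich protrusions — whose heights increase tonotopically from the base
to the apex of the cochlea and whose coordinated in-plane orientation
(planar cell polarity, PCP) underlies directional mechanotransduction.
Confocal stacks of phalloidin-stained tissue capture these bundles in 3D,
but most segmentation models operate per 2D frame. The package therefore
takes *per-frame 2D instance masks from any segmenter* as its input
boundary and handles everything after that: 3D instance reconstruction,
physical measurements, and the statistics used to validate them. Training
or shipping the upstream segmentation networks is explicitly out of scope;
heuristic stand-ins (and a phantom generator) make every stage testable
without them.

## Conventions

Arrays are indexed `(z, y, x)`, 1-based; z = 1 is the first acquired plane
and y increases downward, as in raster images. Voxel sizes are given in µm
per axis and are mandatory for physical outputs; without them computations
proceed in voxel units with a warning. The default scale, 0.110 µm z-steps
and 0.043 µm xy pixels, mirrors common Airyscan acquisitions of mouse
cochlea and puts phantom bundle heights in the realistic 1–5 µm range.

## Reconstruction by overlap tracking

`assign_tracks()` processes frames in order. Frame-1 detections each seed a
track. Later detections claim the eligible track whose last stored mask
they overlap most, provided the overlap reaches `min_overlap` (default 1
pixel — "significant overlap" is left open by the underlying idea, so the
package makes it an explicit parameter rather than a hidden constant).
When several detections claim one track, the largest overlap wins and the
losers *always* seed new tracks (the alternative — silently dropping them —
would violate detection conservation, which the tests assert). Ties go to
the lower track ID and, among detections, to the larger area then the lower
frame-local ID, which makes the outcome independent of processing order.

Eligibility is controlled by `max_gap` (default 0: previous frame only,
since real bundles are z-contiguous). Raising it to 1 lets tracks bridge
single-frame dropouts, which the dropout phantom exercises.

An independent matrix-form restatement of the same rule serves as the test
oracle on small random series, and the noise-free phantom round-trip must
achieve per-instance IoU 1.0.

`filter_components()` removes reconstructed instances below `min_frames = 2`
planes or `min_voxels = 20` voxels — deliberate, visible defaults at the
phantom scale for a filtering step whose criteria are usually left
unstated.

## Height measurement

For each instance, the binary z-projection is computed (occupancy in any
plane), and:

* the **tip** is the topmost projection pixel (minimal y, ties to minimal
  x); its z is the shallowest plane occupied at that (x, y);
* the **base** is found by walking straight down (+y) from the projection
  centroid at fixed x until the support ends, stepping back one pixel; its
  z is the deepest plane the instance occupies anywhere.

Height is the scaled Euclidean distance between the two voxels. The walk
assumes the mask is filled below its centroid, which holds for real
segmentation masks (bundles are dense V-shaped wedges); for pathological
concave shapes where the centroid is off-support, x snaps to the nearest
support column in the centroid row and the output is flagged. When several
planes contain the tip pixel the shallowest is used — the tip of the
tallest stereocilium is the first thing to appear as the stack descends
into the tissue.

Because the distance is taken through the stack rather than from a
projection, it is rotation-invariant: the tests require < 5% change under a
15° in-plane rotation, and recovery within one voxel diagonal of phantom
truth across 100 seeded bundles.

## Orientation

Two endpoint strategies on the binary projection, then identical angle
arithmetic:

* **height only** — on each side of the centroid's x, the lowest pixel
  (ties to the horizontally outermost). Ideal for clean V shapes; on
  J-shaped or truncated bundles it can land on a non-wing pixel, which is a
  documented limitation rather than a bug.
* **height and distance** — on each side, pixels within `tolerance_px` of
  that side's lowest y compete by Euclidean distance from the peak.
  `tolerance_px` defaults to 2 px, appropriate for PCP-aligned stacks where
  the baseline is nearly horizontal. For deliberately tilted inputs the
  band must cover the baseline tilt across a half-width
  (≈ `half_width × tan(tilt)`; about 4 px at 10° for default phantoms), so
  the angle-recovery analyses use `tolerance_px = 6`. In the intended
  pipeline, rotation correction precedes orientation, keeping residual
  tilts small.

From left point L, right point R and peak P: the baseline angle is
`atan2(Δy, Δx)` of L→R mapped to [0, 180); the axis angle is the direction
from the midpoint of LR to P (a symmetric upright V gives exactly 90°); the
apex angle is the opening angle at P. All three are exported; the axis
angle is the headline "orientation" because observed orientation
distributions center near 90° for upright bundles, matching the axis rather
than the ~0° baseline.

## Region measurements

Fifteen measurements per instance: voxel count, physical volume, centroid,
exposed-face surface area (faces between an instance voxel and anything
else, weighted by the physical face area — a solid a×b×c box yields exactly
2(ab+bc+ca)), z-depth, and, on the projection: area, perimeter (exposed
pixel-edge length, so a single pixel has perimeter 4sₓ), eccentricity and
axis lengths from the central-moment ellipse, equivalent diameter, solidity
(area over convex-hull area, clamped to 1 for degenerate hulls), extent,
and major-axis orientation. Degenerate single-voxel instances get defined
values (eccentricity 0, solidity 1) rather than NaNs.

## Intensity quantification

`per_layer_intensity()` sums the fluorescence channel over each bundle's
voxels per plane. Background subtraction, when enabled, subtracts the
per-plane mean of all voxels outside every mask times the bundle's voxel
count in that plane, clamped at zero — the simplest estimator consistent
with "subtract ambient background", and documented as such.

Segmentation depth varies across bundles (signal strength, imaging depth,
biology), which biases raw totals. Three aggregation modes address this:

1. sum over all detected layers;
2. sum over exactly n layers per bundle, n = the largest depth shared by
   all bundles compared (their minimum depth). "Which n layers" is
   genuinely ambiguous, so the package defaults to the n layers from the
   bundle's shallowest plane (the anatomically tip-side layers, always
   defined and deterministic) and offers a brightest-n variant behind
   `top_rule = "brightest"`;
3. pad shallower bundles to the maximum depth by repeating their
   weakest-layer value, then sum.

For non-negative intensities mode 2 ≤ mode 1 ≤ mode 3 always, with equality
when depths match; both facts are asserted in the tests, as is conservation
(mode-1 totals sum to the masked voxel intensity sum). Mean intensity is
the mode-1 total over the bundle's voxel count. Max normalization divides
by the group maximum, mapping it to 1.

## Row identity

Rows are horizontal bands after PCP alignment, so the base-point
y-coordinate is the discriminative feature; clustering uses it alone by
default (an (x, y) option exists behind a flag). K-means (10 restarts under
a fixed seed) and a 1-D Gaussian mixture (unequal variances, falling back
to pooled variance when the richer model cannot be fit on few points) are
both offered; with exactly k bundles each becomes its own cluster directly.
Cluster means are ordered by descending y: bottom-most is IHC, then OHC1,
OHC2, OHC3. The mapping is permutation-invariant and tied means are an
error, not a silent choice. On well-separated phantoms both backends must
reach zero errors; on deliberately overlapping rows they may disagree, and
the misassignment rate against phantom truth is what the tests report.

## Detection evaluation

Instances are matched by 3D IoU. All overlapping (GT, prediction) pairs are
ranked by descending IoU and matched greedily one-to-one, so a GT instance
keeps its largest-overlap prediction and any further prediction on it
becomes a false positive. Pairs at or above the threshold are TP; unmatched
predictions FP; unmatched GT FN. True negatives are not counted — background
voxels dominate and would inflate every metric. The sweep runs thresholds
0.10–1.00 in 0.05 steps (19 values) with TP non-increasing and FP/FN
non-decreasing by construction.

Detection accuracy is TP/(TP+FP+FN), the definition uniquely consistent
with reported (F1, accuracy) pairs via the identity acc = F1/(2−F1), which
holds exactly for every result and is asserted on random counts. Whether
ties should be resolved jointly is open; an exhaustive optimal matcher
(`method = "optimal"`) is available and agrees with the greedy rule on the
small-volume oracle suite.

Descriptive statistics default to population (divisor n) standard
deviation — the normalization that reproduces the published benchmark
table's value (0.725 population vs 0.747 sample) — with a sample option.
The agreement battery (Pearson, paired t with df = n−1, Wilcoxon
signed-rank dropping zero differences, Mann–Whitney U exact for small
tie-free samples) uses the standard `stats` implementations; identical
paired series return t = 0 rather than an error.

## Frame-level stack logic

**Zones.** Stacks pass through a pre-cellular zone, a cellular-clarity zone
(CCZ) and a noise-saturation zone; only CCZ frames are analyzed. The
"switches" stability count is only ever named, not defined, by its source
idea, so the package adopts the rule: a switch is any decreasing transition
or any forward transition repeating one already used. This scores exactly 0
on the clean monotone 0→1→2 profile and is positive for every fluctuation;
the equivalence "0 switches ⟺ non-decreasing" is property-tested. Because
plugged-in classifiers may emit non-contiguous CCZ labels, `ccz_range()`
takes the longest run (first on ties) — a conservative extension of the
contiguous case.

**Rotation.** Per-frame scores over 72 classes (class c ↔ 5c degrees) are
averaged across frames, the argmax (lowest class on ties) gives the
predicted angle, and the stack is rotated by 360° minus it.
`rotate_and_crop_max_rect()` then crops the largest axis-aligned rectangle
inside the rotated footprint, from the closed form for a rotated W×H
rectangle (a 256×256 frame at 45° yields ⌊256/√2⌋ = 181), verified to
contain no padding for all 72 class angles.

**Tonotopic vote.** The stack's cochlear region (BASE/MIDDLE/APEX) is the
majority of per-frame predictions over a 13-frame window starting at the
median frame ⌊(F−1)/2⌋ (0-based), clipped at the stack end — the edge
handling is the package's own definition since none is stated. Ties go to
the label with the higher summed score, else the earlier label.

## Texture

GLCM features use a symmetric, normalized co-occurrence matrix; parameters
default to 256 levels, distance 1, and the average over angles
{0°, 45°, 90°, 135°} (whether one angle or an average was used originally
is unknowable from the description; averaging is the common choice and
halves orientation sensitivity). Level binning rescales the crop's own
range, making features invariant to uniform intensity offsets. A constant
crop returns contrast 0, energy 1, homogeneity 1 and a *flagged* (NA)
correlation rather than a fabricated 0. The strict two-level checkerboard
closed forms (contrast 1, energy 0.5, homogeneity 0.5) anchor the tests.

LBP uses P = 8, R = 1 with nearest-pixel sampling and the uniform mapping —
the only convention with bins indexed 0–9 (bit counts 0..8 plus the
non-uniform bin). The ≥ comparison sends a constant crop to bin 8. The
histogram is normalized, invariant to strictly increasing intensity
transforms, and checked against a per-pixel brute-force oracle.

Group comparison is the two-sided Mann–Whitney U as implemented by
`stats::wilcox.test` (exact for small tie-free samples; normal
approximation with tie correction otherwise), reporting group medians
alongside; {1,2,3} vs {10,11,12} gives U = 0, exact p = 0.1.

## The phantom generator

Phantoms are the package's study conditions, not a tuning dial. Each bundle
is a filled V wedge — a triangle with its apex on top — extruded over its
z-range, in four horizontal rows (IHC bottom-most, then OHC1–3), with
Gaussian-jittered base positions, constant amplitude over a constant
background, Gaussian intensity noise (labels stay noise-free), and an
optional global rotation applied last so alignment logic can be tested
against a known angle. Wedges are filled rather than drawn as two bare
strokes because the centroid-descent base trace — like the real masks it
was designed for — requires support below the centroid; hollow strokes
would terminate the walk early and misstate the height. Out-of-bounds
bundles (including after rotation) are an error listing the offending IDs;
nothing is clipped silently.

Defaults: 12×256×256 voxels at (0.110, 0.043, 0.043) µm, wing half-angle
35°, wing length 42 px, depth 6 planes, amplitude 180 over background 20,
noise SD 8, base jitter SD 2 px — heights ≈1.6 µm, the scale of neonatal
mouse bundles. Test suites use a smaller 8×120×140 configuration for speed;
the acceptance script measures 25 such phantoms (100 bundles) for height
recovery, a 12×256×256 three-per-row layout for rotation analyses, and a
4×8 layout for row assignment.

`degrade_to_frame_masks()` turns truth labels into segmenter-like per-frame
detections: random frame-local relabeling, Bernoulli dropout per
bundle-frame, and splitting across the principal axis. What phantoms do
*not* emulate: PSF blur, anisotropic noise, touching bundles, cuticular
plate signal, intensity falloff with depth. Passing tests therefore
demonstrate algorithmic correctness on geometrically faithful inputs, not
segmentation robustness on real tissue — the latter remains the segmenter's
burden, outside this package's boundary.

## Benchmark data

`height_agreement_data()` ships the 18-bundle validation table (automated
measurements and two human observers, four datasets: two wildtype, two
Eps8-KO with AAV rescue, heights in µm). It is the input to the agreement
statistics the acceptance script recomputes: automated column mean 3.137 /
median 3.166 / population SD 0.726, Pearson r of 0.943 / 0.802 / 0.830 and
paired t of 1.869 / 1.192 / 0.180 for the three column pairs.

## Problem sizes and determinism

Every stochastic step takes an explicit seed (phantom noise, degradation,
clustering restarts, the GMM initialization), and the batch pipeline is
byte-deterministic given its seed — re-running a configuration reproduces
identical CSVs. The test suite completes in well under a minute on one CPU
with the phantom sizes above; the acceptance script in under half a minute.
These sizes were chosen as the smallest at which every property is
non-trivially exercised (multiple bundles per row, multiple occupied
planes, realistic µm scales).

## Known limitations

* The base trace assumes filled masks; thin hollow V outlines would need a
  different base rule.
* "Height only" orientation misreads bundles without a clear V, by design;
  use "height and distance" there.
* The greedy instance matcher can in principle differ from the optimal
  assignment under contrived IoU ties; the optimal matcher is provided for
  small volumes and agrees on everything the suite generates.
* Macro accuracy averages per-class (TP+TN)/N one-vs-rest values, so
  `accuracy + error_rate = 1` holds only for two-class problems (in
  general macro accuracy is 1 − 2e/k).
* Single-stereocilium resolution is out of scope; measurements are
  per-bundle.
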