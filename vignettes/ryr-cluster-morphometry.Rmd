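---
title: "Nanoscale RyR2 cluster morphometry: models, parameters and verification"
author: "ryrclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoscale RyR2 cluster morphometry: models, parameters and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryrclust)
```

## The measurement problem

Cardiac ryanodine receptors (RyR2) sit in the junctional sarcoplasmic
reticulum in clusters of a few to a few hundred channels; each channel has a
roughly 30 x 30 nm membrane footprint. Clusters whose edges lie within about
150 nm of each other are thought to act as one calcium release unit (CRU),
and cluster position relative to the sarcomeric z-disk (marked by
alpha-actinin) shapes how calcium release propagates. Single-molecule
localization microscopy (dSTORM) resolves this organization: an acquisition
of ~20,000 camera frames yields a table of localization events which is
rendered into a grayscale image whose pixel intensity is proportional to the
local event density, and all downstream morphometry operates on that image.

`ryrclust` implements the full analysis chain — rendering, cluster
segmentation, channel-count/packing/nearest-neighbour metrics,
CRU (super-cluster) grouping, z-disk colocalization, cell-size morphometry
with clinical normalization, and hierarchical group statistics — together
with a synthetic-scene generator that provides exact ground truth for every
stage. Patient imaging data of this kind are generally not deposited, so
verification is property-based: every measurement is tested against brute
force oracles and against scenes whose true geometry is known.

## The synthetic scene model

`simConfig()` + `buildScene()` generate a ground-truth scene:

* **Cluster sizes.** Observed size distributions are strongly right-skewed
  (median ~4 channels against a mean of ~18). No one-parameter counting law
  matches both order statistics, so sizes follow a two-component mixture:
  with weight `w` a uniform draw on {1..6}, otherwise a geometric tail.
  `w` and the tail mean are solved numerically at configuration time so the
  mixture mean equals the target exactly and the CDF pins the median
  (defaults: mean 18, median 4, giving `w` ~ 0.82 and a tail mean of ~84).
* **Cluster geometry.** A cluster of *n* channels occupies the *n* most
  central sites of a randomly rotated square grid of pitch one channel
  footprint (30 nm); an `occupancy` parameter below one thins the grid.
* **CRU structure.** Group sizes are drawn so that a configured fraction of
  clusters (default 0.70) has an in-group neighbour below the 150 nm cutoff
  and the mean group size hits its target (default 2.18): the singleton
  probability is `(1 - f) * mu` and multi-member groups are `2 + geometric`.
  Members chain at edge-to-edge gaps drawn uniformly from 60-140 nm,
  branching from any already-placed member; distinct groups are kept at
  least 220 nm apart so the within-cutoff fraction is controlled by
  construction. Placement is rejection sampling; groups containing a giant
  cluster are placed first (placement order enters no statistic), an
  unplaceable multi-member group is split into smaller CRUs, and only an
  unplaceable singleton raises the over-density error.
* **Z-disks.** Straight horizontal bands (default width 200 nm, period
  1,800 nm, random phase; only whole bands inside the field). A configured
  fraction of groups (default 0.45) is seeded on a band with members chained
  along the band axis — the physiological CRU arrangement — and the rest
  are seeded between bands. Under the default density the realized
  cluster-level aligned fraction is ~0.36-0.41 rather than 0.45, because
  crowded bands occasionally force a group to fall back to interior
  placement; the stored per-scene truth is always the realized geometry.
  Setting `zdiskAlignedFraction = NA` places clusters uniformly — the null
  geometry used to calibrate the alignment measurement.
* **Blinking acquisition.** Each channel is labeled with probability
  `labelingEfficiency` (default 0.5; the true efficiency of any given
  immunolabeling is unknown, so it is exposed, not asserted); each label
  blinks a geometric number of times (mean 5, support 1, 2, ...); each blink
  yields one localization displaced by isotropic Gaussian error
  (`localizationSigma`, default 15 nm, i.e. ~30 nm lateral resolution);
  background events arrive as a homogeneous Poisson process (default
  2 per square micron). Frames are uniform over the acquisition and unused
  downstream; raw-frame movies and richer photophysics are out of scope.
* **Determinism.** One integer seed, split deterministically per stage;
  identical (config, seed) pairs reproduce scenes, events and rendered
  files byte for byte.

Every stored "true" metric — mean cluster size, density, the edge-to-edge
nearest-neighbour distribution, the fraction of clusters within 150 nm, the
CRU partition, z-disk alignment — is recomputed from the final channel
positions by exhaustive brute force after placement, so construction
approximations cannot leak into the ground truth. True edge-to-edge distance
between clusters is the minimal channel centre-to-centre distance minus one
footprint, floored at zero.

What the generator does *not* emulate: sample drift and registration error,
anisotropic or depth-dependent localization precision, antibody-specific
label multiplicity, curved or branching z-disks (the straight-band default
is chosen for testability; real z-disks are not linear), and tissue
autofluorescence. Passing recovery tests therefore demonstrates that the
measurement chain is unbiased under the stated acquisition model, not that
any particular biological dataset would be recovered perfectly.

## Rendering

`renderEvents()` converts events to a density image at 5 nm/pixel (0-based
pixels, x to columns, y to rows, half-open pixel intervals). Each event
deposits a unit-mass Gaussian integrated exactly over pixels and
renormalized inside the field, so the pre-quantization pixel sum equals the
total event weight to floating precision regardless of truncation or edge
clipping; `kernelSigma = 0` degenerates to plain binning. The default
kernel is 7.5 nm — half the localization precision. A wider kernel (10 nm
was evaluated) visibly bridges sub-cutoff inter-cluster gaps and merges
CRU members into single segmented clusters; half the precision keeps the
density-proportionality contract while adding negligible extra blur.

16-bit quantization maps the 99.9th percentile of positive densities to
60,000 counts (clipping only the extreme tail); the linear scale is stored
in the image and in a JSON sidecar next to every TIFF so counts convert
back to density exactly.

## Segmentation and per-cluster metrics

Clusters are 8-connected components above an intensity threshold.
Threshold policies (`estimateThreshold()`): percentile of nonzero pixels
(70th by default), Otsu on the nonzero pixels, a fixed value, or — the
pipeline default — an absolute **density threshold of one event per
channel footprint** (1/900 nm^-2). The percentile policy drifts with field
occupancy (the nonzero support is dominated by the Gaussian halo around
clusters, whose extent depends on how much of the field is labeled); the
absolute policy exploits the density-proportional rendering contract and
was the only evaluated policy keeping cluster-count recovery inside +/-10%
on ground-truth scenes.

Detection and delineation are deliberately split (two thresholds). After
detection, components whose integrated event mass is below `minEvents`
(default 2) are discarded — enough to remove single-blink background while
keeping genuine one-channel clusters, ~20% of which emit only one blink
under the geometric law. Each retained cluster is then re-cut at 0.55 of its
median pixel intensity (largest connected piece kept): localization error
and the kernel widen the mask by ~15 nm per side, and the cut
returns the boundary to the physical channel footprint. On fully labeled
scenes this brings mean estimated channel count to within ~7% and mean
edge-to-edge nearest-neighbour distance to within ~3% of truth; without
refinement both are biased by 15-25%. Channel counts are area-based:
`max(1, round(area / 900 nm^2))`. Packing density is reported as mean
rendered intensity over the cluster pixels, in arbitrary units — no
absolute channel-intensity calibration is attempted.

Nearest-neighbour distances are exact Euclidean distance-transform values
of the remaining clusters sampled at the focal cluster's pixels (computed
on expanding windows, so the result equals the brute-force minimum over
all pixel-centre pairs — asserted against that oracle in the tests).
Distances are pixel-centre to pixel-centre. Border-touching clusters are
flagged and excluded from reported distributions (their true neighbour may
lie outside the field) but remain usable as neighbours. The analysis area
for cluster density is the ROI when one is supplied, otherwise the
morphological closing (radius 1 um, computed via two exact distance
transforms) of the thresholded labeling — a proxy for the labeled cell
footprint.

## Super-cluster grouping

`groupSuperclusters()` partitions clusters into CRUs: connected components
of the graph joining clusters whose edge-to-edge distance is at most the
cutoff (150 nm). The production path thresholds the Euclidean distance
transform of the mask at half the cutoff plus a one-pixel guard band,
labels the dilated mask to generate candidate groups in O(pixels), then
confirms each candidate edge with an exact boundary-pixel distance. The
guard band matters: pure half-cutoff dilation on a pixel grid both misses
pairs just inside the cutoff and merges pairs just outside it (the
midpoint pixel centre need not be equidistant), so dilation alone is only
equivalent to the graph up to +/-1 pixel; with the guard band plus exact
confirmation the produced partition equals the brute-force graph partition
identically, which the acceptance suite asserts on 100 random masks.
Singletons count as CRUs of size one, so the mean members-per-CRU is well
defined. Two readings of "fraction of clusters within 150 nm" are emitted:
the per-cluster nearest-neighbour reading (headline) and membership in a
multi-cluster CRU; they differ only through border-cluster handling.

## Z-disk analysis

The widefield alpha-actinin channel (simulated as z-disk bands convolved
with a 250 nm Gaussian PSF, integrated over 100 nm camera pixels) is
resampled to the dSTORM grid and segmented into a band mask. The default
policy is ridge-based: band center-lines are the intensity centroids of
above-half-max segments of the row-mean profile, and the physical band
width comes from the profile's local second moment after subtracting the
PSF variance, the window-truncation shrinkage (Gaussian fixed point), and
the camera pixel-integration variance twice (acquisition integration and
the nearest-neighbour resampling staircase each contribute px^2/12). Width
deconvolution of a 200 nm band under a 250 nm PSF is ill-conditioned, which
is exactly why global Otsu fails here: the blurred ridge is much wider than
the band, and Otsu-style thresholds inflate the mask about four-fold.
Bands too close to the field edge for a full moment window inherit the
median width of the interior bands (z-disks across one cell share their
width). The moment-corrected estimate recovers band area to within ~5-10%
on simulated channels. Otsu and quantile policies remain available for
non-band-like reference channels.

A cluster is "aligned" when its centroid pixel falls on the mask
(centroid-in-mask is scale-stable for large clusters; any-overlap would
grow with cluster size). The labeling-distribution metric is the fraction
of total rendered RyR2 intensity on pixels whose exact distance to the
mask is at most a window (0 nm = co-localized; default window 300 nm,
measured from the mask edge, not the band center-line — an explicit
assumption). The distance map guarantees monotonicity in the window and
fractions in [0, 1]; under uniform cluster placement the aligned
percentage equals the mask area fraction within sampling error, which is
the calibration the acceptance suite runs.

Widefield-to-dSTORM registration is assumed exact (simulation shares
coordinates; ingested data must be pre-registered) — no registration
algorithm is implemented.

## Morphometry and clinical normalization

Cell cross-sectional areas come from supplied label masks at confocal
scale (tracing itself is out of scope; `syntheticCellLabels()` builds test
fixtures with known areas). Body surface area uses the Du Bois formula
`0.007184 * weight^0.425 * height^0.725` (kg, cm, m^2), atrial end-systolic
volumes are indexed as mL/m^2 by exact division, and the
hypertrophy-dilation relationship is a Pearson correlation with the
two-sided t-transform p-value.

## Hierarchical statistics

Metrics are measured per cluster, averaged per image, then averaged
(unweighted by cluster count — the declared convention) per patient; the
patient is the unit of analysis everywhere, and duplicating images within
a patient provably changes nothing. Group comparison follows a gated
decision tree at alpha = 0.05: Shapiro-Wilk per group (any failure:
Kruskal-Wallis with tie-corrected, Bonferroni-adjusted Dunn post hoc);
otherwise Brown-Forsythe-Levene (failure: Welch ANOVA with Games-Howell);
otherwise one-way ANOVA with Tukey HSD. The gate tests and post-hoc
procedures are declared defaults — the branch *conditions* (non-normality,
unequal variance) are standard, the specific gates are a design choice —
and every result logs its full decision path. A group of identical values
cannot be tested for normality and is treated as not rejecting it. The
tree's realized type-I error is ~5% under Gaussian and heavy-tailed nulls
at the study's group sizes (10/9/8 patients), verified by simulation.
Group summaries are mean +/- SEM over patients. `blindGroups()` replaces
labels with opaque random codes (checksummed key stored separately;
unblinding with a wrong key fails outright), so the analysis can run
blinded end to end.

## Numerical choices and degenerate inputs

* Distances and connectivity: 8-connected components; exact Euclidean
  distance transforms; pixel-centre metric throughout (the 150 nm cutoff
  equals 30 pixels at the 5 nm rendering scale).
* Empty cases are values, not errors: zero density gives an empty scene,
  an empty mask an empty ClusterSet, an all-zero actinin channel is the
  one hard error ("no z-disk signal").
* Ties in Otsu are broken toward the lower bin; the Dunn statistic uses
  the tie-corrected rank variance.
* Quantization clips only above the 99.9th percentile; mass conservation
  is asserted pre-quantization.
* All scene-level randomness flows from one integer seed split per stage
  (Lehmer-style mixing), so every artifact is reproducible bit for bit.

## Problem sizes used in verification

The shipped tests run the generator at its default study conditions
(6 x 6 um fields, 4.3 clusters/um^2, ~150 clusters and ~14,000 events per
scene): 20 fully-labeled scenes for parameter recovery, 50 uniform-null
scenes for alignment calibration, 100 random masks (up to ~320 x 320 px)
for the distance and grouping oracles, 1,000 replicates for the type-I
calibration and 2,000 draws for the size-law order statistics. These sizes
put Monte-Carlo error comfortably inside each asserted band; all reported
empirical numbers above (recovery within ~5-10%, type-I ~5%) are the
quantities those tests and `scripts/acceptance.R` themselves compute.

## Known limitations

* Detection at one event per footprint cannot see one-channel clusters
  that blinked once or twice; at full labeling ~6% of clusters are lost
  this way (reported as the density recovery bias), and at 0.5 labeling
  efficiency the loss grows — the acceptance script reports the
  degradation explicitly rather than asserting it away.
* The ridge z-disk segmenter assumes roughly horizontal bands, matching
  the simulator and the alignment convention; arbitrary-orientation
  reference channels should use the Otsu/quantile policies and will
  inherit their mask-inflation bias.
* Packing density is an arbitrary-unit proxy; no claim is made about
  absolute channel occupancy within a cluster.
* Event tables are assumed drift-corrected and precision-filtered
  upstream; the CSV reader validates only field bounds.

## A minimal session

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1, labelingEfficiency = 1)
scene <- buildScene(cfg)
events <- simulateEvents(scene)
res <- analyzeImage(events, actinin = simulateActininWidefield(scene))
res$metrics
trueMetrics(scene)[c("meanClusterSize", "clusterDensity", "pctWithinCutoff")]
```
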