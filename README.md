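# ryrclust

Nanoscale morphometry of cardiac ryanodine receptor (RyR2) clusters from
single-molecule localization microscopy (dSTORM), with a ground-truth
simulator for end-to-end verification.

## The problem this package addresses

RyR2, the sarcoplasmic-reticulum calcium release channel, sits in the
junctional membrane of cardiomyocytes in clusters; each channel occupies a
~30 x 30 nm footprint. Two organizational scales matter for arrhythmia
research: clusters whose edges lie within ~150 nm of each other behave as
one calcium release unit (CRU, "super-cluster"), and clusters normally
align with the sarcomeric z-disk (marked by alpha-actinin). A dSTORM
acquisition (~20,000 frames) produces a table of localization events that
is rendered into a grayscale image at 5 nm/pixel whose intensity is
proportional to local event density; all morphometry operates on that
image.

`ryrclust` implements the full analysis chain for studies of this design,
for imaging scientists and cardiac-EP labs:

* **Simulation** — `simConfig()`, `buildScene()`, `simulateEvents()`,
  `simulateActininWidefield()`: scenes with known channel positions,
  cluster/CRU structure and z-disk geometry (heavy-tailed size law with
  median ~4 and mean ~18 channels per cluster, ~4.3 clusters/µm², ~70% of
  clusters within 150 nm of a neighbour, ~2.2 clusters per CRU), plus a
  geometric-blinking acquisition model. Every stored "true" metric is
  recomputed from the placed positions by brute force.
* **Rendering** — `renderEvents()`: density-proportional images with exact
  mass conservation; 16-bit TIFF round trips with recorded intensity scale.
* **Cluster analysis** — `segmentClusters()`, `estimateChannels()`,
  `clusterDensity()`, `nearestNeighborDistances()`: threshold + 8-connected
  components, area-based channel counts (`area / 900 nm²`, floored at 1),
  packing density (a.u.), exact edge-to-edge nearest-neighbour distances.
* **Super-clusters** — `groupSuperclusters()`, `superclusterMetrics()`:
  CRU grouping at the 150 nm Euclidean cutoff (distance-transform candidate
  generation, exact confirmation — identical to the brute-force graph
  partition), % of clusters within the cutoff, members per CRU, CRU-to-CRU
  nearest-neighbour distances.
* **Z-disk analysis** — `segmentZdisks()`, `clusterZdiskAlignment()`,
  `labelingFractionNearZdisk()`: band segmentation of the widefield
  alpha-actinin channel with PSF-deconvolved width, centroid-on-mask
  alignment, and the fraction of RyR2 labeling co-localized with or within
  300 nm of the z-disk.
* **Morphometry & clinical** — `cellAreas()`, `duBoisBSA()`
  (BSA = 0.007184 · W^0.425 · H^0.725), `indexVolume()`,
  `correlatePatients()` (Pearson r, r², two-sided p).
* **Statistics** — `aggregateStudy()` (cluster → image → patient; the
  patient is the unit of analysis), `compareGroups()` (Shapiro-Wilk →
  Kruskal-Wallis/Dunn; Brown-Forsythe-Levene → Welch/Games-Howell; else
  ANOVA/Tukey; full decision path logged), `blindGroups()`/`unblindGroups()`,
  `reportTables()`.
* **Pipeline** — `pipelineConfig()`, `runSimulate()`, `runAnalyze()`,
  `runStats()`, plus a thin command-line front end at
  `inst/cli/ryrclust.R` (subcommands `simulate`, `analyze`, `stats`,
  `show-config`).

## Worked example

Simulate one fully-labeled field under the default study conditions,
analyze it, and compare with the scene's exact ground truth:

```r
library(ryrclust)

cfg   <- simConfig(seed = 1, labelingEfficiency = 1)
scene <- buildScene(cfg)
res   <- analyzeImage(simulateEvents(scene),
                      actinin = simulateActininWidefield(scene))
round(res$metrics, 2)
#>                 n_clusters mean_cluster_size_channels
#>                     136.00                      17.28
#>    cluster_density_per_um2            mean_packing_au
#>                       3.78                       0.11
#>                     nnd_nm          pct_within_cutoff
#>                     161.07                      60.45
#>  clusters_per_supercluster        supercluster_nnd_nm
#>                       1.77                     292.89
#>          pct_zdisk_aligned       fraction_colocalized
#>                      40.44                       0.17
#>     fraction_within_window
#>                       0.36

tm <- trueMetrics(scene)
round(c(size = tm$meanClusterSize, density = tm$clusterDensity,
        within = tm$pctWithinCutoff, aligned = tm$pctZdiskAligned), 2)
#>    size density  within aligned
#>   19.73    3.86   58.27   38.85
```

Reading the output: this field drew 139 true clusters at 3.9 clusters/um^2
with a mean of 19.7 channels each; the pipeline segmented 136 clusters
(one-to-two-blink singletons fall below the detection floor), estimated
17.3 channels per cluster from mask area, and put 60% of clusters within
150 nm of a neighbour against a ground truth of 58%. Alignment (40.4% of
cluster centroids on the segmented z-disk mask) is measured against the
mask the pipeline itself segments from the widefield channel (band-geometry
truth: 38.9%). Packing density is in arbitrary rendered-intensity units;
single-field deviations like these average out across a study (the
acceptance run below pools 27 fields).

A grouped study is one call per stage:

```r
summary <- runAnalyze(inputs, config = pipelineConfig())  # per-image rows
study   <- runStats(summary)                              # patient-level tests
study$report$text                                         # mean ± SEM table
```

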