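# wheatrecon

Data-driven 3D reconstruction and phenotyping of single wheat plants from
organ-labelled point clouds.

Modern multi-view-stereo (MVS) phenotyping platforms deliver dense point
clouds of potted wheat plants, and deep segmentation networks attach a
semantic label (leaf / tiller / ear) and an organ instance id to every
point. Turning that labelled cloud into *plant architecture* — which points
form which tiller axis, where each leaf inserts, how long and wide each
blade is — is the part this package implements. It is aimed at plant
phenotyping researchers and breeders who need per-organ trait tables from
segmented single-plant clouds, and at method developers who need a fully
controlled synthetic benchmark for skeleton-extraction pipelines.

## Method

**Tiller skeletons.** The tiller-labelled points are cut into horizontal
slabs of height 2 cm from the lowest point upward; each slab's
xy-projection is clustered with DBSCAN, and each cluster is summarised by
its 3D centroid *SP<sub>nm</sub>* (optionally, the sparse slab points are
replaced by sampled cylinders of height 2 cm and radius 0.5 cm to repair
the cloud). The centroids are then chained by a scored top-down search:
every pair (i, j) receives

    score_ij = alpha * h_ij + beta * v_ij

with *h* the horizontal and *v* the vertical distance (defaults alpha = 2,
beta = 1). Working from the highest centroid downward, each point either
extends the chain whose head offers the lowest admissible score — subject
to caps on score, link slope from vertical, inter-segment bend, and skipped
slabs — or seeds a new chain. Chains with fewer than 4 points are
discarded; surviving chains S<sub>t,k</sub> are extended vertically from
their original base height H<sub>S<sub>t,0</sub></sub> down to the lowest
tiller point H<sub>0</sub>.

**Leaf skeletons.** Each leaf instance is divided along its axis by
k-means (k = 4 below 1000 points, k = 7 at or above), segment centroids
LP<sub>i</sub> form the skeleton nodes, the blade endpoints are the segment
points farthest from the neighbouring segment's centroid, and the polyline
is closed by nearest-neighbour chaining. The base endpoint is chosen by
wheat morphology (splayed lower leaves: endpoint nearer the plant centre;
upright upper leaves: lower endpoint) and corrected by the minD/avgD rule:
if a leaf's base-to-skeleton distance minD exceeds 1.75 x the plant-wide
mean avgD, the other endpoint is tested and swapped when closer. The leaf
is snapped to its attachment point — the nearest tiller skeleton point —
completing the phytomer assembly.

**Phenotyping.** From the assembled model the package extracts the 18
plant-morphology parameters: tiller count and main stem; tiller length

    H_t = sum_k dist(S_t,k , S_t,k+1) + (H_St,0 − H_0)

tiller-to-main-stem angle and azimuth (1/3- and 2/3-height vectors); plant
height; girth (diameter of the smallest enclosing circle, via Welzl's
algorithm, of the tillers' mid-height cross-section); leaf count, length
(polyline sum), width (second-principal-axis extent of the mid-blade
segments), stem-leaf angle, azimuth, attachment point and venule nodes; ear
count, length (first-principal-axis extent), attachment (lowest point) and
convex-hull volume (divergence-theorem sum over hull faces).

A procedural generator (`generate_plant()`) builds labelled wheat plants
with exact ground truth — bowed tiller tubes, arched lanceolate leaf
strips, ellipsoidal ears — plus MVS artifacts (jitter, dropout holes,
missing stem bottoms, crossing tillers), so every stage is testable without
external data. Evaluation utilities implement per-class accuracy and IoU,
instance average precision (AP/AP50/AP25, RC50/RC25), and recovery
R²/RMSE.

## Worked example

```r
library(wheatrecon)

pl  <- generate_plant(plant_spec(rng_seed = 7))   # synthetic plant + truth
fit <- reconstruct_plant(pl$cloud)                # full reconstruction
fit
#> Reconstructed wheat plant
#> Wheat plant phenotype report
#>   tillers: 3 (main stem: 1)   leaves: 9   ears: 3
#>   plant height: 96.5 cm   girth: 17.1 cm
#>   tiller lengths (cm): 88.9, 57.5, 43.3
#>   leaf length (cm): mean 17.3 [8.5, 24.5]

coef(fit)
#>       n_tillers       main_stem plant_height_cm        girth_cm
#>         3.00000         1.00000        96.47081        17.08643
#>        n_leaves          n_ears
#>         9.00000         3.00000
```

Three tillers are traced, the tallest central one is picked as the main
stem, and the plant spreads its tillers over a 17.1-cm mid-height circle.
Per-leaf rows of the report give the Table-style traits:

```r
head(fit$report$leaves[, c("id", "length_cm", "width_cm", "angle_deg",
                           "attach_z", "host_tiller")], 4)
#>   id length_cm width_cm angle_deg attach_z host_tiller
#>    1      8.54     1.55     47.10    45.31           1
#>    2     24.47     1.38     25.89    64.66           1
#>    3     13.38     1.99     17.46    67.39           1
#>    4     17.84     1.22     40.81    29.21           2
```

Because the plant is synthetic, every value can be compared with its
ground truth (`evaluate_plant_recovery(fit, pl$truth)`): the first leaf's
true length is 8.60 cm (extracted 8.54), the second 24.89 cm (extracted
24.47). `summary(fit)` prints all per-organ tables, `plot(fit)` draws the
traced skeletons over the cloud, and `write_report(fit$report, "out.csv")`
exports the flat trait table. Labelled clouds are read and written as
ASCII PLY or as S3DIS-style per-instance text directories
(`read_labeled_cloud()` / `write_labeled_cloud()`), with
`voxel_downsample()` for density normalisation. A thin command-line
wrapper lives in `inst/cli/wheatrecon.R`.

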