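---
title: "Reconstructing wheat plant architecture from organ-labelled point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing wheat plant architecture from organ-labelled point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatrecon)
```

## The problem and the model

A multi-view-stereo (MVS) scan of a potted wheat plant, after semantic and
instance segmentation, is a cloud of 10^4^–10^5^ points in cm (z-up), each
carrying an organ label (leaf / tiller / ear) and, for leaves and ears, an
instance id. The reconstruction task is to recover the plant's
*architecture* from this cloud: individual tiller axes (the segmentation
provides no tiller instances, and the reconstructed stems are sparse, noisy
and bottomless), leaf midrib skeletons with a known base and tip, the
attachment point of every leaf on its host tiller, and finally a table of
18 morphological parameters.

The pipeline makes three structural assumptions about wheat:

* **tillers grow upward** — each stem axis is a single-valued function of
  height, never doubling back, so horizontal slicing and a top-down scan
  order are sound;
* **leaves are narrow and long**, so an ordered chain of segment centroids
  approximates the midrib, and the blade's principal axes separate length,
  width and thickness;
* **plant morphology constrains the leaf base** — lower leaves splay
  outward from the crown (their base is the endpoint nearer the plant
  centre), upper leaves grow near-vertically (their base is the lower
  endpoint).

### Tiller stage

Tiller points are partitioned into half-open height slabs
$[z_0 + 2(n-1),\, z_0 + 2n)$ cm anchored at the lowest tiller point. Within
each slab, DBSCAN on the xy-projection separates the stem cross-sections;
each cluster contributes its 3D centroid $SP_{nm}$ as a candidate skeleton
point (and can be replaced by a sampled cylinder of height 2 cm and radius
0.5 cm to produce a repaired cloud for visualisation). We cluster the
*projection* rather than the 3D slab points deliberately: the slab is only
2 cm thick, the task is to separate cross-sections in the horizontal plane,
and projecting keeps a stem in one cluster even when a dropout hole empties
a vertical band inside the slab (3D clustering then splits one stem into
two stacked clusters and derails the chain search).

Candidates are chained top-down. Every pair is scored
$\mathrm{score}_{ij} = \alpha h_{ij} + \beta v_{ij}$, a weighted sum of
horizontal and vertical distance; processing centroids in decreasing
height, each one extends the chain whose head offers the lowest
*admissible* score, or seeds a new chain. Admissibility encodes the
morphology: the score is capped, the link may not be closer to horizontal
than `max_slope_deg` (stems grow upward; a near-horizontal link connects
two different stems — without this cap, two tillers of similar height can
be stitched into "ladder" rungs, because a same-height link costs only
$\alpha h$ and a fresh one-point chain imposes no bend constraint), the
bend between consecutive chain segments is capped, and a link may skip at
most `max_gap_slabs` empty slabs. Ties on score break to the smaller bend,
then the lower chain id, so tracing is deterministic. Chains with fewer
than 4 points are noise and discarded; survivors are extended vertically
from their original base height down to the lowest tiller point $H_0$, and
the skipped height enters the tiller length as the correction term
$H_{S_{t,0}} - H_0$.

### Leaf stage

Each leaf is split along its axis by k-means — k = 4 below 1000 points,
k = 7 at or above (a strict reading of the threshold: exactly 1000 points
uses 7) — with a per-leaf deterministic seed so pipelines are reproducible.
Segments are ordered by projecting their centroids onto the leaf's first
principal axis. The endpoint of an edge segment is its point farthest from
the neighbouring segment's centroid, which lands on the blade's physical
extremity rather than an interior maximal chord; centroids and endpoints
are chained by repeated nearest-neighbour linking into the skeleton
polyline.

Base identification applies the two morphology rules through a zone split
at relative height `z_split` (default 0.5 — the sources only distinguish
"bottom" from "top" leaves, so the midpoint is the neutral choice). The
minD/avgD correction then repairs mistakes: with avgD the plant-wide mean
of the base-to-skeleton distances (computed in one pass before any
correction), a leaf whose minD exceeds `attach_factor` x avgD (default
1.75, an empirical multiplier kept as configuration) has its other endpoint
tested, and the endpoints swap iff that distance is smaller. The final base
snaps onto the nearest tiller skeleton point when within `snap_max_cm`
(default 3 cm) — farther leaves stay in place and are flagged rather than
deformed.

### Parameter extraction

Tiller length is the skeleton polyline sum plus the base correction. Tiller
angles use the vector between the skeleton points nearest 1/3 and 2/3 of
the *tiller's own* z-extent (tiller-relative rather than plant-relative, so
the angle stays defined for short tillers). Azimuths are measured
counterclockwise from +x in the xOy plane, in [0°, 360°); angles between
vectors are unsigned, in [0°, 180°]; the azimuth of a numerically vertical
vector is reported as `NA` rather than an arbitrary direction. Girth takes
each tiller's skeleton point nearest half the *plant* height (the
plant-height reading of "half height"; when no tiller reaches it, tiller
tops are used with a warning), forms the xy convex hull, and returns the
smallest-enclosing-circle diameter via Welzl's algorithm. The main stem is
the tiller with the best rank-sum of length (descending) and centrality
(ascending); centrality is the xy-distance of the skeleton's *mean* axis
position from the plant centre — near the crown all tillers converge and
the traced base of one chain can sit on the shared crown column, so the
base position carries no signal, while the main stem is the axis that stays
central over its whole height. Leaf width pools the two *middle* segments
(1-based indices $\lfloor k/2\rfloor$ and $\lfloor k/2\rfloor + 1$ — for
k = 4 that is segments 2 and 3, the central half of the blade) and reports
the extent along the second principal axis. Ear length is the
first-principal-axis extent, ear attachment the lowest ear point (ties to
the lowest index), and ear volume the divergence-theorem sum of signed
tetrahedra over the faces of an incremental 3D convex hull built in the
package (coplanar ears yield volume 0 with a warning).

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `slab_height_cm` | 2 | cm | stem slice height; cross-sections stay compact |
| `eps_cm` | 1.0 | cm | DBSCAN radius, 2x the repair-cylinder radius |
| `min_samples` | 5 | points | DBSCAN core threshold; kills isolated noise |
| `alpha`, `beta` | 2, 1 | — | horizontal drift is penalised more: tillers are near-vertical, and slabs already quantise vertical distance |
| `max_score` | 12 | cm-scaled | a link skipping g empty slabs carries an unavoidable vertical distance of about 2(g+1) cm, so the cap must exceed beta·6 for the permitted 2-slab gaps; the remainder (about alpha·3) is the lateral allowance. A cap of 6 would silently forbid every 2-slab gap the gap cap is meant to permit |
| `max_slope_deg` | 60 | deg | links more horizontal than this join two stems, not one |
| `max_bend_deg` | 35 | deg | permits bowed tillers, rejects sharp cross-links |
| `max_gap_slabs` | 2 | slabs | bridges dropout holes spanning up to two empty slabs |
| `min_skeleton_points` | 4 | points | chains below this are noise |
| `kmeans_threshold` | 1000 | points | leaf k switches 4 to 7 |
| `attach_factor` | 1.75 | — | minD/avgD correction trigger (empirical) |
| `z_split` | 0.5 | fraction | bottom/top zone split for base identification |
| `snap_max_cm` | 3 | cm | snap cap; avoids deforming badly segmented leaves |

## The synthetic generator

`generate_plant()` is the package's recovery oracle: it builds a plant from
analytic axis curves, samples organ surfaces, labels every point from the
generating organ, and only then applies MVS artifacts — so ground truth is
exact by construction. Tillers are tubes of radius 0.25 cm around bowed
curves (the repair cylinders at 0.5 cm comfortably cover them); leaves are
strips around arched midribs whose initial direction makes *exactly* the
drawn insertion angle with the local tiller tangent (the arch term grows as
u², so its derivative vanishes at the base and does not perturb the
ground-truth angle); blades follow a lanceolate width profile
$w(u) = W \sin(\pi u^{0.7})^{0.6}$ — widest about a third from the base,
blunt at the sheath, acute at the apex. A symmetric $\sin(\pi u)$ profile
was tried first and rejected: it makes the tip needle-like, the sampled
density vanishes over the outer few percent of the midrib, and endpoint
extraction then systematically undershoots in a way real MVS clouds of
wheat blades do not. Ears are ellipsoidal surface tufts capping flagged
tillers. Ground-truth organ lengths are dense numeric arc lengths of the
generating curves (checked in the tests against refined re-integration to
within 0.1%).

Unspecified fields are drawn deterministically from the spec's seed using
field-realistic ranges: tiller heights U(40, 90) cm with the main stem
tallest and most central, leans U(2, 15)° (main stem U(0, 4)°), azimuths
evenly spaced around the crown with ±25° jitter, leaf lengths U(8, 25) cm,
peak widths U(0.6, 2.0) cm, insertion fractions U(0.15, 0.85), insertion
angles U(15, 45)°, ear lengths U(5, 10) cm. Surface density defaults to 30
points/cm² (a plant of 10^4^–10^5^ points, comparable to downsampled MVS
output), jitter to 0.05 cm (sub-millimetre, post-downsampling MVS surface
noise), dropout to 10% (half uniform, half 0.8-cm spherical holes), and
base truncation to 2 cm of missing stem bottom.

`make_crossing_tillers()` produces the overlap regimes for tracing tests:
two tiller tubes whose axes swerve smoothly (tanh profile, peak slope about
45° at the crossing) toward and past each other. Smoothness matters: with a
kinked crossing the *straight* continuation at the crossing belongs to the
other tiller, so a continuity-based tracer would be punished for being
right. Base separations of 5–8 cm give a partial crossing whose axes pass
within 1 cm over about two slabs; separation 0 gives coincident tubes,
flagged degenerate — the documented failure mode in which tracing is
expected to merge the pair into one chain.

What the generator does **not** emulate: leaf sheaths wrapping the stem,
blade twist and serrated edges, segmentation *errors* (labels are always
correct; only geometry is corrupted), anisotropic MVS noise along viewing
directions, calibration-scale errors, and tillering/senescence over time.
Passing recovery tests therefore demonstrates the geometric pipeline is
correct and robust to sampling artifacts — not that any particular
segmentation network is accurate on real scans.

## Numerical choices

* Half-open binning everywhere (slabs, voxels), anchored at the cloud
  minimum; a point exactly on a boundary belongs to the upper bin; the top
  slab also includes the maximum.
* Voxel downsampling labels by majority vote, ties to the lowest label
  ordinal / lowest id — deterministic, and preserves class balance better
  than first-point sampling.
* All stochastic stages (generator, k-means) draw from seeds derived from
  the input, through a wrapper that restores the caller's RNG state; the
  pipeline never mutates global RNG state.
* Welzl's algorithm runs on the convex-hull vertices of the mid-height
  points with a scale-relative containment tolerance of 1e-10.
* The incremental 3D hull uses a scale-relative visibility epsilon of
  1e-9 and returns volume 0 (with a warning) for degenerate inputs rather
  than failing the report.
* Tie-breaks are explicit everywhere randomness could creep in: tracing
  (score, then bend, then chain id), ear attachment (lowest index), main
  stem (rank sum, then id).
* Degenerate inputs degrade per-field: `compile_report()` converts
  per-organ failures (a vertical azimuth, a coplanar ear, a two-point
  skeleton) into `NA` fields plus a warning, never an aborted report.

## Scope of the validation suite

The test suite validates formulas against hand-computed and closed-form
values (at 1e-12 where arithmetic is exact), geometry against exhaustive
oracles (enclosing circles against the all-pairs/triples search, the
greedy trace against full enumeration of two-chain partitions, instance AP
against exhaustive matching), and the end-to-end pipeline against the
generator's ground truth over a 50-plant population (2–4 tillers each,
default artifacts): traced tiller counts, R² (agreement form, so constant
bias is penalised) for tiller length, leaf length, leaf width and
attachment height, mean stem-leaf angle error, and base/host assignment
accuracy. `scripts/acceptance.R` recomputes exactly these quantities from
scratch at a caller-chosen seed. Problem sizes (50 plants of roughly
15,000 points, five crossing fixtures) are chosen so the whole study runs
in about half a minute on one CPU while keeping several hundred leaves in
every regression.

## Known limitations

* Missing stem bottoms below the lowest surviving tiller point are
  unrecoverable by construction; the base-extension correction restores
  height only down to $H_0$, so a globally truncated plant yields
  systematically short tiller lengths.
* Heavily overlapping tillers (axes within the clustering radius over many
  slabs) merge into one chain — the documented failure regime; the
  crossing fixture reproduces it at separation 0.
* Leaf width is an extent, so it inherits the known biases of extents:
  outlier noise inflates it, blade curl shrinks it relative to the
  unrolled width.
* The tracer assumes stems are single-valued in height; a lodged
  (horizontal) tiller violates the slope constraint and would fragment.
* Instance segmentation quality is taken as given; wrong input labels
  propagate directly into the skeletons.
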