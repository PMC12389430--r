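---
title: "Quantifying stand structure from backpack laser scanning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stand structure from backpack laser scanning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standstruct)
```

## The problem this package addresses

Mixed, multi-storied natural stands — the motivating case being ancient
tea-tree (*Camellia taliensis*) communities growing on steep subtropical
mountainsides — are hard to survey with tape and clinometer, and repeated
manual measurement disturbs exactly the rare populations one wants to
protect. Backpack laser scanning (BLS) walks a plot once and returns a
dense 3-D point cloud from which each stem's diameter at breast height
(DBH), total height (TH) and position can be recovered. From those
per-tree parameters, two complementary families of descriptors
characterise the community:

* **spatial structure** — how trees are arranged relative to their
  immediate neighbours: the uniform angle index *W* (regular vs clumped
  placement), mingling *M* (interspecific isolation), dominance *U*
  (local size standing) and the Hegyi competition index *CI*;
* **non-spatial structure** — what the community is made of: species
  richness (Patrick, Margalef), diversity (Shannon–Wiener, Simpson),
  evenness (Pielou), species importance values and the diameter-class
  distribution.

This vignette documents the models implemented, the defaults chosen, the
numerical decisions taken where the conventional definitions are silent,
and what the synthetic validation suite does and does not demonstrate.

## Point-cloud pre-processing

The cloud-to-table chain is:

1. **Plot clipping** to a quadrilateral marked by four corner points
   (`cropToPlot`); boundary points are kept.
2. **Random thinning** (`randomSample`) retaining a fixed fraction
   (default 80 %) uniformly without replacement. Survivors keep input
   order, and counts use R's round-half-even, so reruns with one seed are
   byte-reproducible.
3. **Statistical outlier removal** (`sorDenoise`): each point's mean
   distance to its *k* = 10 nearest neighbours is compared against the
   global mean plus 2 standard deviations of that statistic. The
   threshold is global, the conventional reading of the "k points /
   n sigma" rule. A relative slack of 1e-9 keeps numerically identical
   statistics from being clipped by floating-point jitter; note that on
   any *finite* homogeneous arrangement, edge points genuinely have
   larger mean-neighbour distances and may legitimately be removed.
4. **Ground classification** (`classifyGround`). Production BLS work
   typically uses a cloth-simulation filter; its parameters are rarely
   reported and the physics adds nothing on the gentle, locally planar
   terrain simulated here, so the package ships a deliberately simple
   lower-envelope classifier: the cloud is gridded (0.5 m cells), each
   cell's envelope is the minimum z over its 3 × 3 cell neighbourhood,
   and points within 0.2 m of the envelope are ground (LAS class 2).
   Every point receives a label. On sloped terrain the within-cell relief
   (cell size × slope) must stay below the tolerance — the defaults
   accommodate slopes to roughly 20 degrees.
5. **TIN elevation model** (`buildDEM`): a Delaunay triangulation of the
   ground points with linear (barycentric) interpolation inside the
   convex hull. Outside the hull, the plane of a facet incident to the
   nearest ground vertex is extended. The triangulation is an in-package
   incremental Bowyer–Watson implementation, tested against a brute-force
   empty-circumcircle oracle.
6. **Height normalization** (`normalizeHeights`): z minus interpolated
   terrain. Horizontal coordinates are untouched, so the planar tree
   pattern is preserved exactly.

## Individual-tree parameters

Trunks are detected by single-linkage density clustering of the points in
a 1–2 m height band (radius 0.3 m, minimum 15 points); every remaining
point then joins the trunk with the nearest horizontal axis
(`segmentTrees`). This is intentionally a trunk-proximity segmentation:
full shortest-path crown delineation requires manual correction in
practice and is out of scope, so crown points of interlocking trees can
be misassigned — DBH and stem position are robust to this, tree height
less so.

**DBH** (`extractDBH`) comes from the 10 cm slice between 1.25 and
1.35 m, projected to the horizontal plane and fitted with the algebraic
least-squares (Kåsa) circle fit. The closed form is exact on noiseless
cylinders and effectively unbiased at realistic slice noise (5 mm radial
standard deviation on a 20 cm radius); an iterative geometric
(orthogonal-distance) refinement is available via `method = "geometric"`
for heavy-noise slices. A slice must contain at least 10 points
(configurable) — the conventional definitions are silent on minimum
occupancy, and sparse slices produce unstable fits. Trees whose fitted
DBH falls below the 5 cm census minimum are dropped, mirroring the field
census rule.

**Height** (`extractHeight`) is the vertical extent (max z − min z) of
the tree's normalized cloud. On synthetic clouds that include the true
tip this is exact; real BLS clouds often miss the uppermost crown, which
is why field comparisons typically show positive height bias. The
generator can emulate this by truncating stem tops.

**Position** (`extractPosition`) is the horizontal centroid of the points
within 0.3 m of the lowest point (the root centre), falling back to the
fitted slice-circle centre when fewer than 3 base points exist.

## Spatial structure

A structure unit is one central tree plus its 4 nearest neighbours by
horizontal distance (`findNeighbors`), distance ties broken by ascending
tree id, coincident stems rejected as errors rather than silently
floored. A 2.5 m edge buffer (`applyEdgeBuffer`) removes edge bias:
buffer trees may serve as neighbours but never as central trees, and all
plot means are over core central trees only. Voronoi (Delaunay) adjacency
is available as an alternative neighbour definition (`voronoiUnits`) for
inspection, but all indices default to the fixed 4-neighbour unit, which
is the definition the classical five-grade scales assume.

With azimuths taken clockwise from north (the convention is fixed for
reproducibility; only angular gaps enter any result):

* **W** — sort the 4 neighbours by azimuth, form the 4 circular gaps,
  fold any gap above 180° to its explement (an angle between two
  directions), and count the fraction *strictly* below the standard
  angle 72° (= 360°/5). Folding is controlled by `foldReflex` (default
  on); results coincide whenever no gap exceeds 180°.
* **M** — fraction of neighbours of a different species.
* **U** — fraction of neighbours with strictly larger DBH; equal
  diameters count as "not larger".
* **CI** — Σ (neighbour DBH / subject DBH) / distance. Scale-free in
  DBH; halves when all distances double.

W, U and M land on the grid {0, 0.25, 0.5, 0.75, 1}; `gradeDistribution`
tabulates the five grades (interval 0.25). `classCompetition` totals the
per-tree CI within 10 cm diameter classes, optionally for one focal
species, reproducing the class-by-class competition profile analysis.

## Non-spatial structure

All logarithms are natural. With S species, N individuals and
proportions p_i: Patrick R = S; Margalef MA = (S − 1)/ln N; Shannon
H = −Σ p_i ln p_i; Simpson D = 1 − Σ p_i²; Pielou E = H/ln S (undefined
at S = 1, returned as NaN with a warning). Shannon and Simpson are
delegated to `vegan::diversity()` and cross-checked in the tests against
the direct formulas.

The importance value of a species is IV = (RA + RF + RD)/3, in percent:
RA its share of individuals, RD its share of basal area
(π(DBH/2)²; units cancel), and RF its share of occupied sampling units.
Relative frequency needs a within-plot sampling unit that the classical
definition leaves to the survey design; a single-plot presence/absence
reading would make RF degenerate (100/S for every species). The package
uses a square quadrat grid, default 5 m — 25 quadrats in a 25 m plot —
and the choice is exposed as `quadratSize` and flagged here prominently:
IVs are comparable only at a fixed quadrat scheme. Within a plot RA, RF,
RD and IV each sum to 100.

Diameter classes are half-open 10 cm bins anchored at the 5 cm census
minimum (class I = [5, 15) cm). `diameterClasses` also diagnoses the
inverse-J shape (non-increasing counts), the classical signature of
active regeneration; isolated counts in the sparse large-diameter tail
of a sample can break strict monotonicity without ecological meaning,
so the diagnosis is best read on the well-populated classes.

## Accuracy evaluation

`evaluateAccuracy` compares field values y against extracted values
ŷ with R² about the 1:1 line (1 − SSE/SST, as defined — not a refitted
regression), RMSE with divisor n (not n − 1), rRMSE and bias as
percentages of the field mean, MAE, and bias = mean(y − ŷ), so a
*positive* bias means the scanner underestimates. Pair matching is by
shared tree id, or by nearest stem position with a distance cap
(`matchStems`, greedy one-to-one in order of increasing distance) when
no tags are shared.

## The synthetic generator: what it emulates, and what it does not

`generateStand` emulates the study conditions the package was validated
under: 25 m × 25 m plots, stem counts from a few dozen to ~200, species
pools of 7–28 with a geometric abundance series (k = 0.35, one dominant
species, as in tea-tree communities), DBH from an exponential truncated
at the 5 cm census minimum (rate 0.08 per cm, giving the inverse-J class
structure), heights from H = 1.3·DBH^0.6 ± 0.5 m (a deliberately generic
broadleaf allometry — heights only need to be plausible), and three
point patterns: Poisson, lattice, and a Thomas-style parent–offspring
cluster process (parents uniform, offspring isotropic Gaussian, reflected
at the plot edges) for the aggregated patterns natural communities show.
`generateStemCloud` / `generatePlotCloud` build noisy cylindrical stems
(with optional taper, lean, ellipsoidal crown blobs and planar terrain)
whose true DBH/height/position are carried as metadata and per-point
labels.

What the generator does **not** emulate: occlusion and beam divergence
(beyond optional top truncation), understory vegetation, non-circular or
buttressed stems, terrain beyond a planar tilt, and species-dependent
allometry. Passing parameter-recovery tests therefore demonstrates the
correctness of the estimators on clean geometry and their stability
under radial noise — not field-grade accuracy, which is limited by
exactly the effects the generator omits.

## Numerical choices and test scales

* Kåsa fit by QR; collinear slices are an error, as are slices under the
  occupancy minimum.
* The Bowyer–Watson triangulation works in centred unit-scaled
  coordinates with a small relative tolerance in the in-circle test;
  fully collinear inputs and duplicated locations are errors. DEM
  queries locate their facet through the facets incident to the query's
  3 nearest ground vertices, with a full scan fallback.
* Nearest-neighbour searches are exact chunked brute force — at plot
  scale (hundreds of trees, clouds of tens of thousands of points) this
  is simpler and more predictable than a spatial index.
* Validation suites run at deliberately moderate sizes chosen to exercise
  the statistics without waste: property checks on stands of 150–800
  trees (≥ 500 core central trees where a mean is asserted to ±0.05),
  pattern comparisons over 20 replicates, DBH noise recovery over 100
  seeded slices of ~2000 points, and one full cloud-to-report run on a
  9-tree plot at 250 points/m with tilted terrain.

## Known limitations

Ground classification is envelope-based, not cloth simulation; crown
assignment is trunk-proximity, not shortest-path; LAS/LAZ binary I/O is
not included (XYZ CSV and tree-table CSV are the exchange formats); and
relative frequency — hence IV — depends on the quadrat convention
described above. Each limitation is deliberate and documented where the
corresponding function is defined.
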