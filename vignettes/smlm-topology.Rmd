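---
title: "Spatial statistics and persistent homology for SMLM point patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial statistics and persistent homology for SMLM point patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmtopo)
```

## The data and the problem

Single-molecule localization microscopy (SMLM) does not produce an image in
the conventional sense: it produces a table of coordinates. Each fluorophore
"blink" is fitted and localized to roughly 10 nm precision, so a recorded
nucleus becomes a point cloud of typically 10,000--50,000 events per
channel. `smlmtopo` analyses such point clouds for a specific radiobiology
question: how are DNA double-strand-break repair foci (marked by
γH2AX) organized at the nanoscale, and how does that organization
relate to the surrounding chromatin (heterochromatin marked by H3K9me3)?

Because raw localization data of this kind are rarely deposited, the package
carries a first-class simulation module that generates point patterns with
known ground truth. All statistical claims made by the test suite are claims
about these synthetic patterns; the section on the generator below spells
out what they do and do not show about real data.

## Pairwise-distance (Ripley-type) analysis

The first summary of a point pattern is the frequency histogram of all
pairwise distances. The package uses the ordered-pair convention throughout:
for events X and Y, both the X→Y and Y→X distances are
counted, so a full-range histogram of N points sums to exactly
N(N−1). Distances are binned half-open, `[lo, hi)`, in bins of 10 nm
by default (matching the localization precision; `bin_width_nm` is a free
parameter).

Three features of the histogram carry the structural information:

* **Linear regime.** A homogeneous (completely random) pattern gives a
  linearly rising curve at distances well below the field size, because the
  number of neighbours at distance r grows with the circumference of the
  r-shell. The slope scales with N²; `fit_linear_slope()` estimates
  it by least squares. The fit range should stay below roughly 10% of the
  field size; beyond that, boundary effects bend the curve. No edge
  correction is applied -- the curves are raw frequencies, not Ripley's K
  with boundary terms, which is a deliberate non-goal.
* **Cluster peak.** Clustered patterns add an excess of short distances.
  `peak_metrics()` measures the contiguous above-baseline run starting at
  the first bin: its support width estimates the maximum intra-cluster
  distance (the cluster diameter, 2R for discs of radius R), and its area
  the number of intra-cluster ordered pairs (proportional to the number of
  clusters times points-per-cluster squared). The run is anchored at the
  small-distance end on purpose: significant bins at large distances
  reflect distances *between* cluster centres and must not be absorbed
  into the peak. A bin is significant when its excess exceeds 3 local
  Poisson standard deviations of the baseline (`threshold_k`, tunable).
* **Cross term.** For a two-component pattern, `decompose_two_sets()`
  splits the pooled histogram into within-A, within-B and the cross term
  holding the A-to-B distances. The decomposition is an exact combinatorial
  identity, tested bin by bin.

```{r distances}
f <- field_spec(24000, 24000)              # 24 x 24 um analysis field
h2 <- distance_histogram(simulate_homogeneous(2000, f, seed = 1), 10, 2000)
h4 <- distance_histogram(simulate_homogeneous(4000, f, seed = 2), 10, 2000)
fit_linear_slope(h4, c(0, 2000)) / fit_linear_slope(h2, c(0, 2000))  # ~ 4
```

## Nano-cluster detection

Repair-focus nano-clusters are detected by density connectivity (DBSCAN
semantics): a point is a core when at least `min_points` events (itself
included) lie within `neighborhood_radius_nm`; cores within that radius of
one another are connected into one cluster, and remaining events within the
radius of a core join as border points. A border point in reach of cores of
two different clusters is assigned to the cluster of its lowest-index core
-- an arbitrary but deterministic tie rule.

Two published parameter sets are shipped as presets: the γH2AX
sets (radius 200 nm with 46 or 50 minimum points, `gammaH2AX_fig4` /
`gammaH2AX_topology`) and the nucleosome set (more than three points within
40 nm, at most 100 points and at most 200 nm extent). The two
γH2AX minima reflect two different analyses; neither is a hidden
default -- the criteria must always be stated. The maximum extent is
enforced post hoc on the hull diameter rather than folded into the
neighbourhood radius, because the two scales (40 nm connectivity, 200 nm
extent) are stated independently.

Cluster geometry follows the surveyor's (shoelace) formula on the convex
hull: polygon centroid, hull area (reported in µm²;
coordinates stay in nm), and the root-mean-square distance of the hull
vertices to the centroid as the size measure. "RMS of the distances of the
points of the convex hull" admits a second reading -- RMS over pairwise
vertex distances -- which is available via
`cluster_size_rms(method = "pairwise")`; the vertex-to-centroid reading is
the default because it reduces to the circumradius for regular shapes.
Collinear or sub-3-point clusters are flagged `degenerate` and fall back to
the member mean, zero area and member-RMS. The hull is used for the area
(rather than an eps-dilated footprint) as the minimal assumption.

Per-cell utilities: `qc_filter_cells()` keeps cells with 10,000--50,000
signals (the published selection window), `fraction_clustered()` reports
the percentage of events inside clusters, and `clusters_per_cell()`
summarises counts with median, quartiles and mean ± 2 SD.

## Persistence barcodes

Topology enters through a growing-sphere filtration: spheres of radius
α grow around every event; an edge joins two events when their
spheres touch (α = half the distance), and any triangle of edges
is filled as a face. This operational rule is exactly the Vietoris--Rips
complex at scale 2α restricted to dimension ≤ 2, and the
package implements it as such (`build_filtration()`). An alpha-complex
backend was considered and deliberately not implemented: the sphere-contact
rule with triangle fill *is* the construction the analysis defines, and for
the dimension-0/1 features used here the Rips reading is the faithful one.
α always denotes the sphere radius, not the edge length.

`persistence_barcode()` computes dimension-0 bars (connected components) by
union-find over the edge insertions and dimension-1 bars (holes) by GF(2)
boundary-matrix reduction of the triangle columns (compiled code; the
reduction is the standard left-to-right algorithm). Guarantees, all tested:
every point contributes a dimension-0 bar born at 0; a connected point set
has exactly one infinite bar; B0 is non-increasing in α;
barcodes are invariant under rigid motions and scale linearly with the
coordinates. Zero-persistence bars (birth = death exactly) are dropped by
default (`keep_zero` retains them). Exactly duplicated points are merged
with a warning before the filtration. The test suite checks the
implementation against an independent brute-force reduction of the full
dense boundary matrix on all fixtures with up to 8 points.

The complex holds choose(n, 3) triangles, so the computation is meant for
cluster-scale point sets (tens to ~150 points; about a second at 80
points). Whole-nucleus clouds are subsampled (`subsample_events()`, seeded)
or capped with `alpha_max_nm`; under a cap, features still alive at the cap
are reported with death `Inf`.

```{r barcode}
persistence_barcode(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
```

Barcodes destined for comparison are post-processed by
`round_and_prune()`: endpoints are expressed in µm, rounded to two
decimals, and bars whose rounded birth equals their rounded death are
excluded. The choice of µm as the rounding unit is an
interpretation and is flagged as such: two-decimal rounding in nm would
prune nothing at SMLM scales, while in µm it imposes a 10-nm
granularity, i.e. the localization precision. Both the unit and the number
of decimals are parameters.

For whole-nucleus chromatin, `endpoint_histogram()` summarises the bar
endpoints (death values -- the highest α of each bar; infinite
bars excluded): per nucleus and dimension the endpoint histogram is
normalized to sum 1, and the per-nucleus histograms are averaged without
weighting, so every nucleus counts equally regardless of its event count. A
nucleus with no finite bars in a dimension is skipped for that dimension
and logged. Dimension-0 endpoints measure the separation of sub-components;
dimension-1 endpoints the size of chromatin holes, which grow when
chromatin decondenses.

## Barcode similarity and heterochromatin association

Two bars are compared by the Jaccard index of their intervals --
intersection length over union length, 0 for disjoint bars, 1 for identical
ones. Two barcodes are compared by a maximum-weight one-to-one matching of
their bars on these Jaccard weights (bipartite assignment via `igraph`),
with the summed weight divided by the *larger* bar count, so surplus bars
penalize. This denominator makes the measure reduce to the stated 0/1
endpoints: identical barcodes score exactly 1, and barcodes with no
overlapping bars score 0. An alternative "mean of best matches" mode
(`method = "best_match"`) is provided since the exact matching scheme used
in prior work is not pinned down; the assignment mode is the default
because it is a proper one-to-one correspondence. The test suite checks the
assignment against an exhaustive enumeration over all permutations on small
barcodes.

Before matching, each barcode's endpoints are divided by its scale
reference (largest finite death), which makes the comparison scale-free:
a point set and any uniformly scaled copy of it compare to similarity 1.
This honours the principle that topological comparisons should not depend
on object size; `normalize = FALSE` disables it. Two barcodes that are both
empty in a dimension are defined to be identical (similarity 1, logged) so
that identical clusters always score 1. The overall similarity is the
plain mean of the dimension-0 and dimension-1 values.

`similarity_heatmap()` assembles the all-versus-all matrix with the
HC-associated clusters ordered first, giving the block structure read in
first-generation heatmaps (HC-HC upper left, nHC-nHC lower right); the
diagonal is 1 for the topology measures. The `size` measure uses the
absolute difference of cluster sizes instead (small difference = similar;
unbounded). `second_generation_heatmap()` reduces each matrix to its block
means (excluding the diagonal) and averages them per condition -- summary
statistics only, by design; no significance testing of block differences is
attempted.

Heterochromatin association itself is decided from the local chromatin
density: concentric shells are drawn around the cluster centroid (defaults:
10 shells of 50 nm) and the cluster is HC when the pooled point density
over the inner region (first 4 shells, i.e. a 200-nm disc -- the
nano-cluster radius scale) reaches the threshold, by default the
nucleus-wide mean density of the chromatin channel. The pooled
(area-weighted) inner density is used rather than an unweighted mean of
per-shell densities, because shells near the centroid contain few points
and their individual densities are noisy. Shell geometry and threshold are
interpretations -- the published analyses defer these details to earlier
work -- and all three are exposed as parameters.

## The synthetic-data generator

`simulate_homogeneous()`, `simulate_clustered()` and `simulate_mixture()`
generate the canonical test patterns: uniform fields, circular clusters
(N_Cl clusters of N_P points with radius R, centres uniform with the whole
disc inside the field) and cluster+background mixtures. Within-cluster
points are uniform over the disc -- the minimal reading of "circular
clusters with homogeneously distributed points" -- with a truncated
Gaussian profile as an option. Cluster centres are unconstrained by
default; a `min_separation_nm` rejection-sampling option exists because
recovery experiments need geometrically well-separated ground truth. The
localization precision column is a constant 10 nm by default, the
instrument-scale precision. Everything is 2D, as the analyses operate on
2D projections. Every generator takes one explicit integer seed and
restores the global RNG state afterwards.

`simulate_two_channel()` builds a two-colour nucleus fixture:
heterochromatin domains (dense discs over background) in channel B and
damage foci with known HC/nHC placement in channel A. The defaults in
`random_two_channel_spec()` emulate a HeLa nucleus 2D projection: a
10 × 10 µm field, 12 domains of 500 nm radius at 5
times the background density, 20 foci of 200 nm radius with 60 events
each, and ~30,000 channel-B events -- inside the published 10,000--50,000
per-cell QC window. Foci are kept from overlapping each other and nHC foci
keep a 500-nm clearance from domain boundaries, so the ground-truth labels
are geometrically unambiguous.

What the generator does *not* emulate: fluorophore re-blinking (one
molecule appearing as several correlated events), localization-error
jitter, non-circular domain shapes, 3D structure, and nucleus boundaries
(the field is rectangular). Passing recovery tests on these fixtures
therefore shows that the estimators are correct under their stated model,
not that real nuclei satisfy that model; in particular, re-blinking
inflates apparent clustering in real data and is explicitly out of scope.

## Numerical choices and problem sizes

* Distance binning is half-open `[lo, hi)` in double precision; the bin
  grid always covers the closed requested range.
* Brute-force O(N²) distance computation is exact and is itself the
  reference; no approximate neighbour search is used. DBSCAN neighbour
  queries go through an eps-sized grid, which changes nothing about the
  result, only the cost.
* Degenerate inputs are defined, not rejected: empty tables give empty
  cluster lists and all-zero histograms; an empty table makes
  `fraction_clustered()` an error because the fraction is undefined;
  zero-length unions in the Jaccard index give similarity 1.
* Test and example problem sizes were chosen at the scale the statistics
  need and no larger: 20-seed replications for the recovery claims, point
  clouds of 60--120 events for persistence fixtures, 24,000² nm
  fields with 2,000--4,000 points for the N² slope law.

## Known limitations

* Dimension-2 homology, persistence images/landscapes, bottleneck and
  Wasserstein distances are out of scope, as are Ripley's K/L with edge
  correction and pair-correlation estimation.
* The persistence backend is exact but cubic in points via the triangle
  count; very large clusters must be subsampled, which adds sampling noise
  to the barcode.
* Cluster counts are sensitive to the published criteria near the
  `min_points` boundary (45 points are not a cluster; 46 are). This is by
  construction, not an artefact.
* HC/nHC classification with the nucleus-wide mean threshold assumes the
  chromatin channel covers the nucleus roughly uniformly outside domains;
  a nucleus mask is not modelled.
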