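---
title: "Network-constrained point pattern analysis with netspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-constrained point pattern analysis with netspat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netspat)
```

## The problem

Urban service facilities — hospitals, clinics, pharmacies — are
*alongside-network events*: they occupy positions on or immediately next
to streets, and access to them happens along streets. Analysing their
distribution with planar tools (ordinary kernel density estimation,
Ripley's K-function in Euclidean distance) treats the whole plane as
habitable and measurably over-detects clustering, because points forced
onto a one-dimensional subnetwork of the plane always look "clustered"
in two dimensions. netspat therefore works in *network space*: every
distance is a shortest path along the road network.

The package answers three questions about a facility layer:

1. **Where is density concentrated?** — weighted network kernel density
   estimation (NetKDE), with a facility-size weight so that one
   1000-bed hospital is not equated to a 10-bed clinic.
2. **Is the pattern clustered, random or dispersed, and do two layers
   attract each other?** — network auto and cross K-functions with
   Monte Carlo envelopes under complete spatial randomness (CSR) on the
   network.
3. **Does facility density follow street structure?** — Spearman
   correlation, on a common raster, between facility density surfaces
   and street centrality (betweenness, closeness, straightness).

## Data model

A `road_network` is an undirected planar graph: nodes with projected
metric coordinates, edges with polyline geometry whose geometric length
is the edge weight. Networks must be connected (loading errors with the
component count otherwise) and coordinates must be planar metres;
longitude/latitude input is rejected rather than silently misused.
Endpoints closer than a snap tolerance (default 0.5 m) are merged at
load, which absorbs digitisation slack at junctions.

Points live *on* the network as (edge, offset) pairs. Off-network
coordinates are attached by nearest-edge snapping (`snap_points()`),
with ties broken deterministically by lowest edge id. The assumption
that a facility belongs to its nearest street segment is exactly that —
an assumption; there is no ground-truth address-to-segment matching
here.

Distances between on-network points account for both partial offsets
and may route around the network when that is shorter than travelling
along the shared edge. The base graph is never mutated: distances are
assembled from a cached node-to-node shortest-path matrix plus offset
arithmetic, which keeps repeated evaluations (lixel grids, Monte Carlo
simulation) cheap.

## Network kernel density estimation

The density at a location $s$ on the network is

$$\lambda(s) \;=\; \sum_{i=1}^{n} \frac{1}{r}\,
  \frac{1}{\sqrt{2\pi}}\; e^{-\,d(s,i)^2 / (2 r^2)}\; B_i
  \qquad (d(s,i) \le r),$$

where $d$ is the shortest-path network distance, $r$ the bandwidth,
and $B_i$ the weight of event $i$ (bed count; $B_i = 1$ in unweighted
mode). Contributions are truncated to zero beyond the bandwidth.
Evaluation happens at the centres of *lixels* — equal subdivisions of
each edge no longer than the configured cell size — and the lixel field
can be rasterized to a planar grid (length-weighted mean over the lixel
portions intersecting each cell) or smoothed with an ordinary planar
Gaussian KDE when a fully covered grid is needed for correlation.

Numerical and design choices worth knowing:

* **Self-distance is included.** The kernel nominally applies for
  $0 < d \le r$, but excluding $d = 0$ would zero the density at an
  isolated facility's own location, which is scientifically absurd for
  a density map; the limit value $B_i/(r\sqrt{2\pi})$ is used instead.
* **No junction correction.** The plain shortest-path Gaussian is used,
  not an equal-split or other unbiased network kernel. Density near
  high-degree junctions is therefore mildly inflated — a known property
  of this estimator, accepted here because the analysis compares
  categories on the same network rather than estimating absolute
  intensity.
* **No global normalization.** $\lambda$ is per metre of network and
  linear in the weights; `normalize_field()` offers min–max scaling to
  $[0,1]$ for map comparison (a constant field maps to zero).
* **Defaults**: bandwidth 600 m, lixel/cell size 20 m. Facilities are
  sparser than, say, shops, so a bandwidth in the mid-hundreds of
  metres is needed before neighbourhoods overlap; both values are
  plain arguments everywhere. No automatic bandwidth selection is
  provided.

## Network K-functions and CSR envelopes

The auto K-function of $n$ points on a network of total length
$|S|$ is

$$K(t) = \frac{1}{\rho}\,\frac{1}{n} \sum_{i=1}^{n} n(t \mid p_i),
  \qquad \rho = \frac{n-1}{|S|},$$

with $n(t\mid p_i)$ the number of *other* points within network
distance $t$ of $p_i$. $K$ is non-decreasing and saturates at $|S|$.
The cross version counts target points within $t$ of each base point
and uses $\rho_T = n_T/|S|$.

CSR on a network means: edge chosen with probability proportional to
its length, offset uniform — intensity uniform per metre. The envelope
is pointwise over `n_sim` CSR simulations: with the default
`n_sim = 99` and one-sided level $\alpha = 0.05$, the 5th and 95th
order statistics. (With an interpretation of the level as 2.5%/97.5%
being equally defensible on the original wording of such envelopes,
the one-sided 5% order statistic was chosen and `alpha` is
configurable.) Cross-mode envelopes hold the base points *fixed* and
resample only the targets: the scientific question is whether
pharmacies cluster around the hospitals that exist, not whether both
layers are jointly random.

Classification is per distance bin — observed strictly above the upper
envelope is clustered, strictly below the lower is dispersed, ties
count as random — and the summary label is the modal bin label over a
reported range. **The default summary range is $0 < t \le
\max(t)/2$**, i.e. up to a quarter of the network diameter under the
default grid ($t$ from 0 to half the diameter in 20 m steps). The
reason is visible in any strongly clustered pattern: at distances
comparable to the network size, $K$ saturates and a pattern whose
points sit in a few tight groups *genuinely* falls below the CSR band
(mid-range pairs are missing), so large-$t$ bins describe boundary
structure, not the process. Users can pass any `t_range`; per-bin
labels are always reported unmodified.

## Street centrality

Three node indices, all using metric shortest paths:

* betweenness
  $C^B_i = \frac{1}{(N-1)(N-2)} \sum_{j \ne k \ne i} n_{jk}(i)/n_{jk}$
  over ordered pairs, with all tied shortest paths counted
  fractionally (float tolerance for ties is immaterial on exact
  lattice lengths and irrelevant on jittered ones);
* closeness $C^C_i = (N-1)/\sum_j d_{ij}$, in 1/metres;
* straightness $C^S_i = \frac{1}{N-1} \sum_j d^{Eu}_{ij}/d_{ij}$,
  equal to 1 exactly when no detour exists.

Centrality is node-based, computed on the one connected network
(disconnected input is an error, not a per-component computation), and
smoothed to a raster with the same planar Gaussian KDE (node locations
weighted by index value) so that facility density and street structure
live on one grid.

## Correlation

`correlation_table()` ranks the cells of each pair of co-registered
rasters over the *intersection* of their valid-cell masks (so each
pair in a table uses the same n) and reports Spearman's r with a
t-approximation p-value on $n-2$ degrees of freedom. Whether
structurally empty cells should count as zeros rather than be dropped
is not an obviously settled question for network-derived rasters, so
`include_empty` exists but defaults to off. No multiple-testing
correction is applied to the 24-cell table, and no spatial correction
of the significance level is attempted: raster cells are strongly
spatially autocorrelated, so the p-values are optimistic and should be
read as descriptive. This is a known limitation, not an oversight.

## The synthetic-city generator

The real study layers behind analyses of this kind (municipal road
centrelines, licensed facility registries) are rarely redistributable,
so the package ships a generator with the statistical structure the
methods assume, and the whole test suite runs on it:

* grid or perturbed-grid networks (`make_grid_network()`);
* CSR sampling, length-uniform by construction;
* clustered patterns: CSR parents, children displaced by a *network
  random walk* of half-normal length (uniform branch choice at
  junctions). Displacing along the network rather than in the plane
  keeps the process intrinsically network-constrained — a planar
  displacement snapped back to the network would leak across blocks;
* regular patterns: deterministic greedy placement along the edge
  traversal, keeping a candidate only if it is at least `spacing` from
  every kept point, which guarantees the minimum-separation property
  on any topology;
* cross-clustered patterns: points displaced from uniformly chosen
  anchor facilities, emulating pharmacies locating near hospitals;
* attributes: strength classes 1–5 drawn with proportions
  33/38/152/135/374 out of 732 and ownership 376 private : 356 public
  (the bundled count table, also the default magnitudes of
  `simulate_city()` together with 569 pharmacies); bed counts uniform
  within per-class ranges chosen so that first-class hospitals can
  exceed 1000 beds while fifth-class facilities are near-zero-bed
  clinics. The ranges are package defaults for generating plausible
  weight skew, not empirical claims about any city.

What the generator does **not** emulate: real street morphology
(irregular blocks, arterials vs alleys), address-based facility
placement, spatial covariates (population, land value), or any
dependence between facility size and location beyond what a scenario
explicitly constructs. Passing tests therefore demonstrate that the
estimators are computed correctly and that the inferential machinery
recovers known generative structure — they do not validate substantive
conclusions about any real city.

## Problem sizes and reproducibility

The test suite and the acceptance script run the stochastic checks at
deliberately moderate sizes chosen as representative rather than
maximal: a 10×10 grid of 100 m blocks (18 km of network), 100 points
per pattern, 99 CSR simulations per envelope, 20 replicate seeds per
recovery rate, and a 12×12 demo city with 150 hospitals and 100
pharmacies for the end-to-end pipeline. All randomness flows through
explicit seeds; `run_full()` reruns byte-identically for a fixed
configuration, and stage outputs are identical to calling the module
functions directly (the pipeline holds no hidden state).

## Known limitations

* Undirected network, no turn restrictions or one-way streets; all
  distances are symmetric.
* No CRS handling: coordinates are taken as planar metres.
* The NetKDE junction bias discussed above.
* Monte Carlo envelopes are pointwise, not simultaneous; reading the
  curve across many bins inflates the global type-I rate (the modal
  summary mitigates but does not remove this).
* Raster-level correlation inherits spatial autocorrelation; p-values
  are descriptive.
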