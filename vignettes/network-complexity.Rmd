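---
title: "Mapping brood parasite–host network complexity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brood parasite-host network complexity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paranet)
```

## The analysis in one paragraph

Brood parasite–host records form a global bipartite network: an edge means
species *P* has been documented laying in nests of species *H* somewhere in
its range. `paranet` projects that global network onto geography. A grid of
equal-area hexagons is intersected with every species' breeding range to
get per-cell presence–absence; each cell is then assigned its *potential
network* — the sub-network of globally documented interactions between
species co-present in the cell ("potential" because a documented
interaction need not have been observed inside that particular cell).
Complexity is summarised by linkage density and a bipartite topology class,
and finally regressed on species richness with OLS and a spatial-error SAR
to ask whether complexity is just richness in disguise.

## Linkage density

For a cell network with $I$ interactions among $S$ species we report

$$L = I / S,$$

counting in $S$ only species incident to at least one retained edge, each
species once even if it somehow appeared in both roles. This is the binary
interactions-per-species ratio: a lone pair gives the global minimum
$L = 1/2$, the complete $2\times2$ network gives $4/4 = 1$, and a cell
holding 6 parasites and 80 hosts wired by 241 interactions gives
$241/86 = 2.8$ (1 dp). Note that $L = 0.5$ is attained exactly by *any*
disjoint union of one-to-one pairs ($k$ edges over $2k$ species), the
single pair being the smallest case. Cells whose species share no
documented interaction have **no** defined linkage density — they are
reported as missing, never as zero, and are excluded from the regressions.

Two deliberate choices:

* **Edge-incident denominator.** A present host with no co-present
  documented parasite is not part of the network. The alternative (count
  all present species) would dilute $L$ with ecologically silent species
  and break the worked $1/2$, $4/4$, $241/86$ anchors.
* **Binary edges.** Host-use intensity is unknown at global scale, so the
  weighted variants of linkage density used by some network packages
  (marginal-weighted mean links per species) do not apply; we implement
  the plain binary ratio and treat the weighted definition as out of
  scope.

Topology classes (one-to-one, one-to-many, many-to-one, many-to-many) are
assigned at whole-network level from the counts of parasite and host
nodes; `component_topologies()` exposes the per-component breakdown, since
e.g. two disjoint pairs classify as many-to-many at network level while
being two one-to-one systems.

## The grid

Equal area is the property that matters — every cell must represent the
same amount of habitat — so we provide it directly rather than
implementing a full icosahedral discrete global grid:

* **Planar worlds** are tiled with pointy-top regular hexagons of side
  $s = \sqrt{2A/(3\sqrt3)}$ for target area $A$, in offset rows (adjacent
  centroids exactly $s\sqrt3$ apart). Cells not sharing area with the
  requested rectangle are dropped; boundary cells may overhang it.
* **Spherical latitude bands** are tiled in the Lambert cylindrical
  equal-area projection ($x = R\lambda$, $y = R\sin\phi$, authalic radius
  $R = 6371.007$ km). Because the projection preserves area, each
  projected hexagon encloses its projected area on the sphere; shapes
  distort towards the poles but areas do not, which is the trade we want.
  The hex side is rescaled so an integer number of columns closes the
  longitude circle exactly (for ~23,323 km² cells the shift is <0.1%),
  and the row count is rounded to the band height, keeping the summed
  cell area within ~0.5% of the closed-form band area
  $2\pi R^2(\sin\phi_2-\sin\phi_1)$.
* **DGGS arithmetic** (`dggs_cell_count()`, `dggs_mean_cell_area()`)
  supplies the aperture/resolution bookkeeping of icosahedral grids:
  $10\,a^r + 2$ cells, hence $4\pi R^2/21872 \approx 23{,}320$ km² at
  aperture 3, resolution 7 — the cell size used for global mapping.
  Full ISEA3H indexing (Snyder projection, hierarchy, pentagon handling)
  is deliberately not implemented: it is expensive, and no result here
  depends on it.

Point-in-cell assignment uses nearest centroids — for a regular hexagon
lattice the tiling *is* the Voronoi diagram of its centres — with ties
broken to the lowest cell index, so assignment is unique (half-open
cells) without floating-point edge cases.

## Ranges, presence and the intersection predicate

Ranges are polygon collections keyed by a normalised species name
(lower-cased, whitespace-collapsed, optional synonym map) — the single
join key between range files and the edge list. Range parts can carry the
conventional integer attributes (presence/origin/seasonal); the
`native_breeding` policy keeps extant, native, resident-or-breeding parts,
which is how native breeding ranges are defined; files without those
fields are accepted with a warning.

A species is present in a cell when its range intersects the cell with
positive area. The data do not fix this predicate, so we default to the
most inclusive reading — consistent with networks that are already
"potential" — and expose a stricter fractional-coverage alternative
(`min_fraction`). Tangential zero-area contact counts as absent to keep
presences independent of floating-point grazing. Sphere-grid intersections
are evaluated in the equal-area projection plane, where areas equal their
spherical values; ranges crossing the antimeridian are not supported and
are a documented non-goal. Geometry predicates (Sutherland–Hodgman
clipping against the convex cells, shoelace areas, bounding-box
prefilters) are implemented in the package.

## The error-SAR

The regression model is
$$y = X\beta + u,\qquad u = \lambda W u + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2 I),$$
with $W$ the row-standardised binary matrix of cells whose centroids lie
within the neighbourhood distance (default 200 km; adjacent hexagon
centroids of ~23,323 km² cells sit ~164 km apart and second rings at
~284 km, so the band recovers the 6-neighbour lattice). Estimation
profiles the likelihood over $\lambda$: the spatial filter
$(I-\lambda W)$ is applied to $y$ and $X$, $\beta(\lambda)$ and
$\sigma^2(\lambda)$ come from least squares on the filtered data, and

$$\ell(\lambda) = -\tfrac n2\left(\log 2\pi\sigma^2(\lambda) + 1\right)
  + \sum_i \log(1-\lambda\omega_i),$$

where $\omega_i$ are the eigenvalues of $W$. Row-standardised $W$ is
asymmetric, but $W = D^{-1}B$ with symmetric binary $B$ is similar to the
symmetric $D^{-1/2}BD^{-1/2}$, so its spectrum is real and is computed on
the symmetrised form; island cells (no neighbour within the band)
contribute $\omega = 0$ and stay in the model with untransformed errors.
$\lambda$ is searched by Brent's method (tolerance $10^{-8}$) strictly
inside $(1/\omega_{\min},\, 1/\omega_{\max})$; an optimum within $10^{-6}$
of a bound triggers a convergence warning. Fixing $\lambda = 0$
reproduces the OLS fit exactly (same $\beta$, same log-likelihood with
the ML variance $\mathrm{RSS}/n$), which is both a correctness check and
the null of the reported likelihood-ratio statistic
$2(\ell_{SAR}-\ell_{OLS})$ on 1 df.

**Nagelkerke's pseudo-R²**,
$[1-e^{(2/n)(\ell_0-\ell_1)}]/[1-e^{(2/n)\ell_0}]$, uses the
intercept-only non-spatial Gaussian fit as $\ell_0$ (the dominant
convention in spatial-regression reporting). For continuous responses
with very small variance ($\sigma^2 < 1/2\pi e$) the Gaussian $\ell_0$ is
positive and the normaliser is non-positive; `nagelkerke_r2()` then
errors and the pipeline reports `NA` for that model rather than a
meaningless number. This regime actually occurs for linkage densities
confined to a narrow band, and is a known limitation of applying this
pseudo-R² to continuous likelihoods. Dense eigen-decomposition bounds the
practical problem size at a few thousand cells; sparse log-determinant
approximations are out of scope.

## The synthetic world

`world_config()` defines a seeded generator whose defaults are a small
planar study system: a 600 × 600 km rectangle tiled by 900 km² hexagons
(~450 cells), 10 brood parasites, 60 hosts, 40 background ("all birds")
species. Per species one circular 64-vertex range is placed with centroid
density increasing linearly along x (gradient strength 0.5 — a richness
gradient without degeneracy), log-normal areas (median $10^5$ km², sdlog
0.6: large enough that ranges overlap and many-to-many networks arise;
under these defaults per-cell linkage densities span at least
[0.5, 1.0]). Hosts-per-parasite counts are $\max(1, \mathrm{NegBin})$
with size 1, mean 7 — a down-scaled copy of the documented global
host-count shape, sized so draws stay feasible against 60 hosts — while
`world_config_global()` carries the globally calibrated distribution
(size 0.62, mean 20: median 11 hosts, IQR 24, a long tail into the
hundreds, matching the empirical host-count summaries) together with
83 parasites and 1585 hosts. Each new interaction reuses an
already-parasitised host with probability 0.4, which is what creates
many-to-one structure. Responses for regression testing come from
`simulate_sar_response()` with $\beta = (1, 2)$, $\lambda = 0.7$,
$\sigma = 1$ — strong positive autocorrelation, the regime the SAR is
meant for.

What the generator does **not** emulate: fragmented or non-convex ranges,
coastlines, phylogenetic signal in host choice, observation effort, or
any real taxonomy. Passing tests therefore demonstrate that the
*machinery* (gridding, intersection, network assembly, estimation) is
correct under known conditions — not that real-world parasite–host
complexity has any particular value. Reproducing the real global maps
requires the proprietary range data and the compiled interaction list,
which this package deliberately does not ship.

## Numerical conventions and degenerate inputs

* Quartiles/IQR: linear interpolation between order statistics (R type 7),
  pinned by a fixture test; percentages are rounded to whole numbers in
  reports; linkage density is reported raw and at 1 dp.
* Duplicate interaction rows collapse with a logged count; a
  parasite-equals-host row is an error naming the row.
* Empty networks: linkage density undefined (error at the metric level,
  `NA`/`empty` in tables). Empty land sets, empty range files and empty
  edge lists warn or abort at the pipeline stage boundary with the stage
  name.
* Determinism: every stochastic function takes an explicit seed and
  restores the caller's RNG state; pipeline reruns are byte-identical.
* Test problem sizes (the package's own choice of scale): lattices of
  ~400–500 cells for SAR recovery (three $\lambda$ regimes × 20 seeds),
  1000-network sweeps for the linkage-density bound, and default synthetic
  worlds of ~450 cells for end-to-end runs.

## Known limitations

* Dense-eigenvalue SAR limits n to a few thousand cells.
* The intersection predicate is a modelling choice; at coarse grids the
  any-overlap default inflates co-occurrence relative to a fractional
  threshold.
* Interaction records are treated as binary and symmetric-in-effort;
  geographic bias in where interactions were documented propagates into
  potential networks by construction.
* True DGGS cell indexing, ellipsoidal geodesy, antimeridian-crossing
  ranges and cartographic rendering are out of scope.
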