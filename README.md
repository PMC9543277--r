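# paranet

Spatial analysis of brood parasite–host network complexity.

Obligate avian brood parasites (cuckoos, cowbirds, honeyguides, viduid
finches, one duck) lay their eggs in the nests of host species. Although the
classic picture is a pairwise arms race between one parasite and one host,
the documented interaction records form a global bipartite network in which
most parasites exploit several hosts and many hosts are exploited by several
parasites. `paranet` is for ecologists who want to map where, on Earth or on
a synthetic world, these systems are simple one-to-one pairs and where they
form complex many-to-many webs — and to test whether that complexity is
explained by species richness alone.

## What it computes

Given a global parasite→host edge list and species breeding-range polygons:

1. **Equal-area hexagonal grid.** Planar worlds are tiled with regular
   hexagons of exactly the requested area; spherical latitude bands are
   tiled in the Lambert cylindrical equal-area projection, so every cell
   encloses the same area on the sphere. Discrete-global-grid arithmetic
   (`10·a^r + 2` cells at aperture *a*, resolution *r*) reproduces the
   ~23,300 km² cell size of an aperture-3, resolution-7 icosahedral grid.
2. **Presence–absence.** Each species range is intersected with the grid
   (default predicate: any positive-area overlap).
3. **Potential networks.** In each cell, the bipartite network whose edges
   are the globally documented interactions between species co-present in
   that cell. Its complexity is the **linkage density**

   *L = I / S*

   where *I* is the number of interactions and *S* the number of species
   incident to at least one of them. A single parasite–host pair gives the
   minimum *L* = 1/2 = 0.5; two parasites and two hosts with all four
   interactions give 4/4 = 1.0. Each network also gets a topology class
   (one-to-one, one-to-many, many-to-one, many-to-many).
4. **Spatial regression.** Per-cell linkage density is regressed on
   parasite, host, or total bird richness — each covariate in its own
   univariate model — by OLS and by a maximum-likelihood **spatial-error
   SAR**, *y = Xβ + u*, *u = λWu + ε*, over row-standardised distance-band
   weights (default 200 km, which recovers the 6-neighbour topology of the
   ~164 km-spaced hexagon lattice). Reports include Nagelkerke's pseudo-R²
   and the likelihood-ratio statistic against OLS (df = 1).

A seeded synthetic-world generator (`world_config()`,
`generate_study_fixture()`) emulates all required inputs — clustered
log-normal ranges with a richness gradient, a long-tailed host-count
distribution, spatially autocorrelated responses — so the entire pipeline
runs and is tested without any proprietary data.

## Worked example

```r
library(paranet)

w     <- generate_study_fixture(world_config(seed = 42))
paths <- save_world(w, "world")
cfg   <- run_config(ranges = paths[["ranges"]],
                    interactions = paths[["interactions"]],
                    grid = paths[["grid"]], out_dir = "out",
                    threshold_km = 1.4 * sqrt(3) * w$grid$side)
run   <- run_pipeline(cfg)
report_summary(run)
```

```
Potential-network complexity summary
  cells: 448 (309 with a non-empty network)
  linkage density: min 0.5 in cell r0c7 (1 parasites, 1 hosts, 1 interactions)
  linkage density: max 1.1 in cell r13c15 (7 parasites, 13 hosts, 23 interactions)
  topology classes: empty = 139, one_to_one = 83, one_to_many = 43, many_to_one = 0, many_to_many = 183
  10 parasites: median 4.5 hosts (IQR 6.2, max 13), 70% with >1 host
  31 hosts: median 1.0 parasites (IQR 1.0, max 5), 48% with >1 parasite
```

The minimum 0.5 is a lone parasite–host pair; the hotspot cell holds 7
parasites and 13 hosts wired by 23 interactions (23/20 = 1.1 interactions
per species). The regression pair for parasite richness:

```r
print(run$fits$parasite_richness$ols)
#> Ordinary least squares (ML variance)
#>       (Intercept) parasite_richness
#>            0.4548            0.0723
#> R2 = 0.629, F[1, 307] = 520.7, logLik = 262.42, n = 309

print(run$fits$parasite_richness$sar)
#> Spatial-error SAR (maximum likelihood)
#>       (Intercept) parasite_richness
#>             0.507             0.054
#> lambda = 0.8848 (bounds -1.752 .. 1.000)
#> sigma2 = 0.0032, logLik = 413.39, Nagelkerke R2 = NA
#> LR vs OLS = 301.94, df = 1, n = 309
```

Each additional co-occurring parasite species raises expected linkage
density by ~0.07 (OLS) or ~0.05 once the strong spatial autocorrelation of
the simulated response (λ ≈ 0.88) is absorbed into the error term; the LR
statistic of 302 on 1 df shows the spatial term dominates. `Nagelkerke R2`
is `NA` here because the response variance is so small that the Gaussian
null log-likelihood is positive, where that pseudo-R² is undefined (see the
methods vignette).

Artifacts land in `out/`: `complexity.csv`, heatmap-ready
`complexity.geojson`, `weights.gal`/`weights.csv`, and one
`model_<covariate>.json` per richness covariate.

A thin CLI over the same functions lives at `inst/cli/paranet.R`
(subcommands `grid`, `simulate`, `run`, `summarize`).

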