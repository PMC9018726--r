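---
title: "Methods: channel-network metrics for coastal wetlands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel-network metrics for coastal wetlands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidechan)
```

## The model and its metrics

A tidal wetland is modelled as a raster domain of square pixels (edge
`pixel_size`, default 3 m — the working resolution of commercial
multispectral imagery over wetlands) partitioned into channel and
vegetated-platform pixels inside an area of interest (AOI). Channel
networks are the centerline graphs of the channel pixels; each
connected network drains a watershed delineated by straight-line
proximity. Three watershed metrics summarise the network:

* **Hortonian drainage density** `D = ΣL/A` (m⁻¹): total centerline
  length over watershed area; the degree of channelization.
* **Mean unchanneled path length** `mUpl` (m): the mean distance from a
  platform pixel centre to the nearest channel pixel centre; how far
  water must travel over the platform.
* **Geometric efficiency** `GE = l_H / mUpl` with `l_H = 1/D`:
  dimensionless, invariant under uniform spatial rescaling, and hence a
  descriptor of branching pattern rather than overall channel
  abundance.

The identities `D·l_H = 1` and `GE = l_H/mUpl` are enforced by
construction in `compute_metrics()`; degenerate watersheds (no channel
length, or no platform pixels) record missing values rather than NaNs.

## Channel extraction

`classify_scene()` clusters the 4-band vectors of AOI pixels into `k`
classes (default 10) by unsupervised Gaussian maximum likelihood:
seeded k-means initialisation, then alternate hard assignment under
per-class full covariances and re-estimation until fewer than `tol` of
pixels change class. Numerical choices: singular covariances (exactly
constant classes arise in noiseless tests) are ridged by
`δ·I, δ = 10⁻⁶ × mean band variance`, with a warning; an emptied class
is re-seeded from the worst-fitting pixel; with a fixed `seed` the
procedure is deterministic. No radiometric calibration is applied —
classification rests on relative spectral differences only.

The reclassification of spectral classes into channel vs platform is
automated with NDWI = (G − NIR)/(G + NIR): a class is water-like when
its mean member NDWI exceeds 0 (open water is NIR-dark). A manual
class map can override the rule, mirroring operator-driven
reclassification, but the NDWI default keeps tests deterministic.
`dem_to_mask()` is the DEM route: channel where the surface lies more
than `depth` below the `window × window` moving median (defaults 15 px,
0.5 m). `clean_mask()` removes 8-connected channel specks below 5 px
and fills enclosed platform holes below 5 px; channels are 8-connected
and platform 4-connected, the standard duality avoiding topological
paradoxes.

## From mask to measured graph

`skeletonize()` applies Zhang–Suen thinning followed by a
minimal-skeleton pass that sequentially deletes non-endpoint simple
pixels (pixels whose foreground neighbours stay mutually 8-connected
without them). The parallel passes alone leave staircase "elbows" and
2×2 clumps that would read as spurious junction triangles and inflate
measured lengths by 20–40%; after the cleanup the skeleton is minimally
8-connected and component counts are preserved exactly.

`build_network()` places nodes at skeleton pixels whose reduced degree
differs from 2 — where a diagonal adjacency is ignored when the two
pixels share a rook neighbour — and traces edges through degree-2
chains. Step lengths are `pixel_size` for rook moves and `√2·pixel_size`
for diagonal moves, with no sub-pixel smoothing: lengths are
deterministic and exactly testable (an 11-pixel diagonal measures
10√2). The 8-connected geodesic overestimates true Euclidean length by
at most 8% (worst at 22.5°), and thinning erodes roughly half a channel
width at each branch tip; on synthetic wetlands the two effects nearly
cancel and total length lands within a few percent of vector truth.
Isolated cycles receive one artificial junction node.

`identify_outlets()` marks, per component, endpoints within two pixels
of the seaward raster edge (a convention fixed to "bottom" for
synthetic scenes); a component with no such endpoint gets its node
closest to that edge. `assign_strahler()` roots each component at its
outlet: leaf edges carry order 1, and below a junction the order is the
maximum upstream order, incremented when that maximum arrives from at
least two branches (the same rule handles >3-way junctions). A
component containing cycles — braided channels, or rasterization
artifacts where branches touch — is reduced to its shortest-path tree
from the outlet: each non-tree edge closes its cycle at the point
farthest from the outlet in graph distance and is dropped with a
warning. `prune_orders(net, r)` removes all edges of order ≤ r and
deliberately does **not** recompute surviving orders: successive
removal of orders 1…5 is then well defined and monotone, whereas
recomputation would promote surviving edges and make the removal steps
incomparable.

## Watersheds and distances

`delineate_watersheds()` assigns every AOI pixel to the nearest channel
pixel's network component (exact squared Euclidean distances between
pixel centres, computed by a per-column candidate scan that provably
finds all global minimisers; ties go to the smaller component id, which
a brute-force oracle reproduces). One watershed per network component
was chosen over per-outlet seeding: watersheds belong to whole networks.
The partition property — watershed areas summing exactly to the AOI
area — is asserted, not approximated.

`mUpl` uses the same exact straight-line distance transform, averaged
over platform pixels only; including zero-distance channel pixels would
deflate the metric by the channel area share. A within-platform
geodesic variant (water routed around channels) is a recognised
alternative reading but is out of scope; the straight-line choice
matches the Euclidean watershed delineation.

## Order-removal correction

Coarse imagery hides low-order creeks. Given a high-resolution
reference network, `order_removal_curve()` computes the wetland-wide
metric after removing orders ≤ r for r = 0…min(5, max order − 1),
re-rasterizing the surviving edges at 1-pixel width so that `mUpl`
responds to pruning; for `D` the r = 0 point equals the uncorrected
density exactly (length is width-free), and for `mUpl` the whole curve
is computed from the re-rasterized network so it is internally
consistent. `fit_exponential()` fits `ln(metric) ~ r` by OLS,
`model(r) = α·e^{βr}`; curves need ≥ 3 strictly positive points.

The application rule is an explicit design choice, since only the
existence of the exponential relationship is given: the effective
removed order `r* = ln(value/α)/β` is the order at which the pruned
reference would match the observation (clamped to [0, 5]); the
corrected value is `value · α / model(r*)`, the full-resolution level
the observation implies. Along the fitted curve the correction inverts
exactly to α; a β = 0 model corrects nothing, with a warning. End to
end — erase orders 1–2 from a synthetic wetland, re-extract, correct —
the recovered density lands within ~10% of full resolution on average;
the residual error is the exponential fit's intercept bias on trees
whose length ratios are only approximately geometric.

## Scaling and group statistics

`fit_power_law()` fits `ΣL = a·Areaᵇ` by OLS on natural logs (the
exponent is base-invariant; `a` is reported on the natural-log
convention) and reports `F = (SSR/1)/(SSE/(n−2))`, satisfying
`F = r²(n−2)/(1−r²)`. `compare_power_laws()` reads the "one pooled
model vs type-specific model" comparison as the standard nested F test
with group-specific intercept *and* slope (df = 2, n − 4): a joint test
was chosen because the type difference may sit in either coefficient; a
numerically zero RSS reduction is reported as F = 0 exactly.
`wilcoxon_rank_sum()` enumerates all `choose(n1+n2, n1)` rank
assignments when `n1+n2 ≤ 20` without ties (two-sided
`p = 2·min(P(W≤w), P(W≥w))`, capped at 1) and otherwise uses the
normal approximation with continuity and tie corrections; identical
samples give p = 1. Shapiro–Wilk (the standard gate before reporting
the nonparametric comparison) wraps the reference implementation; a
constant vector is an error. No multiple-testing correction is applied
across the three metrics.

## The synthetic world

`generate_network()` grows, from each outlet on the seaward (bottom)
edge, a Strahler cascade with Tokunaga-style side branching: a stream
of order budget o runs `2^(o−1)` jittered segments (Horton length ratio
R_L = 2), emits Binomial(2, `branch_prob`) one-order-lower side
tributaries at random interior steps, and ends in a junction of two
budget-(o−1) children, so the bifurcation ratio is R_B = 2 +
2·`branch_prob` and expected channel length per order decays
geometrically — the Hortonian regularity that makes order-removal
curves near-exponential, as the correction methodology presumes. (A
pure tip-bifurcation process was tried first and rejected: it puts
almost no length in the highest order, its log-curves are strongly
convex, and the exponential fit's intercept misses the full-resolution
level by 20–70%.) Growing tips die rather than cross or hug an
established channel (occupancy grid, minimum centreline separation
4 px), keeping the rasterized network a forest, as real networks
competing for drainage area essentially are. Ground-truth Strahler
orders are recomputed from the raw topology, never assumed from the
cascade budget. Defaults state the world once: 500×500 px at 3 m,
3 outlets, `branch_prob` 0.35, 60 m segments, widths `min(order, 3)`
px, vegetation spectrum (90, 80, 60, 200), channel (60, 70, 80, 30),
noise sd 5 — NDWI-separable by construction with a class gap far above
6 noise sd.

The generator emulates branching geometry, order-dependent widths,
class-separable spectra and incised DEMs. It does **not** emulate
meandering, braiding, tidal hydrodynamics, vegetation dynamics, mixed
pixels at channel edges, atmospheric effects or georeferencing error.
A green recovery test therefore establishes the correctness of the
measurement chain on clean Hortonian networks — not the accuracy of
the pipeline on real imagery, where resolution and canopy occlusion
dominate (that is exactly what the order-removal correction addresses).

## Degenerate inputs and numerical conventions

Empty masks produce empty networks (ΣL = 0) and an all-AOI watershed
with a warning; `unchanneled_distance()` on a channel-free mask is an
error. Non-positive values are rejected with offending indices in the
power-law fit and with the offending removed order in the exponential
fit. All generators are pure functions of (spec, seed) with RNG state
restored. Areas are pixel counts × pixel_size²; coordinates are planar
meters with pixel centres at half-integer offsets from the upper-left
origin; no CRS handling is attempted. Rasters travel as Esri ASCII
grids — the one standard raster format that is plain text — because the
target environment provides no GeoTIFF reader; configs are JSON for the
same reason.

## Known limitations

* Lengths are 8-connected geodesics of thinned rasters: individual
  edges can deviate a few percent from vector length, systematically
  upward for slanted channels and downward at branch tips.
* The Euclidean `mUpl` underestimates travel distance where a platform
  parcel's straight line to the nearest channel crosses another
  channel's watershed.
* The correction model extrapolates an exponential fitted on ≤ 6
  points; its intercept inherits any curvature of the true
  order-removal response (observed ~10% on synthetic Hortonian trees).
* `dem_to_mask()` is a deliberate stand-in for unpublished
  high-resolution extraction procedures; its moving-median window and
  depth threshold are tunable, not calibrated.
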