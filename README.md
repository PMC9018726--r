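# tidechan

Tidal channel networks are the circulatory system of coastal wetlands:
they carry the water, sediment and nutrients that keep salt marshes and
mangrove forests alive. How densely a wetland platform is dissected by
channels differs systematically between wetland types, and quantifying
that difference from imagery requires a reproducible chain from raw
multispectral scenes (or DEMs) to watershed-scale network statistics.

`tidechan` implements that chain as an R package:

* **Channel extraction** — unsupervised Gaussian maximum-likelihood
  classification of 4-band (R, G, B, NIR) scenes into k spectral
  classes, NDWI-based reclassification into channel vs platform
  (NDWI = (G − NIR)/(G + NIR)), local-relief thresholding for DEMs, and
  morphological mask cleaning.
* **Network measurement** — morphological thinning to centerlines, graph
  extraction with junction/endpoint/outlet roles, Strahler stream
  ordering, and channel lengths from 8-connected geodesics.
* **Watershed metrics** — Euclidean-allocation watersheds around each
  channel network, and per watershed the Hortonian drainage density
  `D = ΣL / A` (m⁻¹), the Hortonian length `l_H = 1/D` (m), the mean
  unchanneled path length `mUpl` (m; mean distance from a platform
  point to the nearest channel), and the geometric efficiency
  `GE = l_H / mUpl` (–).
* **Order-removal correction** — coarse-resolution imagery misses
  low-order creeks. Against a high-resolution reference network the
  package prunes orders 1…r, fits `metric(r) = α·exp(β·r)`, and
  corrects a satellite-derived value by inverting the fit
  (`apply_correction`), recovering the full-resolution level.
* **Scaling statistics** — power-law fits `ΣL = a·Areaᵇ` by OLS on
  natural logs, nested-model F tests between wetland types, exact
  two-sample Wilcoxon rank-sum tests and Shapiro–Wilk gating.
* **Flume analysis** — hydrodynamic scaling parameter `U·T/L`, sediment
  mobility `BSS/BSS_crit`, sedimentation–erosion maps, transect channel
  counts and experimental D/mUpl for tilting-flume experiments.
* **Synthetic wetlands** — a generator of Hortonian channel networks
  (Strahler cascades with Tokunaga-style side branching) with exact
  vector ground truth, plus matching scenes, DEMs and scaling datasets,
  so every stage above is testable without any data download.

Rasters are exchanged as plain-text Esri ASCII grids (`.asc`; four-band
scenes as `_R/_G/_B/_NIR` siblings), networks as GeoJSON, tables as CSV.

## Worked example

Generate a ground-truthed synthetic wetland (300×300 px at 3 m), run
the full spectral pipeline, and measure it:

```r
library(tidechan)
spec <- synthetic_spec(domain_shape = c(300, 300), n_outlets = 2, seed = 7)
gen     <- generate_network(spec)          # ground-truthed wetland
scene   <- generate_scene(gen$mask, spec)  # 4-band scene with noise
classes <- classify_scene(scene, k = 10, seed = 1)
mask    <- clean_mask(to_channel_mask(classes, scene))
net     <- build_network(skeletonize(mask))
net     <- assign_strahler(identify_outlets(net, mask, "bottom"))
ws      <- delineate_watersheds(mask, net)
dist    <- unchanneled_distance(mask)
rec     <- compute_metrics(ws, net, dist, mask, "demo", "saltmarsh")
```

which prints (`print(rec, digits = 3)` and friends):

```
  watershed_id area_m2 total_length_m drainage_density_per_m mupl_m geometric_efficiency
1            1  607644           3286                0.00541   82.0                 2.25
2            2  202356           1111                0.00549   68.7                 2.65
wetland-wide D: 0.00543 1/m (truth 0.00523)
<channel_network 38 nodes, 36 edges, 2 components, sum(L) = 4396.7 m>
```

Each of the two networks drains its own Euclidean watershed; the
drainage density recovered through classification, thinning and graph
measurement is within 4% of the generator's vector ground truth, and a
platform parcel lies on average ~75 m from the nearest channel. The
order-removal curve of the reference network fits an exponential
cleanly, and a scaling dataset generated on the Venetian salt-marsh
reference line `ΣL = 0.020·Area^1` is recovered by the log-log fit:

```
<correction_model D/saltmarsh: 0.0069547 * exp(-1.0756 * r), r^2 = 0.9551>
<power_law_fit sum(L) = 0.02195 * Area^0.9918, n = 128, F = 9479 on 1 and 126 DF, r^2 = 0.9869>
```

## Command line

```sh
tidechan synth network --seed 5 --out syn        # wetland + ground truth
tidechan extract syn_mask.asc --seaward bottom --out net.geojson
tidechan metrics syn_mask.asc net.geojson --location demo --type saltmarsh --out m.csv
tidechan scaling m.csv --group wetland_type --out scaling.json
tidechan flume diff t0.asc t1.asc --out sedero.asc
```

(`tidechan` is installed under `exec/tidechan` in the package library;
equivalently call `tidechan_main(c("synth", "network", ...))` from R.)
Global flags: `--config cfg.json`, `--seed N`, `--log-level info`.

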