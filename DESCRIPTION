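Package: tidechan
Title: Tidal Channel Network Extraction and Watershed Metrics for Coastal Wetlands
Version: 1.0.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts tidal channel networks from multispectral scenes or
    digital elevation models of coastal wetlands (salt marshes and
    mangroves), computes watershed-scale network metrics (Hortonian
    drainage density, mean unchanneled path length, geometric
    efficiency), applies an order-removal correction linking
    satellite-derived metrics to high-resolution reference networks,
    fits channel-length versus area power laws with nonparametric group
    comparisons, and analyses flume-experiment surfaces
    (sedimentation-erosion maps, transect channel counts, hydrodynamic
    scaling checks). Ships a synthetic-wetland generator with exact
    vector ground truth so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
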