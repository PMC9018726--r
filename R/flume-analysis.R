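#' Hydrodynamic scaling parameter U*T/L
#'
#' The tidal flow velocity and period scaled by a characteristic
#' length; keeping it equal between a tilting-flume experiment and
#' nature preserves hydrodynamic similarity.
#'
#' @param U flow velocity (m/s, > 0).
#' @param T_period tidal period (s, > 0).
#' @param L characteristic length, e.g. the Hortonian length (m, > 0).
#' @return dimensionless U * T / L.
#' @export
scaling_parameter <- function(U, T_period, L) {
  if (any(c(U, T_period, L) <= 0)) stop("all inputs must be positive")
  U * T_period / L
}

#' Sediment mobility parameter
#'
#' Ratio of bed shear stress to critical shear stress for sediment
#' motion; > 1 means the bed is mobile.
#'
#' @param bss bed shear stress (N/m^2).
#' @param bss_crit critical shear stress (N/m^2, > 0).
#' @return dimensionless bss / bss_crit.
#' @export
mobility <- function(bss, bss_crit) {
  if (any(bss_crit <= 0)) stop("bss_crit must be positive")
  bss / bss_crit
}

#' Sedimentation-erosion map
#'
#' Signed elevation difference end minus start: positive = deposition,
#' negative = erosion; nodata propagates.
#'
#' @param dem_start,dem_end [raster_grid()]s on the same grid.
#' @return [raster_grid()] of elevation change (m).
#' @export
sed_erosion_map <- function(dem_start, dem_end) {
  if (!same_grid(dem_start, dem_end)) stop("DEMs must share the grid")
  g <- dem_start
  g$values <- dem_end$values - dem_start$values
  g
}

#' Count channels along flume transects
#'
#' At every sampled cross-section perpendicular to the flume's long
#' axis, a channel is one maximal run of at least 2 contiguous pixels
#' eroded below `-threshold`. Counts are monotone non-increasing in the
#' threshold. The long axis runs along raster columns by default.
#'
#' @param map sedimentation-erosion [raster_grid()] (m, signed).
#' @param threshold erosion depth defining a channel (m, > 0; default
#'   0.002 = 2 mm).
#' @param axis "long" (transects = columns, positions along columns) or
#'   "cross" (transects = rows).
#' @param spacing sample every `spacing` transects (pixels).
#' @return data.frame: `position` (m along the axis, pixel centres) and
#'   `n_channels`.
#' @export
count_channels_transects <- function(map, threshold = 0.002,
                                     axis = c("long", "cross"),
                                     spacing = 1L) {
  stopifnot(threshold > 0, spacing >= 1)
  axis <- match.arg(axis)
  v <- map$values
  eroded <- !is.na(v) & v <= -threshold
  count_runs <- function(line) {
    rl <- rle(line)
    sum(rl$values & rl$lengths >= 2)
  }
  if (axis == "long") {
    pos_idx <- seq(1L, ncol(v), by = spacing)
    counts <- vapply(pos_idx, function(j) count_runs(eroded[, j]), numeric(1))
  } else {
    pos_idx <- seq(1L, nrow(v), by = spacing)
    counts <- vapply(pos_idx, function(i) count_runs(eroded[i, ]), numeric(1))
  }
  data.frame(position = (pos_idx - 0.5) * map$pixel_size,
             n_channels = counts)
}

#' Experimental drainage density and unchanneled path length
#'
#' Thresholds a sedimentation-erosion map into a channel mask (eroded
#' below `-threshold` = channel, the whole vegetated area as AOI and a
#' single whole-domain watershed) and delegates to the watershed
#' metric machinery.
#'
#' @param map sedimentation-erosion [raster_grid()], or a ready
#'   [channel_mask()].
#' @param threshold erosion depth defining channels (m); ignored when a
#'   mask is passed.
#' @param aoi optional 0/1 AOI raster (vegetated area).
#' @return list: D (1/m), mupl (m, NA when no channels), mask, records
#'   (the underlying per-watershed metric rows).
#' @export
experiment_metrics <- function(map, threshold = 0.002, aoi = NULL) {
  mask <- if (inherits(map, "channel_mask")) map else {
    v <- map$values
    ch <- matrix(as.numeric(!is.na(v) & v <= -threshold), nrow(v))
    g <- map; g$values <- ch
    channel_mask(g, aoi)
  }
  aoi_area <- sum(mask$wetland$values != 0) * mask$pixel_size^2
  if (!any(mask$grid$values != 0)) {
    return(list(D = 0, mupl = NA_real_, mask = mask, records = NULL))
  }
  sk <- skeletonize(mask)
  net <- build_network(sk)
  net <- identify_outlets(net, mask, "bottom")
  net <- assign_strahler(net)
  D <- total_length(net) / aoi_area
  d <- unchanneled_distance(mask)
  plat <- mask$wetland$values != 0 & mask$grid$values == 0
  mupl <- if (any(plat)) mean(d$values[plat], na.rm = TRUE) else NA_real_
  ws <- delineate_watersheds(mask, net)
  records <- compute_metrics(ws, net, d, mask, location = "flume")
  list(D = D, mupl = mupl, mask = mask, records = records)
}
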