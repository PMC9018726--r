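#' Delineate watersheds by Euclidean allocation
#'
#' Every in-AOI pixel is assigned the component id of the nearest
#' channel pixel (centre-to-centre Euclidean distance, exact); channel
#' pixels carry their own component's id; distance ties go to the
#' smaller component id. One watershed per channel network component,
#' mirroring delineation around whole networks rather than single
#' outlets.
#'
#' @param mask [channel_mask()].
#' @param network `channel_network` built from the mask (provides the
#'   component labelling; channel pixels are labelled by 8-connected
#'   components of the mask, which match the network's components).
#' @return object of class `watershed_map` with fields `labels`
#'   ([raster_grid()] of ids, 0 outside AOI) and `areas` (named m^2).
#' @export
delineate_watersheds <- function(mask, network = NULL) {
  v <- mask$grid$values
  aoi <- mask$wetland$values != 0
  ch <- matrix(as.integer(v != 0), nrow(v))
  if (!any(ch == 1)) {
    warning("no channel pixels: a single watershed covers the AOI (id 0)")
    lab <- matrix(0, nrow(v), ncol(v))
    lab[aoi] <- 0
    g <- mask$grid; g$values <- lab
    area <- sum(aoi) * mask$pixel_size^2
    return(structure(list(labels = g, areas = c(`0` = area),
                          pixel_size = mask$pixel_size),
                     class = "watershed_map"))
  }
  comp <- cpp_label_components(ch, 8L)
  res <- cpp_edt_alloc(comp)
  lab <- res$label
  lab[!aoi] <- 0L
  g <- mask$grid; g$values <- matrix(as.numeric(lab), nrow(v))
  ids <- sort(unique(lab[aoi]))
  areas <- vapply(ids, function(i) sum(lab == i & aoi), numeric(1)) *
    mask$pixel_size^2
  names(areas) <- ids
  structure(list(labels = g, areas = areas, pixel_size = mask$pixel_size),
            class = "watershed_map")
}

#' @export
print.watershed_map <- function(x, ...) {
  cat(sprintf("<watershed_map %d watersheds, total area %.0f m^2>\n",
              length(x$areas), sum(x$areas)))
  invisible(x)
}

#' Unchanneled path length surface
#'
#' Exact Euclidean distance (meters, centre to centre) from every
#' platform pixel to the nearest channel pixel; channel pixels are 0 and
#' pixels outside the AOI are NA.
#'
#' @param mask [channel_mask()] with at least one channel pixel.
#' @return [raster_grid()] of distances in meters.
#' @export
unchanneled_distance <- function(mask) {
  v <- mask$grid$values
  if (!any(v != 0)) stop("no channel pixels: unchanneled distance undefined")
  ch <- matrix(as.integer(v != 0), nrow(v))
  res <- cpp_edt_alloc(ch)
  d <- sqrt(res$dist2) * mask$pixel_size
  d[mask$wetland$values == 0] <- NA
  g <- mask$grid; g$values <- d
  g
}

#' Per-watershed network metrics
#'
#' For each watershed: area A (m^2), total channel length sum(L) (m),
#' Hortonian drainage density D = sum(L)/A (1/m), Hortonian length
#' l_H = 1/D (m), mean unchanneled path length mUpl (m, averaged over
#' platform pixels only — channel pixels would deflate it), and
#' geometric efficiency GE = l_H / mUpl. Degenerate watersheds (no
#' channel length, no platform pixels) yield NA for the affected
#' metrics.
#'
#' @param watersheds `watershed_map` from [delineate_watersheds()].
#' @param network `channel_network` with component ids matching the
#'   watershed labels.
#' @param distances [raster_grid()] from [unchanneled_distance()].
#' @param mask the [channel_mask()] (to exclude channel pixels from mUpl).
#' @param location system name to record.
#' @param wetland_type "saltmarsh" or "mangrove".
#' @return data.frame of metric records, one row per watershed.
#' @export
compute_metrics <- function(watersheds, network, distances, mask,
                            location = "synthetic",
                            wetland_type = c("saltmarsh", "mangrove")) {
  wetland_type <- match.arg(wetland_type)
  lab <- watersheds$labels$values
  aoi <- mask$wetland$values != 0
  chan <- mask$grid$values != 0
  ids <- as.numeric(names(watersheds$areas))
  sumL <- tapply(network$edges$length_m, network$edges$component_id, sum)
  rows <- lapply(ids, function(i) {
    A <- watersheds$areas[[as.character(i)]]
    L <- if (as.character(i) %in% names(sumL)) sumL[[as.character(i)]] else 0
    D <- if (A > 0) L / A else NA_real_
    lH <- if (!is.na(D) && D > 0) 1 / D else NA_real_
    plat <- lab == i & aoi & !chan
    mupl <- if (any(plat)) mean(distances$values[plat], na.rm = TRUE)
            else NA_real_
    ge <- if (!is.na(lH) && !is.na(mupl) && mupl > 0) lH / mupl else NA_real_
    data.frame(watershed_id = i, location = location,
               wetland_type = wetland_type, area_m2 = A,
               total_length_m = L, drainage_density_per_m = D,
               mupl_m = mupl, hortonian_length_m = lH,
               geometric_efficiency = ge, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wetland-wide drainage density
#'
#' Total channel length over the whole AOI area,
#' DD_wetland = sum(L) / A_wetland; equals the area-weighted mean of the
#' per-watershed densities.
#'
#' @param x either a metric record data.frame or a `channel_network`.
#' @param aoi_area total wetland area in m^2 (required for a network;
#'   for records it defaults to the summed watershed areas).
#' @return drainage density in 1/m.
#' @export
wetland_drainage_density <- function(x, aoi_area = NULL) {
  if (inherits(x, "channel_network")) {
    if (is.null(aoi_area) || aoi_area <= 0)
      stop("aoi_area must be a positive area in m^2")
    return(total_length(x) / aoi_area)
  }
  if (is.null(aoi_area)) aoi_area <- sum(x$area_m2)
  if (aoi_area <= 0) stop("aoi_area must be a positive area in m^2")
  sum(x$total_length_m) / aoi_area
}

#' Per-location summaries and per-type comparison vectors
#'
#' Averages each metric over the watersheds of a location (mean and
#' standard error of the mean), then groups the location means per
#' wetland type: the location means are the units entering the
#' between-type tests, giving every system equal weight.
#'
#' @param records metric data.frame over one or more locations.
#' @return list with `per_location` (data.frame of means/SEs) and
#'   `per_type` (named list: wetland type -> data.frame of location
#'   means for D, mUpl, GE).
#' @export
summarize_locations <- function(records) {
  stopifnot(nrow(records) >= 1)
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  per_location <- do.call(rbind, lapply(
    split(records, records$location), function(df) data.frame(
      location = df$location[1], wetland_type = df$wetland_type[1],
      n_watersheds = nrow(df),
      D_mean = mn(df$drainage_density_per_m), D_se = se(df$drainage_density_per_m),
      mupl_mean = mn(df$mupl_m), mupl_se = se(df$mupl_m),
      ge_mean = mn(df$geometric_efficiency), ge_se = se(df$geometric_efficiency),
      stringsAsFactors = FALSE)))
  rownames(per_location) <- NULL
  per_type <- lapply(split(per_location, per_location$wetland_type),
                     function(df) df[, c("location", "D_mean", "mupl_mean",
                                         "ge_mean")])
  list(per_location = per_location, per_type = per_type)
}
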