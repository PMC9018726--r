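#' @section File formats:
#' Rasters are exchanged as Esri ASCII grids (`.asc`), a plain-text
#' single-band raster format carrying cell size, lower-left corner and a
#' nodata sentinel. Four-band scenes live as four sibling files with
#' `_R`, `_G`, `_B`, `_NIR` suffixes. Networks are GeoJSON
#' FeatureCollections of LineStrings, metric tables CSV, configs JSON.
#' @name scene_io
NULL

BAND_SUFFIXES <- c(R = "_R", G = "_G", B = "_B", NIR = "_NIR")

#' Read a raster or a 4-band scene
#'
#' A path ending in `.asc` that exists as a file is read as a
#' single-band [raster_grid()]. Otherwise the path is treated as a scene
#' stem and `<stem>_R.asc`, `<stem>_G.asc`, `<stem>_B.asc`,
#' `<stem>_NIR.asc` are read into a [scene()].
#'
#' @param path file path or scene stem.
#' @return `raster_grid` or `scene`.
#' @export
read_raster <- function(path) {
  if (file.exists(path)) return(read_ascii_grid(path))
  stem <- sub("\\.asc$", "", path)
  files <- paste0(stem, BAND_SUFFIXES, ".asc")
  present <- file.exists(files)
  if (all(present)) {
    bands <- lapply(files, read_ascii_grid)
    names(bands) <- names(BAND_SUFFIXES)
    return(scene(bands))
  }
  if (any(present))
    stop("unsupported band count: found ", sum(present),
         " of 4 band files for stem '", stem, "'")
  stop("file not found: ", path)
}

#' Write a raster or scene
#'
#' @param x `raster_grid` or `scene`.
#' @param path `.asc` file path (raster) or scene stem (scene).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  if (inherits(x, "raster_grid")) return(write_ascii_grid(x, path))
  if (inherits(x, "scene")) {
    stem <- sub("\\.asc$", "", path)
    for (b in names(BAND_SUFFIXES))
      write_ascii_grid(x$bands[[b]], paste0(stem, BAND_SUFFIXES[[b]], ".asc"))
    return(invisible(path))
  }
  stop("cannot write object of class ", paste(class(x), collapse = "/"))
}

#' Read an Esri ASCII grid
#'
#' @param path `.asc` file.
#' @return [raster_grid()]; nodata cells become NA.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("not an Esri ASCII grid (missing header keys): ", path)
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy)
    stop("non-square pixels are not supported (dx != dy in ", path, ")")
  cellsize <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  if (is.null(cellsize)) stop("no cellsize in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); ncl <- as.integer(hdr$ncols)
  if (length(vals) != nr * ncl)
    stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = ncl, byrow = TRUE)
  m[m == nodata] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * cellsize)
  raster_grid(m, cellsize, origin, nodata)
}

#' Write an Esri ASCII grid
#'
#' @param grid [raster_grid()].
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  nr <- nrow(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nr),
    paste("xllcorner", format(grid$origin[1], digits = 15)),
    paste("yllcorner", format(grid$origin[2] - nr * grid$pixel_size,
                              digits = 15)),
    paste("cellsize", format(grid$pixel_size, digits = 15)),
    paste("NODATA_value", format(grid$nodata, digits = 15))), con)
  writeLines(apply(v, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

#' Write a channel network as GeoJSON
#'
#' One LineString feature per edge with properties `length_m`,
#' `strahler_order` and `component_id`; coordinates are world meters.
#' An empty network yields an empty FeatureCollection.
#'
#' @param network `channel_network` with assigned Strahler orders.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "channel_network"))
  ne <- nrow(network$edges)
  if (ne > 0 && anyNA(network$edges$strahler_order))
    stop("orders not assigned: run assign_strahler() before writing")
  feats <- vector("list", ne)
  if (ne > 0) {
    for (i in seq_len(ne)) {
      feats[[i]] <- list(
        type = "Feature",
        properties = list(
          length_m = network$edges$length_m[i],
          strahler_order = network$edges$strahler_order[i],
          component_id = network$edges$component_id[i]),
        geometry = list(type = "LineString",
                        coordinates = unname(network$polylines[[i]])))
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON channel network written by [write_network()]
#'
#' @param path `.geojson` file.
#' @param pixel_size pixel size to record on the network (m).
#' @return `channel_network`.
#' @export
read_network <- function(path, pixel_size = 1) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- fc$features
  ne <- length(feats)
  polylines <- vector("list", ne)
  len <- ord <- comp <- numeric(ne)
  for (i in seq_len(ne)) {
    co <- feats[[i]]$geometry$coordinates
    polylines[[i]] <- do.call(rbind, lapply(co, function(p)
      c(p[[1]], p[[2]])))
    pr <- feats[[i]]$properties
    len[i] <- pr$length_m
    ord[i] <- pr$strahler_order
    comp[i] <- pr$component_id
  }
  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      role = character(0), stringsAsFactors = FALSE)
  edges <- data.frame(id = seq_len(ne), node_a = NA_integer_,
                      node_b = NA_integer_, length_m = len,
                      strahler_order = as.integer(ord),
                      component_id = as.integer(comp))
  new_channel_network(nodes, edges, polylines, pixel_size)
}

METRIC_COLUMNS <- c("watershed_id", "location", "wetland_type", "area_m2",
                    "total_length_m", "drainage_density_per_m", "mupl_m",
                    "hortonian_length_m", "geometric_efficiency")

#' Write per-watershed metric records to CSV
#'
#' @param records data.frame of metric records (see [compute_metrics()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(setNames(
      replicate(length(METRIC_COLUMNS), numeric(0), simplify = FALSE),
      METRIC_COLUMNS))
  }
  out <- records[, METRIC_COLUMNS]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 12))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metric CSV written by [write_metrics()]
#'
#' @param path CSV file.
#' @return data.frame with the standard metric columns.
#' @export
read_metrics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(METRIC_COLUMNS, names(df))
  if (length(missing)) stop("metric file misses columns: ",
                            paste(missing, collapse = ", "))
  df
}

#' Read a JSON configuration file
#'
#' Configs are JSON objects with one top-level namespace per module
#' (e.g. `{"classify": {"k": 10}}`); any CLI flag can be preset there.
#'
#' @param path JSON file, or NULL for an empty config.
#' @return nested named list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop("config not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @keywords internal
tc_log <- function(level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  threshold <- getOption("tidechan.log_level", "info")
  if (levels[[level]] >= levels[[threshold]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  invisible(NULL)
}
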