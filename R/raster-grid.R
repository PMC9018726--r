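#' Raster grid
#'
#' Minimal in-memory raster: a numeric matrix plus square pixel size,
#' nodata sentinel and the world coordinates of the upper-left pixel
#' corner. Rows run north to south, columns west to east; the centre of
#' pixel (row, col) (1-based) sits at
#' (x0 + (col - 0.5) * pixel_size, y0 - (row - 0.5) * pixel_size).
#' Areas are pixel counts times pixel_size^2. Nodata cells are held as
#' NA in memory; the sentinel only appears on disk.
#'
#' @param values numeric matrix (row-major grid of cell values).
#' @param pixel_size edge length of a (square) pixel in meters; > 0.
#' @param origin numeric length-2, world (x0, y0) of the upper-left
#'   pixel corner in meters.
#' @param nodata sentinel written to file for NA cells.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, pixel_size, origin = c(0, 0), nodata = -9999) {
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L)
    stop("values must be a non-empty matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  storage.mode(values) <- "double"
  structure(
    list(values = values, pixel_size = as.numeric(pixel_size),
         origin = as.numeric(origin[1:2]), nodata = as.numeric(nodata)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid %d x %d, pixel %g m, origin (%g, %g), %d NA>\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Pixel-centre world coordinates
#'
#' @param grid a `raster_grid`.
#' @param row,col 1-based pixel indices (vectors recycled together).
#' @return two-column matrix of (x, y) in meters.
#' @export
pixel_to_world <- function(grid, row, col) {
  cbind(x = grid$origin[1] + (col - 0.5) * grid$pixel_size,
        y = grid$origin[2] - (row - 0.5) * grid$pixel_size)
}

#' Inverse of [pixel_to_world()] for in-bounds points
#'
#' @param grid a `raster_grid`.
#' @param x,y world coordinates in meters.
#' @return two-column matrix of 1-based (row, col).
#' @export
world_to_pixel <- function(grid, x, y) {
  cbind(row = round((grid$origin[2] - y) / grid$pixel_size + 0.5),
        col = round((x - grid$origin[1]) / grid$pixel_size + 0.5))
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size))
}

#' Four-band multispectral scene
#'
#' Bundles R, G, B, NIR rasters sharing shape, pixel size and origin.
#'
#' @param bands named list of four `raster_grid`s, keys R, G, B, NIR.
#' @return object of class `scene`.
#' @export
scene <- function(bands) {
  need <- c("R", "G", "B", "NIR")
  if (!is.list(bands) || !setequal(names(bands), need))
    stop("scene needs exactly the bands R, G, B, NIR")
  bands <- bands[need]
  ref <- bands[[1]]
  for (b in bands[-1]) {
    if (!same_grid(ref, b)) stop("all bands must share shape and pixel_size")
  }
  structure(list(bands = bands, pixel_size = ref$pixel_size,
                 origin = ref$origin), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$bands$R$values)
  cat(sprintf("<scene 4 bands (R,G,B,NIR) %d x %d, pixel %g m>\n",
              d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Binary channel mask with wetland AOI
#'
#' `grid` holds 1 for channel pixels, 0 elsewhere; `wetland` holds 1
#' inside the area of interest. Channel pixels are clipped to the AOI.
#'
#' @param grid `raster_grid` of 0/1 channel labels.
#' @param wetland `raster_grid` of 0/1 AOI labels (defaults to all-1).
#' @return object of class `channel_mask`.
#' @export
channel_mask <- function(grid, wetland = NULL) {
  if (is.null(wetland)) {
    wetland <- raster_grid(matrix(1, nrow(grid$values), ncol(grid$values)),
                           grid$pixel_size, grid$origin, grid$nodata)
  }
  if (!same_grid(grid, wetland))
    stop("mask and wetland must share shape and pixel_size")
  v <- ifelse(is.na(grid$values), 0, grid$values)
  w <- ifelse(is.na(wetland$values), 0, wetland$values)
  v <- as.numeric(v != 0) * as.numeric(w != 0)   # channel subset of AOI
  g <- grid; g$values <- matrix(v, nrow(grid$values))
  wet <- wetland; wet$values <- matrix(as.numeric(w != 0), nrow(w))
  structure(list(grid = g, wetland = wet, pixel_size = grid$pixel_size),
            class = "channel_mask")
}

#' @export
print.channel_mask <- function(x, ...) {
  cat(sprintf("<channel_mask %d x %d, %d channel px / %d AOI px, pixel %g m>\n",
              nrow(x$grid$values), ncol(x$grid$values),
              sum(x$grid$values != 0), sum(x$wetland$values != 0),
              x$pixel_size))
  invisible(x)
}
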