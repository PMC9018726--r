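#' Unsupervised Gaussian maximum-likelihood classification
#'
#' Clusters the 4-band vectors of in-AOI pixels into `k` spectral
#' classes: seeded k-means initialization, then alternating (i)
#' assignment of each pixel to the class maximizing the Gaussian
#' log-likelihood under a per-class full covariance and (ii)
#' re-estimation of class means and covariances, until fewer than a
#' `tol` fraction of pixels change label or `max_iter` is reached.
#' Singular covariances are ridge-regularized (delta * I with delta
#' proportional to the mean band variance) with a warning; a class that
#' empties is re-seeded from the pixel with the lowest maximum
#' log-likelihood.
#'
#' @param scene [scene()].
#' @param wetland 0/1 AOI [raster_grid()] (NULL = whole scene).
#' @param k number of classes (default 10).
#' @param max_iter iteration cap.
#' @param tol stop when the fraction of pixels changing label drops
#'   below this.
#' @param seed RNG seed for the k-means initialization.
#' @return object of class `class_raster`: `grid` (labels 0..k-1, NA
#'   outside the AOI), `k`, and `class_stats` (per-class mean,
#'   covariance, size).
#' @export
classify_scene <- function(scene, wetland = NULL, k = 10, max_iter = 50,
                           tol = 1e-4, seed = 1L) {
  stopifnot(k >= 2)
  ref <- scene$bands$R
  nr <- nrow(ref$values); ncl <- ncol(ref$values)
  if (is.null(wetland))
    wetland <- raster_grid(matrix(1, nr, ncl), ref$pixel_size, ref$origin)
  inw <- which(wetland$values != 0 & !is.na(wetland$values) &
               !is.na(ref$values))
  if (length(inw) < k) stop("AOI has fewer pixels than classes")
  X <- cbind(scene$bands$R$values[inw], scene$bands$G$values[inw],
             scene$bands$B$values[inw], scene$bands$NIR$values[inw])
  ridge_warned <- FALSE
  delta <- 1e-6 * mean(apply(X, 2, var))
  if (!is.finite(delta) || delta <= 0) delta <- 1e-8
  lab <- with_seed(seed, {
    # jitter breaks exact duplicates that make kmeans degenerate
    km <- suppressWarnings(kmeans(
      X + matrix(rnorm(length(X), 0, 1e-9 * (1 + mean(abs(X)))), nrow(X)),
      centers = k, nstart = 3, iter.max = 50))
    km$cluster
  })
  n <- nrow(X)
  loglik_matrix <- function(stats) {
    ll <- matrix(-Inf, n, k)
    for (j in seq_len(k)) {
      st <- stats[[j]]
      if (is.null(st)) next
      ll[, j] <- -0.5 * st$logdet -
        0.5 * mahalanobis(X, st$mean, st$cov_inv, inverted = TRUE)
    }
    ll
  }
  estimate <- function(lab) {
    lapply(seq_len(k), function(j) {
      idx <- which(lab == j)
      if (!length(idx)) return(NULL)
      mu <- colMeans(X[idx, , drop = FALSE])
      S <- if (length(idx) > 1) cov(X[idx, , drop = FALSE])
           else matrix(0, 4, 4)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < delta) {
        if (!ridge_warned) {
          warning("singular class covariance regularized with ridge ",
                  signif(delta, 3))
          ridge_warned <<- TRUE
        }
        S <- S + diag(delta, 4)
      }
      list(mean = mu, cov = S, cov_inv = solve(S),
           logdet = determinant(S, logarithm = TRUE)$modulus[1],
           n = length(idx))
    })
  }
  for (it in seq_len(max_iter)) {
    stats <- estimate(lab)
    ll <- loglik_matrix(stats)
    # re-seed empty classes from the worst-fit pixel
    for (j in seq_len(k)) {
      if (is.null(stats[[j]])) {
        worst <- which.min(apply(ll, 1, max))
        lab[worst] <- j
        stats <- estimate(lab)
        ll <- loglik_matrix(stats)
      }
    }
    new_lab <- max.col(ll, ties.method = "first")
    changed <- mean(new_lab != lab)
    lab <- new_lab
    if (changed < tol) break
  }
  stats <- estimate(lab)
  lg <- matrix(NA_real_, nr, ncl)
  lg[inw] <- lab - 1                      # labels 0..k-1
  grid <- ref; grid$values <- lg
  structure(list(grid = grid, k = k,
                 class_stats = lapply(stats, function(s)
                   if (is.null(s)) NULL
                   else list(mean = s$mean, cov = s$cov, n = s$n)),
                 wetland = wetland),
            class = "class_raster")
}

#' @export
print.class_raster <- function(x, ...) {
  cat(sprintf("<class_raster k = %d over %d labelled pixels>\n",
              x$k, sum(!is.na(x$grid$values))))
  invisible(x)
}

#' Reclassify spectral classes into a channel mask
#'
#' Unless `manual_map` is given, a class is labelled channel when its
#' mean NDWI = (G - NIR)/(G + NIR) over member pixels exceeds
#' `ndwi_threshold` (open water is NIR-dark, so NDWI > 0). The mask is
#' the union of channel classes intersected with the AOI.
#'
#' @param classes `class_raster` from [classify_scene()].
#' @param scene the classified [scene()].
#' @param ndwi_threshold NDWI cutoff (default 0).
#' @param manual_map optional character vector mapping class label
#'   (0-based, as names) to "channel" or "wetland"; overrides the NDWI
#'   rule entirely.
#' @return [channel_mask()].
#' @export
to_channel_mask <- function(classes, scene, ndwi_threshold = 0,
                            manual_map = NULL) {
  lg <- classes$grid$values
  if (!identical(dim(lg), dim(scene$bands$G$values)))
    stop("classes and scene must share the grid")
  if (is.null(manual_map)) {
    G <- scene$bands$G$values; NIR <- scene$bands$NIR$values
    ndwi <- (G - NIR) / (G + NIR)
    labs <- sort(unique(lg[!is.na(lg)]))
    mean_ndwi <- vapply(labs, function(l)
      mean(ndwi[!is.na(lg) & lg == l], na.rm = TRUE), numeric(1))
    is_channel_class <- mean_ndwi > ndwi_threshold
    if (all(is_channel_class) || !any(is_channel_class))
      warning("all classes fall on one side of the NDWI threshold; ",
              "returning an all-",
              if (all(is_channel_class)) "channel" else "platform", " mask")
    channel_labels <- labs[is_channel_class]
  } else {
    channel_labels <- as.numeric(names(manual_map)[manual_map == "channel"])
  }
  ch <- matrix(0, nrow(lg), ncol(lg))
  ch[!is.na(lg) & lg %in% channel_labels] <- 1
  g <- classes$grid; g$values <- ch; g$nodata <- -9999
  channel_mask(g, classes$wetland)
}

#' Extract a channel mask from a DEM
#'
#' A pixel is channel when its elevation lies more than `depth` below
#' the moving median of the DEM over a `window` x `window`
#' neighbourhood — a local-relief threshold standing in for
#' high-resolution channel extraction.
#'
#' @param dem [raster_grid()] DEM.
#' @param wetland 0/1 AOI raster (NULL = whole grid).
#' @param window odd window size in pixels (default 15).
#' @param depth incision threshold in meters (> 0).
#' @return [channel_mask()].
#' @export
dem_to_mask <- function(dem, wetland = NULL, window = 15, depth = 0.5) {
  stopifnot(window %% 2 == 1, depth > 0)
  if (window > min(dim(dem$values)))
    stop("window larger than the grid")
  med <- cpp_moving_median(dem$values, as.integer(window))
  ch <- matrix(0, nrow(dem$values), ncol(dem$values))
  ch[!is.na(dem$values) & !is.na(med) & dem$values < med - depth] <- 1
  g <- dem; g$values <- ch
  channel_mask(g, wetland)
}

#' Despeckle a channel mask
#'
#' Removes 8-connected channel components smaller than `min_component`
#' pixels and fills 4-connected platform holes (fully channel-enclosed,
#' away from the raster border) smaller than `max_hole` pixels.
#' Idempotent.
#'
#' @param mask [channel_mask()].
#' @param min_component minimum surviving channel component size (px).
#' @param max_hole maximum filled hole size (px).
#' @return cleaned [channel_mask()].
#' @export
clean_mask <- function(mask, min_component = 5, max_hole = 5) {
  v <- mask$grid$values
  nr <- nrow(v); ncl <- ncol(v)
  ch <- matrix(as.integer(v != 0), nr)
  lab <- cpp_label_components(ch, 8L)
  sz <- tabulate(lab[lab > 0])
  small <- which(sz < min_component)
  ch[lab %in% small] <- 0L
  # platform holes: 4-connected background regions not touching the border
  bg <- matrix(as.integer(ch == 0), nr)
  hl <- cpp_label_components(bg, 4L)
  border <- unique(c(hl[1, ], hl[nr, ], hl[, 1], hl[, ncl]))
  hsz <- tabulate(hl[hl > 0])
  fill <- setdiff(which(hsz < max_hole), border)
  ch[hl %in% fill] <- 1L
  g <- mask$grid; g$values <- matrix(as.numeric(ch), nr)
  channel_mask(g, mask$wetland)
}
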