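#' Order-removal sensitivity curve
#'
#' Reproduces the satellite-vs-reference sensitivity experiment:
#' low-order channels are successively removed from a high-resolution
#' (DEM-derived) network, the surviving edges are re-rasterized at
#' 1-pixel width (so mUpl responds to the pruning), and the wetland-wide
#' metric is recomputed on the same AOI for every removed order
#' r = 0 .. min(5, max_order - 1). Drainage density is non-increasing
#' and mUpl non-decreasing in r.
#'
#' @param network `channel_network` with assigned orders, max order >= 2
#'   (max order 1 yields the single r = 0 point).
#' @param mask the [channel_mask()] the network came from (fixes grid
#'   and AOI).
#' @param metric_name "D" (wetland-wide drainage density, 1/m) or
#'   "mUpl" (mean unchanneled path length over the AOI platform, m).
#' @param wetland_type recorded on the curve.
#' @return object of class `order_removal_curve` with `points`
#'   (data.frame r, value).
#' @export
order_removal_curve <- function(network, mask,
                                metric_name = c("D", "mUpl"),
                                wetland_type = "saltmarsh") {
  metric_name <- match.arg(metric_name)
  if (nrow(network$edges) == 0) stop("empty network")
  if (anyNA(network$edges$strahler_order))
    stop("orders not assigned: run assign_strahler() first")
  max_order <- max(network$edges$strahler_order)
  aoi_area <- sum(mask$wetland$values != 0) * mask$pixel_size^2
  rs <- 0:min(5, max_order - 1)
  vals <- vapply(rs, function(r) {
    pruned <- prune_orders(network, r)
    if (metric_name == "D") return(total_length(pruned) / aoi_area)
    pm <- rasterize_network(pruned, mask$grid, width = 1,
                            wetland = mask$wetland)
    d <- unchanneled_distance(pm)
    plat <- pm$wetland$values != 0 & pm$grid$values == 0
    mean(d$values[plat], na.rm = TRUE)
  }, numeric(1))
  structure(list(metric_name = metric_name, wetland_type = wetland_type,
                 points = data.frame(r = rs, value = vals)),
            class = "order_removal_curve")
}

#' Fit an exponential metric-vs-removed-order model
#'
#' Ordinary least squares of ln(metric) on the removed order r:
#' model(r) = alpha * exp(beta * r) with alpha = exp(intercept),
#' beta = slope.
#'
#' @param curve `order_removal_curve` with >= 3 strictly positive
#'   points.
#' @return object of class `correction_model` with fields `alpha`,
#'   `beta`, `fit_r2`, `metric_name`, `wetland_type`.
#' @export
fit_exponential <- function(curve) {
  pts <- curve$points
  if (nrow(pts) < 3) stop("need at least 3 points to fit")
  bad <- pts$r[pts$value <= 0]
  if (length(bad)) stop("non-positive metric value at removed order r = ",
                        paste(bad, collapse = ", "))
  fit <- lm(log(value) ~ r, data = pts)
  res <- residuals(fit)
  sst <- sum((log(pts$value) - mean(log(pts$value)))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1    # constant curve: exact
  structure(list(metric_name = curve$metric_name,
                 wetland_type = curve$wetland_type,
                 alpha = exp(unname(coef(fit)[1])),
                 beta = unname(coef(fit)[2]),
                 fit_r2 = r2),
            class = "correction_model")
}

#' Evaluate a correction model at removed order r
#'
#' @param model `correction_model`.
#' @param r removed order (vectorized).
#' @return alpha * exp(beta * r).
#' @export
model_value <- function(model, r) model$alpha * exp(model$beta * r)

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model %s/%s: %.6g * exp(%.4f * r), r^2 = %.4f>\n",
    x$metric_name, x$wetland_type, x$alpha, x$beta, x$fit_r2))
  invisible(x)
}

#' Correct a satellite-derived metric
#'
#' Inverts the fitted order-removal relationship: the effective removed
#' order r* = ln(value / alpha) / beta is the order at which the pruned
#' reference metric equals the satellite observation (clamped to
#' [0, 5]); the corrected value is value * alpha / model(r*), i.e. the
#' full-resolution level implied by the observation. When r* clamps to
#' 0 the value is returned unchanged; a degenerate beta = 0 model is an
#' identity correction (with a warning).
#'
#' @param satellite_value observed metric (> 0; vectorized).
#' @param model `correction_model`.
#' @return corrected value(s).
#' @export
apply_correction <- function(satellite_value, model) {
  stopifnot(all(satellite_value > 0))
  if (model$beta == 0) {
    warning("beta = 0: identity correction")
    return(satellite_value)
  }
  r_star <- log(satellite_value / model$alpha) / model$beta
  r_star <- pmin(pmax(r_star, 0), 5)
  satellite_value * model$alpha / model_value(model, r_star)
}

#' Serialize / deserialize correction models as JSON
#'
#' @param model `correction_model`.
#' @param path JSON file path.
#' @return `path` (write) or `correction_model` (read).
#' @export
write_correction_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj[c("metric_name", "wetland_type", "alpha", "beta", "fit_r2")],
            class = "correction_model")
}
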