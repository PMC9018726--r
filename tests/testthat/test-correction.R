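branchy_gen <- function(seed = 31) {
  generate_network(synthetic_spec(domain_shape = c(300, 300),
                                  n_outlets = 1, segment_len = 25,
                                  branch_prob = 0.5, max_order = 4,
                                  seed = seed))
}

test_that("order-removal curves are monotone and anchored at r = 0", {
  gen <- branchy_gen()
  cd <- order_removal_curve(gen$network, gen$mask, "D")
  cm <- order_removal_curve(gen$network, gen$mask, "mUpl")
  expect_true(all(diff(cd$points$value) < 0))       # D decreases
  expect_true(all(diff(cm$points$value) > 0))       # mUpl increases
  # r = 0 equals the uncorrected wetland-wide drainage density
  aoi_area <- sum(gen$mask$wetland$values != 0) * gen$mask$pixel_size^2
  expect_equal(cd$points$value[1],
               wetland_drainage_density(gen$network, aoi_area))
  expect_equal(cd$points$r, 0:(max(gen$network$edges$strahler_order) - 1))
})

test_that("fit_exponential recovers exact geometric decay and flags bad input", {
  curve <- structure(list(metric_name = "D", wetland_type = "saltmarsh",
                          points = data.frame(r = 0:2, value = c(10, 5, 2.5))),
                     class = "order_removal_curve")
  m <- fit_exponential(curve)
  expect_equal(m$alpha, 10, tolerance = 1e-10)
  expect_equal(m$beta, log(0.5), tolerance = 1e-10)
  expect_equal(m$fit_r2, 1)
  # constant curve: beta = 0, alpha = the constant
  cc <- curve; cc$points$value <- c(4, 4, 4)
  mc <- fit_exponential(cc)
  expect_equal(mc$beta, 0)
  expect_equal(mc$alpha, 4)
  # round-trip from model-generated curves, arbitrary parameters
  for (p in list(c(0.03, -0.5), c(120, -1.1), c(2, 0.8))) {
    gcurve <- curve
    gcurve$points <- data.frame(r = 0:4, value = p[1] * exp(p[2] * 0:4))
    gm <- fit_exponential(gcurve)
    expect_equal(gm$alpha, p[1], tolerance = 1e-10)
    expect_equal(gm$beta, p[2], tolerance = 1e-10)
  }
  bad <- curve; bad$points$value[2] <- 0
  expect_error(fit_exponential(bad), "r = 1")
  expect_error(fit_exponential(structure(list(
    points = data.frame(r = 0:1, value = c(1, 2))),
    class = "order_removal_curve")), "3 points")
})

test_that("apply_correction inverts the fitted model exactly", {
  model <- structure(list(metric_name = "D", wetland_type = "saltmarsh",
                          alpha = 10, beta = log(0.5), fit_r2 = 1),
                     class = "correction_model")
  # satellite at the full-resolution level -> unchanged
  expect_equal(apply_correction(10, model), 10)
  # worked example: D = 2.5 maps to r* = 2 and corrects to alpha
  expect_equal(apply_correction(2.5, model), 10)
  # exact inversion along the curve for any r in [0, 5]
  for (r in seq(0, 5, by = 0.5))
    expect_equal(apply_correction(model_value(model, r), model), 10,
                 tolerance = 1e-12)
  # correction never decreases D (beta < 0)
  vals <- c(0.5, 2, 8, 10)
  expect_true(all(apply_correction(vals, model) >= vals))
  flat <- model; flat$beta <- 0
  expect_warning(out <- apply_correction(5, flat), "identity")
  expect_equal(out, 5)
})

test_that("degraded satellite metrics correct back to full resolution", {
  # satellite view: orders 1-2 invisible; re-extract D from its raster,
  # correct it with the reference model, compare to full resolution.
  # Averaged over wetlands, as single trees carry fit-intercept noise.
  errs <- vapply(1:8, function(seed) {
    gen <- branchy_gen(seed)
    stopifnot(max(gen$network$edges$strahler_order) >= 3)
    model <- fit_exponential(order_removal_curve(gen$network, gen$mask, "D"))
    expect_lt(model$beta, 0)
    sat_mask <- rasterize_network(prune_orders(gen$network, 2),
                                  gen$mask$grid, width = 3,
                                  wetland = gen$mask$wetland)
    suppressWarnings(sat_net <- assign_strahler(identify_outlets(
      build_network(skeletonize(sat_mask)), sat_mask, "bottom")))
    aoi_area <- sum(gen$mask$wetland$values != 0) * gen$mask$pixel_size^2
    sat_D <- total_length(sat_net) / aoi_area
    full_D <- wetland_drainage_density(gen$network, aoi_area)
    corrected <- apply_correction(sat_D, model)
    expect_gt(corrected, sat_D)    # correction restores lost channels
    abs(corrected / full_D - 1)
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})

test_that("correction models serialize and read back", {
  model <- structure(list(metric_name = "mUpl", wetland_type = "mangrove",
                          alpha = 55.2, beta = 0.21, fit_r2 = 0.98),
                     class = "correction_model")
  f <- withr::local_tempfile(fileext = ".json")
  write_correction_model(model, f)
  back <- read_correction_model(f)
  expect_equal(back$alpha, model$alpha)
  expect_equal(back$beta, model$beta)
  expect_s3_class(back, "correction_model")
})
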