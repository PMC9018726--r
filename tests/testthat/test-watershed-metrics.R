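test_that("two parallel channels split the plane with ties to the smaller id", {
  m <- matrix(0, 11, 21)
  m[, 1] <- 1; m[, 21] <- 1
  mask <- mask_of(m)
  ws <- delineate_watersheds(mask)
  lab <- ws$labels$values
  expect_true(all(lab[, 1:11] == 1))     # col 11 is equidistant -> smaller id
  expect_true(all(lab[, 12:21] == 2))
  expect_equal(sum(ws$areas), 11 * 21)   # partition property
})

test_that("Euclidean allocation equals brute force on random grids", {
  set.seed(7)
  for (i in 1:30) {
    m <- matrix(0, 30, 30)
    m[cbind(sample(30, 12, TRUE), sample(30, 12, TRUE))] <- 1
    sites <- tidechan:::cpp_label_components(matrix(as.integer(m), 30), 8L)
    got <- tidechan:::cpp_edt_alloc(sites)
    want <- oracle_edt(sites)
    expect_equal(got$dist2, want$dist2, info = paste("grid", i))
    expect_equal(got$label, want$label, info = paste("grid", i))
  }
})

test_that("unchanneled distance: column channel, exhaustive oracle, homogeneity", {
  # channel along col 1, 1 m pixels: platform col i+1 lies i meters away
  m <- matrix(0, 5, 8); m[, 1] <- 1
  d <- unchanneled_distance(mask_of(m))
  for (i in 2:8) expect_equal(unname(d$values[, i]), rep(i - 1, 5))
  # distances scale linearly with pixel_size
  d3 <- unchanneled_distance(mask_of(m, px = 3))
  expect_equal(d3$values, 3 * d$values)
  # random 20x20 masks vs exhaustive nearest search
  set.seed(11)
  for (i in 1:10) {
    mm <- matrix(0, 20, 20)
    mm[cbind(sample(20, 8, TRUE), sample(20, 8, TRUE))] <- 1
    got <- unchanneled_distance(mask_of(mm))
    want <- sqrt(oracle_edt(matrix(as.integer(mm != 0), 20))$dist2)
    expect_equal(got$values, want, info = paste("mask", i))
  }
  expect_error(unchanneled_distance(mask_of(matrix(0, 4, 4))), "no channel")
})

test_that("metric identities: D, l_H, mUpl, GE on a strip watershed", {
  # channel along col 1, platform cols 2..11, 1 m pixels, 5 rows
  m <- matrix(0, 5, 11); m[, 1] <- 1
  mask <- mask_of(m)
  net <- assign_strahler(identify_outlets(
    build_network(skeletonize(mask)), mask, "bottom"))
  ws <- delineate_watersheds(mask, net)
  d <- unchanneled_distance(mask)
  rec <- compute_metrics(ws, net, d, mask, "strip", "saltmarsh")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mupl_m, mean(1:10))                    # 5.5 m
  expect_equal(rec$area_m2, 55)
  expect_equal(rec$drainage_density_per_m * rec$hortonian_length_m, 1)
  expect_equal(rec$geometric_efficiency,
               rec$hortonian_length_m / rec$mupl_m)
  # arithmetic example: sum(L) = 100 m over 1000 m^2
  expect_equal(100 / 1000, 0.1)
  expect_equal(1 / 0.1, 10)
})

test_that("bisecting channel approaches the w/4 continuous limit", {
  # channel bisecting a strip of width w: mUpl -> w/4; the discrete mean
  # equals the exact pixel average
  nrp <- 41; w <- nrp  # rows as the strip width, 1 m pixels
  m <- matrix(0, nrp, 9); m[(nrp + 1) / 2, ] <- 1
  d <- unchanneled_distance(mask_of(m))
  plat <- m == 0
  got <- mean(d$values[plat])
  half <- (nrp - 1) / 2
  closed_form <- mean(rep(abs(seq_len(nrp) - (nrp + 1) / 2)[plat[, 1]]))
  expect_equal(got, closed_form)
  expect_lt(abs(got - w / 4), 1)     # approaches w/4 in the limit
})

test_that("wetland drainage density is the area-weighted mean of D", {
  rec <- data.frame(area_m2 = c(1000, 500), total_length_m = c(100, 50),
                    drainage_density_per_m = c(0.1, 0.1))
  expect_equal(wetland_drainage_density(rec), 150 / 1500)
  expect_equal(wetland_drainage_density(rec),
               sum(rec$drainage_density_per_m * rec$area_m2) / sum(rec$area_m2))
  # empty network -> 0
  empty <- build_network(skeletonize(mask_of(matrix(0, 4, 4))))
  expect_equal(wetland_drainage_density(empty, aoi_area = 100), 0)
})

test_that("watersheds partition the AOI exactly, including non-square AOIs", {
  spec <- synthetic_spec(domain_shape = c(120, 160), n_outlets = 2,
                         segment_len = 40, max_order = 3, seed = 3)
  gen <- generate_network(spec)
  wl <- matrix(0, 120, 160); wl[10:110, 20:150] <- 1
  mask <- channel_mask(gen$mask$grid, raster_grid(wl, 3, gen$mask$grid$origin))
  ws <- delineate_watersheds(mask)
  expect_equal(sum(ws$areas), sum(wl) * 9)
  lab <- ws$labels$values
  expect_true(all(lab[wl == 0] == 0))
  expect_true(all(lab[wl == 1] > 0))
})

test_that("summarize_locations averages per location and groups per type", {
  rec <- rbind(
    data.frame(watershed_id = 1:2, location = "A", wetland_type = "saltmarsh",
               area_m2 = 1, total_length_m = 1,
               drainage_density_per_m = c(0.1, 0.3), mupl_m = c(4, 6),
               hortonian_length_m = 1, geometric_efficiency = c(1, 2)),
    data.frame(watershed_id = 1, location = "B", wetland_type = "mangrove",
               area_m2 = 1, total_length_m = 1,
               drainage_density_per_m = 0.05, mupl_m = 9,
               hortonian_length_m = 1, geometric_efficiency = 1.5))
  s <- summarize_locations(rec)
  a <- s$per_location[s$per_location$location == "A", ]
  expect_equal(a$D_mean, 0.2)
  expect_equal(a$D_se, 0.1)
  b <- s$per_location[s$per_location$location == "B", ]
  expect_true(is.na(b$D_se))                  # single watershed -> no SE
  expect_equal(names(s$per_type), c("mangrove", "saltmarsh"))
  expect_equal(nrow(s$per_type$saltmarsh), 1)
  # 8 + 7 locations -> type vectors of lengths 8 and 7
  many <- do.call(rbind, lapply(1:15, function(i) {
    data.frame(watershed_id = 1, location = paste0("L", i),
               wetland_type = if (i <= 8) "saltmarsh" else "mangrove",
               area_m2 = 1, total_length_m = 1,
               drainage_density_per_m = 0.1, mupl_m = 5,
               hortonian_length_m = 10, geometric_efficiency = 2)
  }))
  s2 <- summarize_locations(many)
  expect_equal(nrow(s2$per_type$saltmarsh), 8)
  expect_equal(nrow(s2$per_type$mangrove), 7)
})

test_that("no-channel AOI degenerates to a single warned watershed", {
  mask <- mask_of(matrix(0, 10, 10))
  expect_warning(ws <- delineate_watersheds(mask), "no channel")
  expect_equal(sum(ws$areas), 100)
})

test_that("GE is invariant under uniform spatial rescaling", {
  spec <- synthetic_spec(domain_shape = c(120, 120), n_outlets = 1,
                         segment_len = 40, max_order = 3, seed = 5)
  gen <- generate_network(spec)
  compute_ge <- function(mask, net) {
    ws <- delineate_watersheds(mask, net)
    d <- unchanneled_distance(mask)
    compute_metrics(ws, net, d, mask)$geometric_efficiency
  }
  net <- assign_strahler(identify_outlets(
    build_network(skeletonize(gen$mask)), gen$mask, "bottom"))
  ge1 <- compute_ge(gen$mask, net)
  # same pixels at doubled pixel size: l_H and mUpl both scale by 2
  g2 <- gen$mask$grid; g2$pixel_size <- 6
  w2 <- gen$mask$wetland; w2$pixel_size <- 6
  mask2 <- channel_mask(g2, w2)
  net2 <- assign_strahler(identify_outlets(
    build_network(skeletonize(mask2)), mask2, "bottom"))
  ge2 <- compute_ge(mask2, net2)
  expect_equal(ge2, ge1, tolerance = 1e-9)
})
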