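#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of (spec, seed).
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic wetland
#'
#' Defaults state a realistic desk-scale wetland: a 500 x 500 grid of
#' 3 m pixels (the working resolution of the satellite analysis, so a
#' 1.5 x 1.5 km tile), three networks rooted on the seaward (bottom)
#' edge, landward-branching growth, order-dependent channel widths up
#' to 3 pixels, and NDWI-separable 4-band spectra (vegetation bright in
#' NIR, water dark in NIR) with additive Gaussian noise.
#'
#' @param domain_shape (rows, cols) of the raster domain.
#' @param pixel_size pixel edge in meters.
#' @param n_outlets number of networks rooted on the seaward edge.
#' @param branch_prob probability per interior growth step that a
#'   stream emits a one-order-lower side tributary; 0 disables all
#'   branching (one order-1 channel per outlet).
#' @param segment_len mean segment length in meters.
#' @param max_order order budget of the trunk stream: a stream of
#'   budget o runs 2*o segments and ends in a junction of two budget
#'   o-1 children (Strahler cascade with side branching, giving
#'   near-geometric Hortonian length ratios). Boundary clipping and
#'   channel competition can leave realized maximum orders below the
#'   budget; ground-truth orders are always recomputed from topology.
#' @param width_per_order function mapping Strahler order to channel
#'   width in pixels (default `min(order, 3)`).
#' @param spectra list with `vegetation`/`channel` mean 4-vectors
#'   (R, G, B, NIR digital numbers) and `noise_sd`.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(domain_shape = c(500, 500), pixel_size = 3,
                           n_outlets = 3, branch_prob = 0.35,
                           segment_len = 60, max_order = 4,
                           width_per_order = function(o) pmin(o, 3),
                           spectra = list(
                             vegetation = c(90, 80, 60, 200),
                             channel = c(60, 70, 80, 30),
                             noise_sd = 5),
                           seed = 1L) {
  stopifnot(branch_prob >= 0, branch_prob <= 1, n_outlets >= 1,
            segment_len > 0, all(domain_shape >= 8))
  structure(list(domain_shape = domain_shape, pixel_size = pixel_size,
                 n_outlets = n_outlets, branch_prob = branch_prob,
                 segment_len = segment_len, max_order = max_order,
                 width_per_order = width_per_order, spectra = spectra,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a ground-truthed branching channel network
#'
#' Grows, from each of `n_outlets` points on the seaward (bottom) edge,
#' a landward-branching tree of straight vector segments: every active
#' tip extends by a jittered segment each step and bifurcates with
#' probability `branch_prob`; tips leaving the domain are clipped and
#' stopped. The exact vector network (per-edge lengths and Strahler
#' orders computed from the tree topology) is the ground truth; the
#' mask is its rasterization at order-dependent widths, so skeleton
#' artifacts never contaminate the truth.
#'
#' @param spec [synthetic_spec()].
#' @return list with `network` (vector `channel_network`, orders set,
#'   roots marked outlet), `mask` ([channel_mask()], AOI = full domain),
#'   and `truth` (list: `edges` data.frame, `total_length_m`,
#'   `max_order`, per-component `component_length_m`).
#' @export
generate_network <- function(spec) {
  nr <- spec$domain_shape[1]; ncl <- spec$domain_shape[2]
  px <- spec$pixel_size
  W <- ncl * px; H <- nr * px
  if (ncl < 2 * spec$n_outlets)
    stop("domain too small to place ", spec$n_outlets, " outlets")
  with_seed(spec$seed, {
    outlets_x <- (seq_len(spec$n_outlets) - 0.5) * W / spec$n_outlets
    nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
    edges <- data.frame(id = integer(0), node_a = integer(0),
                        node_b = integer(0), length_m = numeric(0),
                        component_id = integer(0))
    parent_of <- integer(0)       # edge id -> parent edge id (0 = root edge)
    add_node <- function(x, y) {
      nodes[nrow(nodes) + 1L, ] <<- list(nrow(nodes) + 1L, x, y)
      nrow(nodes)
    }
    add_edge <- function(a, b, comp, parent) {
      id <- nrow(edges) + 1L
      len <- sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2)
      edges[id, ] <<- list(id, a, b, len, comp)
      parent_of[id] <<- parent
      id
    }
    # occupancy grid enforcing a minimum centreline separation of one
    # cell (4 pixels) between distinct channels, so rasterized branches
    # at widths <= 3 px never merge and the network stays a forest
    cs <- 4 * px
    occ <- matrix(FALSE, ceiling(H / cs), ceiling(W / cs))
    occ_cell <- function(x, y)
      cbind(pmin(pmax(ceiling(y / cs), 1L), nrow(occ)),
            pmin(pmax(ceiling(x / cs), 1L), ncol(occ)))
    seg_points <- function(x0, y0, x1, y1) {
      L <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(L / (cs / 2)) + 1L))
      list(x = x0 + t * (x1 - x0), y = y0 + t * (y1 - y0),
           arc = t * L)
    }
    seg_blocked <- function(x0, y0, x1, y1) {
      p <- seg_points(x0, y0, x1, y1)
      test <- p$arc > 4 * cs                 # carve-out near the junction
      if (!any(test)) return(FALSE)
      rc <- occ_cell(p$x[test], p$y[test])
      for (q in seq_len(nrow(rc))) {
        i0 <- max(1L, rc[q, 1] - 1L); i1 <- min(nrow(occ), rc[q, 1] + 1L)
        j0 <- max(1L, rc[q, 2] - 1L); j1 <- min(ncol(occ), rc[q, 2] + 1L)
        if (any(occ[i0:i1, j0:j1])) return(TRUE)
      }
      FALSE
    }
    seg_mark <- function(x0, y0, x1, y1) {
      p <- seg_points(x0, y0, x1, y1)
      occ[occ_cell(p$x, p$y)] <<- TRUE
    }
    # one segment of jittered length/direction; returns the new node id
    # or 0 when the tip was clipped at the boundary or blocked by an
    # established channel (competition for drainage area)
    extend <- function(node, ang, comp, pedge) {
      len <- spec$segment_len * runif(1, 0.7, 1.3)
      x1 <- nodes$x[node] + len * sin(ang)
      y1 <- nodes$y[node] + len * cos(ang)    # landward = +y
      clipped <- FALSE
      m <- 0.5 * px
      if (x1 < m || x1 > W - m || y1 > H - m) {
        tmax <- 1
        if (x1 < m) tmax <- min(tmax, (m - nodes$x[node]) /
                                        (x1 - nodes$x[node]))
        if (x1 > W - m) tmax <- min(tmax, (W - m - nodes$x[node]) /
                                            (x1 - nodes$x[node]))
        if (y1 > H - m) tmax <- min(tmax, (H - m - nodes$y[node]) /
                                            (y1 - nodes$y[node]))
        tmax <- max(tmax, 0)
        x1 <- nodes$x[node] + tmax * (x1 - nodes$x[node])
        y1 <- nodes$y[node] + tmax * (y1 - nodes$y[node])
        clipped <- TRUE
      }
      if (sqrt((x1 - nodes$x[node])^2 + (y1 - nodes$y[node])^2) < 0.5 * px)
        return(list(node = 0L, edge = pedge))
      if (seg_blocked(nodes$x[node], nodes$y[node], x1, y1))
        return(list(node = 0L, edge = pedge))
      nid <- add_node(x1, y1)
      seg_mark(nodes$x[node], nodes$y[node], x1, y1)
      eid <- add_edge(node, nid, comp, pedge)
      list(node = if (clipped) 0L else nid, edge = eid)
    }
    # Strahler cascade with Tokunaga-style side branching: a stream of
    # budget o runs 2^(o-1) segments (Horton length ratio R_L = 2),
    # emits Binomial(2, branch_prob) one-order-lower side tributaries at
    # random interior steps, and ends in a junction of two budget o-1
    # children, so the bifurcation ratio R_B = 2 + 2 * branch_prob and
    # the expected channel length per order decays geometrically -- the
    # Hortonian regularity the order-removal correction presumes.
    grow_stream <- function(node, ang, order, comp, pedge) {
      nseg <- 2L^(order - 1L)
      side_steps <- integer(0)
      if (order > 1L && nseg > 1L) {
        n_side <- rbinom(1, 2, spec$branch_prob)
        if (n_side > 0)
          side_steps <- sample(seq_len(nseg - 1L), min(n_side, nseg - 1L))
      }
      for (step in seq_len(nseg)) {
        ang_j <- ang + rnorm(1, 0, 12 * pi / 180)
        ang_j <- max(min(ang_j, 70 * pi / 180), -70 * pi / 180)
        res <- extend(node, ang_j, comp, pedge)
        if (res$node == 0L) return(invisible(NULL))  # clipped or blocked
        node <- res$node; pedge <- res$edge; ang <- ang_j
        if (step %in% side_steps) {
          side <- sample(c(-1, 1), 1) * runif(1, 35, 60) * pi / 180
          grow_stream(node, ang + side, order - 1L, comp, pedge)
        }
      }
      if (order > 1L) {
        spread <- runif(1, 20, 40) * pi / 180
        grow_stream(node, ang - spread, order - 1L, comp, pedge)
        grow_stream(node, ang + spread, order - 1L, comp, pedge)
      }
      invisible(NULL)
    }
    top <- if (spec$branch_prob > 0) spec$max_order else 1L
    for (k in seq_len(spec$n_outlets)) {
      root <- add_node(outlets_x[k], 0.5 * px)   # on the bottom pixel row
      grow_stream(root, 0, top, k, 0L)
    }
    # Strahler orders from the stored tree topology (children lists)
    ne <- nrow(edges)
    children <- vector("list", ne)
    for (e in seq_len(ne)) {
      p <- parent_of[e]
      if (p > 0L) children[[p]] <- c(children[[p]], e)
    }
    ord <- integer(ne)
    # process edges deepest-first: edges were appended level by level
    for (e in rev(seq_len(ne))) {
      ch <- children[[e]]
      if (is.null(ch)) ord[e] <- 1L
      else {
        m <- max(ord[ch])
        ord[e] <- if (sum(ord[ch] == m) >= 2L) m + 1L else m
      }
    }
    template <- raster_grid(matrix(0, nr, ncl), px, origin = c(0, H))
    polylines <- lapply(seq_len(ne), function(e) {
      a <- edges$node_a[e]; b <- edges$node_b[e]
      cbind(c(nodes$x[a], nodes$x[b]), c(nodes$y[a], nodes$y[b]))
    })
    rc <- world_to_pixel(template, nodes$x, nodes$y)
    deg <- tabulate(c(edges$node_a, edges$node_b), nbins = nrow(nodes))
    comp_of_node <- integer(nrow(nodes))
    comp_of_node[edges$node_a] <- edges$component_id
    comp_of_node[edges$node_b] <- edges$component_id
    is_root <- nodes$id %in% edges$node_a[parent_of == 0L]
    node_df <- data.frame(
      id = nodes$id, x = nodes$x, y = nodes$y,
      row = pmin(pmax(rc[, 1], 1L), nr), col = pmin(pmax(rc[, 2], 1L), ncl),
      role = ifelse(is_root, "outlet",
                    ifelse(deg <= 1, "endpoint", "junction")),
      component_id = comp_of_node, stringsAsFactors = FALSE)
    edge_df <- data.frame(
      id = edges$id, node_a = edges$node_a, node_b = edges$node_b,
      length_m = edges$length_m, strahler_order = ord,
      component_id = edges$component_id)
    network <- new_channel_network(node_df, edge_df, polylines, px)
    mask <- rasterize_network(network, template,
                              width = spec$width_per_order)
    truth_edges <- cbind(edge_df, parent_edge = parent_of)
    truth <- list(
      edges = truth_edges,
      total_length_m = sum(edge_df$length_m),
      component_length_m = tapply(edge_df$length_m, edge_df$component_id, sum),
      max_order = max(ord))
    list(network = network, mask = mask, truth = truth)
  })
}

#' Synthesize a 4-band scene from a channel mask
#'
#' Per-pixel band values are the class mean (channel vs vegetation)
#' plus zero-mean Gaussian noise. Channel spectra are water-like
#' (NIR < G), vegetation NIR-bright (NIR > R).
#'
#' @param mask [channel_mask()].
#' @param spec [synthetic_spec()] carrying `spectra` and `seed`.
#' @return [scene()].
#' @export
generate_scene <- function(mask, spec) {
  sp <- spec$spectra
  stopifnot(length(sp$vegetation) == 4, length(sp$channel) == 4)
  nr <- nrow(mask$grid$values); ncl <- ncol(mask$grid$values)
  ch <- mask$grid$values != 0
  with_seed(spec$seed + 1L, {
    bands <- lapply(1:4, function(b) {
      m <- matrix(sp$vegetation[b], nr, ncl)
      m[ch] <- sp$channel[b]
      if (sp$noise_sd > 0) m <- m + matrix(rnorm(nr * ncl, 0, sp$noise_sd),
                                           nr, ncl)
      raster_grid(m, mask$pixel_size, mask$grid$origin)
    })
    names(bands) <- c("R", "G", "B", "NIR")
    scene(bands)
  })
}

#' Synthesize a channelized DEM from a channel mask
#'
#' Platform pixels at `platform_z` plus noise, channel pixels incised
#' `channel_depth` below, plus noise.
#'
#' @param mask [channel_mask()].
#' @param platform_z platform elevation (m).
#' @param channel_depth incision depth (m, > 0).
#' @param noise_sd elevation noise sd (m).
#' @param seed RNG seed.
#' @return [raster_grid()] DEM.
#' @export
generate_dem <- function(mask, platform_z = 1, channel_depth = 1,
                         noise_sd = 0, seed = 1L) {
  stopifnot(channel_depth > 0)
  nr <- nrow(mask$grid$values); ncl <- ncol(mask$grid$values)
  with_seed(seed, {
    z <- matrix(platform_z, nr, ncl)
    z[mask$grid$values != 0] <- platform_z - channel_depth
    if (noise_sd > 0) z <- z + matrix(rnorm(nr * ncl, 0, noise_sd), nr, ncl)
    raster_grid(z, mask$pixel_size, mask$grid$origin)
  })
}

#' Generate a power-law (area, total length) scaling dataset
#'
#' Areas are log-uniform on `area_range`; total lengths follow
#' sum(L) = a * Area^b * exp(eps) with eps ~ N(0, log_noise_sd^2),
#' i.e. a power law with lognormal scatter as observed for tidal
#' channel networks.
#'
#' @param a coefficient; defaults to 0.020, the Venetian salt-marsh
#'   reference line.
#' @param b exponent; defaults to 1.
#' @param n number of watersheds (>= 3).
#' @param area_range (min, max) watershed areas in m^2.
#' @param log_noise_sd sd of the lognormal scatter (natural-log scale).
#' @param seed RNG seed.
#' @return data.frame with columns `area_m2`, `total_length_m`.
#' @export
generate_scaling_dataset <- function(a = 0.020, b = 1, n = 100,
                                     area_range = c(1e3, 1e7),
                                     log_noise_sd = 0.3, seed = 1L) {
  stopifnot(n >= 3, all(area_range > 0))
  with_seed(seed, {
    A <- exp(runif(n, log(area_range[1]), log(area_range[2])))
    eps <- if (log_noise_sd > 0) rnorm(n, 0, log_noise_sd) else rep(0, n)
    data.frame(area_m2 = A, total_length_m = a * A^b * exp(eps))
  })
}
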