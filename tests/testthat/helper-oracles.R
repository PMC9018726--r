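# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Recursive Strahler recomputation on a parent->child edge table
# (node_a = upstream end). Returns orders in edge order.
oracle_strahler <- function(edges) {
  children_of <- lapply(seq_len(nrow(edges)), function(e)
    which(edges$node_a == edges$node_b[e]))
  memo <- rep(NA_integer_, nrow(edges))
  rec <- function(e) {
    if (!is.na(memo[e])) return(memo[e])
    ch <- children_of[[e]]
    o <- if (!length(ch)) 1L else {
      oo <- vapply(ch, rec, integer(1))
      m <- max(oo)
      if (sum(oo == m) >= 2L) m + 1L else m
    }
    memo[e] <<- o
    o
  }
  vapply(seq_len(nrow(edges)), rec, integer(1))
}

# Brute-force exact nearest-site search: for every pixel, scan all site
# pixels; ties broken toward the smaller label.
oracle_edt <- function(sites) {
  nr <- nrow(sites); nc <- ncol(sites)
  sp <- which(sites > 0, arr.ind = TRUE)
  labs <- sites[sp]
  d2 <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dd <- (sp[, 1] - r)^2 + (sp[, 2] - c)^2
    best <- min(dd)
    d2[r, c] <- best
    lab[r, c] <- min(labs[dd == best])
  }
  list(dist2 = d2, label = lab)
}

# Run-length channel count: maximal runs of >= 2 TRUE values.
oracle_run_count <- function(eroded_line) {
  n <- 0L; run <- 0L
  for (v in c(eroded_line, FALSE)) {
    if (v) run <- run + 1L
    else { if (run >= 2L) n <- n + 1L; run <- 0L }
  }
  n
}

# Vector-geometry mUpl truth: mean over platform pixels of the distance
# from the pixel centre to the nearest channel edge (nearest polyline
# minus the stamped half-width), floored at 0.
oracle_mupl <- function(gen, spec) {
  mask <- gen$mask
  net <- gen$network
  px <- spec$pixel_size
  nr <- nrow(mask$grid$values); ncl <- ncol(mask$grid$values)
  plat <- which(mask$grid$values == 0 & mask$wetland$values != 0,
                arr.ind = TRUE)
  pxy <- pixel_to_world(mask$grid, plat[, 1], plat[, 2])
  best <- rep(Inf, nrow(plat))
  for (e in seq_along(net$polylines)) {
    pl <- net$polylines[[e]]
    w <- spec$width_per_order(net$edges$strahler_order[e])
    half <- (w / 2) * px
    for (s in seq_len(nrow(pl) - 1)) {
      dx <- pl[s + 1, 1] - pl[s, 1]; dy <- pl[s + 1, 2] - pl[s, 2]
      L2 <- dx^2 + dy^2
      t <- ((pxy[, 1] - pl[s, 1]) * dx + (pxy[, 2] - pl[s, 2]) * dy) / L2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((pxy[, 1] - pl[s, 1] - t * dx)^2 +
                (pxy[, 2] - pl[s, 2] - t * dy)^2) - half
      best <- pmin(best, pmax(d, 0))
    }
  }
  mean(best)
}

# Small deterministic raster helpers
grid_of <- function(m, px = 1) raster_grid(m, px)
mask_of <- function(m, px = 1, wetland = NULL) {
  channel_mask(raster_grid(m, px),
               if (is.null(wetland)) NULL else raster_grid(wetland, px))
}
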