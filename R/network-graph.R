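#' @keywords internal
new_channel_network <- function(nodes, edges, polylines, pixel_size) {
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 pixel_size = pixel_size),
            class = "channel_network")
}

#' @export
print.channel_network <- function(x, ...) {
  cat(sprintf(
    "<channel_network %d nodes, %d edges, %d components, sum(L) = %.1f m>\n",
    nrow(x$nodes), nrow(x$edges),
    length(unique(x$edges$component_id)), total_length(x)))
  invisible(x)
}

#' Thin a channel mask to a 1-pixel centerline skeleton
#'
#' Morphological (Zhang-Suen) thinning producing an 8-connected,
#' 1-pixel-wide skeleton with the same number of connected components
#' as the input mask.
#'
#' @param mask [channel_mask()].
#' @return binary [raster_grid()] skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "channel_mask"))
  m <- mask$grid$values
  im <- matrix(as.integer(m != 0 & !is.na(m)), nrow(m))
  sk <- cpp_thin(im)
  g <- mask$grid
  g$values <- matrix(as.numeric(sk), nrow(m))
  g
}

#' Build a measured centerline graph from a skeleton
#'
#' Nodes sit at skeleton pixels with a number of 8-neighbours different
#' from 2 (endpoints and junctions); edges are traced through degree-2
#' chains. Step lengths are `pixel_size` for rook moves and
#' `sqrt(2) * pixel_size` for diagonal moves. An isolated cycle (all
#' pixels degree 2) receives one artificial junction node.
#'
#' @param skeleton binary [raster_grid()] from [skeletonize()].
#' @param pixel_size pixel edge in meters (defaults to the skeleton's).
#' @return `channel_network` with world-coordinate polylines, per-edge
#'   lengths and component ids; Strahler orders unset.
#' @export
build_network <- function(skeleton, pixel_size = skeleton$pixel_size) {
  v <- skeleton$values
  nr <- nrow(v); ncl <- ncol(v)
  im <- matrix(as.integer(v != 0 & !is.na(v)), nr)
  # reduced adjacency: diagonal contacts that share a rook neighbour are
  # redundant (staircase elbows), both here and in the tracing below
  deg <- cpp_neighbor_count(im, TRUE)
  comp <- cpp_label_components(im, 8L)
  idx <- which(im == 1)                       # column-major linear indices
  if (length(idx) == 0) {
    return(new_channel_network(
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 row = integer(0), col = integer(0),
                 role = character(0), component_id = integer(0),
                 stringsAsFactors = FALSE),
      data.frame(id = integer(0), node_a = integer(0), node_b = integer(0),
                 length_m = numeric(0), strahler_order = integer(0),
                 component_id = integer(0)),
      list(), pixel_size))
  }
  is_node <- im == 1 & deg != 2
  # 8-neighbour offsets in (row, col)
  offs <- cbind(dr = c(-1,-1,-1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1,-1, 1,-1, 0, 1))
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= ncl && im[r, c] == 1
  nbrs_of <- function(r, c) {
    out <- matrix(0L, 0, 2)
    for (k in seq_len(8)) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (!at(rr, cc)) next
      if (offs[k, 1] != 0 && offs[k, 2] != 0 &&
          (at(r, cc) || at(rr, c))) next     # redundant diagonal
      out <- rbind(out, c(rr, cc))
    }
    out
  }
  node_lin <- which(is_node)
  node_id <- integer(0)
  node_map <- new.env(hash = TRUE)
  nodes_rc <- arrayInd(node_lin, c(nr, ncl))
  for (i in seq_along(node_lin))
    assign(as.character(node_lin[i]), i, envir = node_map)

  visited <- matrix(FALSE, nr, ncl)           # chain pixels consumed
  edges_a <- edges_b <- integer(0)
  edges_len <- numeric(0)
  edges_comp <- integer(0)
  polylines <- list()
  seen_pair <- new.env(hash = TRUE)           # direct node-node contacts

  step_len <- function(rc) {                  # rc: k x 2 pixel path
    if (nrow(rc) < 2) return(0)
    d <- abs(diff(rc))
    sum(ifelse(rowSums(d) == 2, sqrt(2), 1)) * pixel_size
  }
  add_edge <- function(a, b, rc) {
    edges_a <<- c(edges_a, a); edges_b <<- c(edges_b, b)
    edges_len <<- c(edges_len, step_len(rc))
    edges_comp <<- c(edges_comp, comp[rc[1, 1], rc[1, 2]])
    polylines[[length(polylines) + 1L]] <<-
      pixel_to_world(skeleton, rc[, 1], rc[, 2])
  }

  for (i in seq_along(node_lin)) {
    r0 <- nodes_rc[i, 1]; c0 <- nodes_rc[i, 2]
    for (k in seq_len(nrow(offs))) {
      r1 <- r0 + offs[k, 1]; c1 <- c0 + offs[k, 2]
      if (r1 < 1 || r1 > nr || c1 < 1 || c1 > ncl || im[r1, c1] == 0) next
      if (offs[k, 1] != 0 && offs[k, 2] != 0 &&
          (at(r0, c1) || at(r1, c0))) next   # redundant diagonal
      if (is_node[r1, c1]) {
        j <- get(as.character((c1 - 1L) * nr + r1), envir = node_map)
        key <- paste(min(i, j), max(i, j))
        if (!exists(key, envir = seen_pair)) {
          assign(key, TRUE, envir = seen_pair)
          add_edge(i, j, rbind(c(r0, c0), c(r1, c1)))
        }
        next
      }
      if (visited[r1, c1]) next
      # walk the degree-2 chain
      path <- list(c(r0, c0), c(r1, c1))
      visited[r1, c1] <- TRUE
      prev <- c(r0, c0); cur <- c(r1, c1)
      repeat {
        nb <- nbrs_of(cur[1], cur[2])
        nxt <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nxt) == 0) break             # dead-end chain pixel
        nxt <- nxt[1, ]
        if (is_node[nxt[1], nxt[2]]) {
          path[[length(path) + 1L]] <- nxt
          j <- get(as.character((nxt[2] - 1L) * nr + nxt[1]), envir = node_map)
          add_edge(i, j, do.call(rbind, path))
          break
        }
        if (visited[nxt[1], nxt[2]]) {        # chain loops back onto itself
          path[[length(path) + 1L]] <- nxt
          add_edge(i, i, do.call(rbind, path))
          break
        }
        visited[nxt[1], nxt[2]] <- TRUE
        path[[length(path) + 1L]] <- nxt
        prev <- cur; cur <- nxt
      }
    }
  }

  # isolated cycles: every pixel degree 2, none visited, no node on them
  rest <- which(im == 1 & !is_node & !visited)
  if (length(rest)) {
    rest_rc <- arrayInd(rest, c(nr, ncl))
    handled <- rep(FALSE, length(rest))
    lin_of <- function(rc) as.integer((rc[2] - 1L) * nr + rc[1])
    rest_lin <- rest
    for (s in seq_along(rest)) {
      if (handled[s]) next
      r0 <- rest_rc[s, 1]; c0 <- rest_rc[s, 2]
      # artificial node at the first pixel of the cycle
      nodes_rc <- rbind(nodes_rc, c(r0, c0))
      node_lin <- c(node_lin, lin_of(c(r0, c0)))
      i <- nrow(nodes_rc)
      is_node[r0, c0] <- TRUE
      assign(as.character(lin_of(c(r0, c0))), i, envir = node_map)
      nb <- nbrs_of(r0, c0)
      path <- list(c(r0, c0), nb[1, ])
      prev <- c(r0, c0); cur <- nb[1, ]
      visited[cur[1], cur[2]] <- TRUE
      repeat {
        nb2 <- nbrs_of(cur[1], cur[2])
        nxt <- nb2[!(nb2[, 1] == prev[1] & nb2[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nxt) == 0) break
        nxt <- nxt[1, ]
        path[[length(path) + 1L]] <- nxt
        if (nxt[1] == r0 && nxt[2] == c0) break
        visited[nxt[1], nxt[2]] <- TRUE
        prev <- cur; cur <- nxt
      }
      handled[rest_lin %in% vapply(path, lin_of, integer(1))] <- TRUE
      add_edge(i, i, do.call(rbind, path))
    }
  }

  xy <- pixel_to_world(skeleton, nodes_rc[, 1], nodes_rc[, 2])
  ndeg <- deg[cbind(nodes_rc[, 1], nodes_rc[, 2])]
  nodes <- data.frame(
    id = seq_len(nrow(nodes_rc)), x = xy[, 1], y = xy[, 2],
    row = nodes_rc[, 1], col = nodes_rc[, 2],
    role = ifelse(ndeg <= 1, "endpoint", "junction"),
    component_id = comp[cbind(nodes_rc[, 1], nodes_rc[, 2])],
    stringsAsFactors = FALSE)
  edges <- data.frame(
    id = seq_along(edges_a), node_a = edges_a, node_b = edges_b,
    length_m = edges_len, strahler_order = NA_integer_,
    component_id = edges_comp)
  new_channel_network(nodes, edges, polylines, pixel_size)
}

#' Mark seaward outlets on a channel network
#'
#' For every connected component, endpoints lying within two pixels of
#' the seaward raster edge are marked as outlets; a component with no
#' such endpoint gets its endpoint closest to that edge (junctions are
#' used as a fallback for endpoint-free components). Every component
#' ends up with at least one outlet.
#'
#' @param network `channel_network` from [build_network()].
#' @param mask the [channel_mask()] the network came from.
#' @param seaward_edge one of "top", "bottom", "left", "right".
#' @return network with node roles updated.
#' @export
identify_outlets <- function(network, mask,
                             seaward_edge = c("bottom", "top", "left", "right")) {
  seaward_edge <- match.arg(seaward_edge)
  nr <- nrow(mask$grid$values); ncl <- ncol(mask$grid$values)
  edge_dist <- switch(seaward_edge,
    bottom = nr - network$nodes$row,
    top    = network$nodes$row - 1L,
    left   = network$nodes$col - 1L,
    right  = ncl - network$nodes$col)
  nodes <- network$nodes
  for (cid in unique(nodes$component_id)) {
    in_comp <- nodes$component_id == cid
    ep <- in_comp & nodes$role == "endpoint"
    hits <- ep & edge_dist <= 2L
    if (!any(hits)) {
      cand <- if (any(ep)) which(ep) else which(in_comp)
      hits <- rep(FALSE, nrow(nodes))
      hits[cand[which.min(edge_dist[cand])]] <- TRUE
    }
    nodes$role[hits] <- "outlet"
  }
  network$nodes <- nodes
  network
}

#' Assign Strahler stream orders
#'
#' Each component is rooted at its outlet (the smallest-id outlet when
#' several touch the seaward edge). Edges ending in leaves get order 1;
#' downstream of a junction the order is the maximum of the upstream
#' orders, incremented by one when that maximum is attained by at least
#' two upstream branches. A component containing a cycle is first
#' reduced to its shortest-path (Dijkstra) tree from the outlet: every
#' non-tree edge closes a cycle at its farthest point from the outlet
#' and is dropped with a warning.
#'
#' @param network `channel_network` with outlets identified.
#' @return network with `strahler_order` set on every surviving edge.
#' @export
assign_strahler <- function(network) {
  nodes <- network$nodes; edges <- network$edges
  if (!any(nodes$role == "outlet"))
    stop("no outlets identified: run identify_outlets() first")
  edges$strahler_order <- NA_integer_
  drop_edge <- rep(FALSE, nrow(edges))
  for (cid in unique(edges$component_id)) {
    eidx <- which(edges$component_id == cid)
    nid <- nodes$id[nodes$component_id == cid]
    root_ids <- nodes$id[nodes$component_id == cid & nodes$role == "outlet"]
    if (!length(root_ids)) next
    nv <- length(nid)
    a <- match(edges$node_a[eidx], nid)
    b <- match(edges$node_b[eidx], nid)
    root <- match(min(root_ids), nid)
    # adjacency as flat vectors: for local node u, incident (edge, other)
    inc_edge <- c(seq_along(eidx), seq_along(eidx))
    inc_node <- c(b, a)
    ord_by <- order(c(a, b))
    inc_edge <- inc_edge[ord_by]; inc_node <- inc_node[ord_by]
    ptr <- cumsum(c(0L, tabulate(c(a, b)[ord_by], nbins = nv)))
    # Dijkstra from the outlet over edge lengths (O(V^2), V is modest)
    distv <- rep(Inf, nv); distv[root] <- 0
    parent_edge <- rep(NA_integer_, nv)      # local edge index into eidx
    done <- rep(FALSE, nv)
    len <- edges$length_m[eidx]
    repeat {
      u <- which.min(ifelse(done, Inf, distv))
      if (!is.finite(distv[u]) || done[u]) break
      done[u] <- TRUE
      if (ptr[u + 1L] > ptr[u]) {
        for (k in (ptr[u] + 1L):ptr[u + 1L]) {
          v <- inc_node[k]; e <- inc_edge[k]
          nd <- distv[u] + len[e]
          if (!done[v] && nd < distv[v]) {
            distv[v] <- nd
            parent_edge[v] <- e
          }
        }
      }
    }
    tree_edges <- parent_edge[!is.na(parent_edge)]
    extra <- setdiff(seq_along(eidx), tree_edges)
    if (length(extra)) {
      warning("component ", cid, " contains cycles; ",
              length(extra), " edge(s) broken farthest from the outlet")
      drop_edge[eidx[extra]] <- TRUE
    }
    # children lists in the rooted tree
    kids <- vector("list", nv)
    for (v in which(!is.na(parent_edge))) {
      e <- parent_edge[v]
      u <- if (a[e] == v) b[e] else a[e]
      kids[[u]] <- c(kids[[u]], v)
    }
    # reverse preorder = children before parents
    pre <- integer(0)
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      pre <- c(pre, v)
      stack <- c(stack, kids[[v]])
    }
    edge_order <- rep(NA_integer_, nv)
    for (v in rev(pre)) {
      ch <- kids[[v]]
      if (!length(ch)) edge_order[v] <- 1L
      else {
        oo <- edge_order[ch]
        m <- max(oo)
        edge_order[v] <- if (sum(oo == m) >= 2L) m + 1L else m
      }
    }
    ok <- !is.na(parent_edge)
    edges$strahler_order[eidx[parent_edge[ok]]] <- edge_order[ok]
  }
  if (any(drop_edge)) {
    keep <- !drop_edge
    network$polylines <- network$polylines[keep]
    edges <- edges[keep, , drop = FALSE]
    edges$id <- seq_len(nrow(edges))
  }
  network$edges <- edges
  network$nodes <- nodes
  network
}

#' Total channelized network length
#'
#' @param network `channel_network`.
#' @return sum of edge lengths in meters (0 when empty).
#' @export
total_length <- function(network) {
  if (nrow(network$edges) == 0) return(0)
  sum(network$edges$length_m)
}

#' Remove low-order channels
#'
#' Drops every edge whose Strahler order is `removed_max_order` or less;
#' surviving edges keep their original orders (orders are deliberately
#' not recomputed, so successive removals are monotone and comparable).
#'
#' @param network `channel_network` with assigned orders.
#' @param removed_max_order r in 0..5; r = 0 returns the network as is.
#' @return pruned `channel_network`.
#' @export
prune_orders <- function(network, removed_max_order) {
  r <- removed_max_order
  stopifnot(r >= 0, r <= 5)
  if (r == 0) return(network)
  if (nrow(network$edges) > 0 && anyNA(network$edges$strahler_order))
    stop("orders not assigned: run assign_strahler() first")
  keep <- network$edges$strahler_order > r
  network$polylines <- network$polylines[keep]
  network$edges <- network$edges[keep, , drop = FALSE]
  if (nrow(network$edges)) network$edges$id <- seq_len(nrow(network$edges))
  used <- unique(c(network$edges$node_a, network$edges$node_b))
  network$nodes <- network$nodes[network$nodes$id %in% used, , drop = FALSE]
  network
}

#' Rasterize a network's polylines into a channel mask
#'
#' Walks each polyline at quarter-pixel steps and stamps a square of
#' side `width` pixels around every touched cell. Used to re-rasterize
#' pruned networks before metric recomputation and by the synthetic
#' generator (per-order widths).
#'
#' @param network `channel_network`.
#' @param template [raster_grid()] fixing shape, pixel size and origin.
#' @param width either a single width in pixels or a function
#'   (strahler_order) -> width.
#' @param wetland optional AOI raster for the resulting mask.
#' @return [channel_mask()].
#' @export
rasterize_network <- function(network, template, width = 1, wetland = NULL) {
  nr <- nrow(template$values); ncl <- ncol(template$values)
  out <- matrix(0, nr, ncl)
  wfun <- if (is.function(width)) width else function(o) width
  px <- template$pixel_size
  for (i in seq_along(network$polylines)) {
    pl <- network$polylines[[i]]
    w <- max(1L, round(wfun(network$edges$strahler_order[i])))
    lo <- -((w - 1L) %/% 2L); hi <- w %/% 2L
    for (s in seq_len(nrow(pl) - 1L)) {
      p0 <- pl[s, ]; p1 <- pl[s + 1L, ]
      lenpx <- sqrt(sum((p1 - p0)^2)) / px
      nstep <- max(1L, ceiling(lenpx * 4))
      t <- seq(0, 1, length.out = nstep + 1L)
      xs <- p0[1] + t * (p1[1] - p0[1])
      ys <- p0[2] + t * (p1[2] - p0[2])
      rc <- world_to_pixel(template, xs, ys)
      for (dr in lo:hi) for (dc in lo:hi) {
        rr <- rc[, 1] + dr; cc <- rc[, 2] + dc
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncl
        out[cbind(rr[ok], cc[ok])] <- 1
      }
    }
  }
  g <- template; g$values <- out
  channel_mask(g, wetland)
}
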