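# Mode-aware street graph and shortest-path itineraries.
#
# This replaces an external multimodal routing engine with single-criterion
# (distance) shortest paths on mode-filtered subgraphs: the downstream
# features are all distance-based, so per-mode speeds and schedules add
# nothing to the exposure accounting being validated. The substitution is
# deliberate and documented.

#' Default street-class to mode rules
#'
#' Arterials carry motorised and cycle traffic; walking is confined to
#' local streets.
#' @return named list mapping street class to allowed modes
#' @export
default_mode_rules <- function() {
  list(arterial = c("car", "bicycle"), local = c("car", "bicycle", "walk"))
}

#' Build a routable street network
#'
#' Each street polyline becomes one edge between its first and last
#' coordinates, with length equal to the polyline's geometric length.
#' Endpoints are snapped at 1e-6 m; one node is created per distinct
#' coordinate (ids ascending by x, then y, so rebuilding the same streets
#' always yields the same ids).
#'
#' @param streets either a segment data frame with columns \code{x1, y1,
#'   x2, y2, class} (one two-point polyline per row) or a list of polylines,
#'   each a coordinate matrix or a \code{list(coords = , class = )}
#' @param mode_rules named list: street class -> character vector of allowed
#'   modes
#' @return a \code{street_network}: \code{nodes} (node_id, x, y),
#'   \code{edges} (edge_id, from, to, length, class), edge geometries and
#'   \code{rules}
#' @export
build_network <- function(streets, mode_rules = default_mode_rules()) {
  pl <- as_polylines(streets)
  if (!length(pl$geoms))
    rx_stop("empty_network", "cannot build a network from an empty street set")
  unknown <- setdiff(unique(pl$class), names(mode_rules))
  if (length(unknown))
    rx_stop("config", sprintf("no mode rule for street class: %s", paste(unknown, collapse = ", ")))
  snap <- function(v) round(v * 1e6) / 1e6
  geoms <- lapply(pl$geoms, function(m) {
    m[1, ] <- snap(m[1, ]); m[nrow(m), ] <- snap(m[nrow(m), ]); m
  })
  ends <- do.call(rbind, lapply(geoms, function(m) c(m[1, ], m[nrow(m), ])))
  key <- function(x, y) paste(sprintf("%.6f", x), sprintf("%.6f", y), sep = ",")
  allx <- c(ends[, 1], ends[, 3]); ally <- c(ends[, 2], ends[, 4])
  kk <- key(allx, ally)
  first <- !duplicated(kk)
  ux <- allx[first]; uy <- ally[first]; uk <- kk[first]
  ord <- order(ux, uy)
  nodes <- data.frame(node_id = seq_along(ord), x = ux[ord], y = uy[ord])
  lut <- stats::setNames(nodes$node_id, uk[ord])
  from <- unname(lut[key(ends[, 1], ends[, 2])])
  to <- unname(lut[key(ends[, 3], ends[, 4])])
  len <- vapply(geoms, function(m) sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))), 0)
  edges <- data.frame(edge_id = seq_along(from), from = from, to = to,
                      length = len, class = pl$class)
  structure(list(nodes = nodes, edges = edges, geoms = geoms, rules = mode_rules),
            class = "street_network")
}

as_polylines <- function(streets) {
  if (is.data.frame(streets)) {
    if (!nrow(streets)) return(list(geoms = list(), class = character(0)))
    cls <- if (is.null(streets$class)) rep("local", nrow(streets)) else streets$class
    geoms <- lapply(seq_len(nrow(streets)), function(i)
      rbind(c(streets$x1[i], streets$y1[i]), c(streets$x2[i], streets$y2[i])))
    return(list(geoms = geoms, class = cls))
  }
  if (!is.list(streets)) rx_stop("invalid_config", "streets must be a data frame or list of polylines")
  geoms <- lapply(streets, function(s) {
    m <- if (is.list(s) && !is.null(s$coords)) as.matrix(s$coords) else as.matrix(s)
    if (nrow(m) < 2L) rx_stop("geometry", "a polyline needs at least 2 points")
    m
  })
  cls <- vapply(streets, function(s) {
    if (is.list(s) && !is.null(s$class)) s$class
    else attr(s, "class_label") %||% "local"
  }, "")
  list(geoms = geoms, class = cls)
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("street_network: %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$edges$class)), table(x$edges$class)),
                    collapse = ", ")))
  invisible(x)
}

mode_edges <- function(net, mode) {
  allowed <- vapply(net$edges$class, function(cl) mode %in% net$rules[[cl]], TRUE)
  net$edges[allowed, , drop = FALSE]
}

# adjacency list: per node, matrix with columns (to, w, edge_id); undirected
adjacency <- function(edges, n_nodes) {
  adj <- vector("list", n_nodes)
  both <- rbind(
    data.frame(a = edges$from, b = edges$to, w = edges$length, e = edges$edge_id),
    data.frame(a = edges$to, b = edges$from, w = edges$length, e = edges$edge_id)
  )
  sp <- split(both[, c("b", "w", "e")], both$a)
  for (nm in names(sp)) adj[[as.integer(nm)]] <- as.matrix(sp[[nm]])
  adj
}

# Dijkstra from src over an adjacency list, with deterministic tie-breaking:
# among equal-length paths the lexicographically smallest node-id sequence
# wins. Ties are resolved lazily by reconstructing both candidate paths.
dijkstra <- function(adj, n_nodes, src) {
  dist <- rep(Inf, n_nodes); prev <- rep(NA_integer_, n_nodes)
  prev_edge <- rep(NA_integer_, n_nodes)
  done <- rep(FALSE, n_nodes)
  dist[src] <- 0
  path_to <- function(v) {
    p <- integer(0)
    while (!is.na(v)) { p <- c(v, p); v <- prev[v] }
    p
  }
  lex_less <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  for (iter in seq_len(n_nodes)) {
    d <- dist; d[done] <- Inf
    u <- which.min(d)            # first minimum = smallest node id
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]; w <- nb[r, 2]
      nd <- dist[u] + w
      tol <- 1e-9 * (1 + abs(nd))
      if (nd < dist[v] - tol) {
        dist[v] <- nd; prev[v] <- u; prev_edge[v] <- nb[r, 3]
      } else if (abs(nd - dist[v]) <= tol && !is.na(prev[v]) && prev[v] != u) {
        if (lex_less(c(path_to(u), v), path_to(v))) {
          dist[v] <- nd; prev[v] <- u; prev_edge[v] <- nb[r, 3]
        }
      }
    }
  }
  list(dist = dist, prev = prev, prev_edge = prev_edge)
}

nearest_accessible_node <- function(net, edges, pt) {
  ids <- sort(unique(c(edges$from, edges$to)))
  if (!length(ids)) rx_stop("no_route", "mode subgraph has no edges")
  nx <- net$nodes$x[ids]; ny <- net$nodes$y[ids]
  d2 <- (nx - pt[1])^2 + (ny - pt[2])^2
  ids[which.min(d2)]   # ties -> lowest node id (ids sorted)
}

make_itinerary <- function(net, origin, dest, mode, node_path, edge_ids, path_len) {
  no <- node_path[1]; nd <- node_path[length(node_path)]
  c0 <- seg_len(origin, c(net$nodes$x[no], net$nodes$y[no]))
  c1 <- seg_len(c(net$nodes$x[nd], net$nodes$y[nd]), dest)
  # concatenate edge polylines oriented along the node path
  pts <- list(rbind(origin, c(net$nodes$x[no], net$nodes$y[no])))
  for (i in seq_along(edge_ids)) {
    g <- net$geoms[[edge_ids[i]]]
    if (net$edges$from[edge_ids[i]] != node_path[i]) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
    pts[[length(pts) + 1L]] <- g[-1, , drop = FALSE]
  }
  pts[[length(pts) + 1L]] <- matrix(dest, ncol = 2)
  coords <- do.call(rbind, pts)
  structure(list(origin = origin, dest = dest, mode = mode,
                 nodes = node_path, edge_ids = edge_ids,
                 total_distance = c0 + path_len + c1,
                 coords = unname(coords)),
            class = "itinerary")
}

#' Shortest itinerary between two points for one mode
#'
#' Origin and destination are connected by straight access/egress segments
#' to their nearest mode-accessible nodes; between the nodes the
#' minimum-length path on the mode subgraph is used, with equal-length ties
#' broken towards the lexicographically smallest node-id sequence.
#'
#' @param net a \code{street_network}
#' @param origin,dest length-2 coordinates (metres)
#' @param mode one of \code{"car"}, \code{"bicycle"}, \code{"walk"}
#' @return an \code{itinerary}: origin, dest, mode, node path, edge ids,
#'   \code{total_distance} (connectors included) and the polyline coords
#' @export
shortest_itinerary <- function(net, origin, dest, mode) {
  edges <- mode_edges(net, mode)
  no <- nearest_accessible_node(net, edges, origin)
  nd <- nearest_accessible_node(net, edges, dest)
  if (no == nd) return(make_itinerary(net, origin, dest, mode, no, integer(0), 0))
  adj <- adjacency(edges, nrow(net$nodes))
  res <- dijkstra(adj, nrow(net$nodes), no)
  if (!is.finite(res$dist[nd]))
    rx_stop("no_route",
            sprintf("no %s route between (%.1f, %.1f) and (%.1f, %.1f)",
                    mode, origin[1], origin[2], dest[1], dest[2]),
            origin = origin, dest = dest, mode = mode)
  path <- integer(0); eids <- integer(0); v <- nd
  while (!is.na(v)) {
    path <- c(v, path)
    if (!is.na(res$prev_edge[v])) eids <- c(res$prev_edge[v], eids)
    v <- res$prev[v]
  }
  make_itinerary(net, origin, dest, mode, path, eids, res$dist[nd])
}

#' Route a table of OD flows
#'
#' Runs one single-source shortest-path computation per distinct
#' (mode, origin node) pair. Flows with no feasible route in their mode
#' subgraph are dropped and reported, not errored.
#'
#' @param net a \code{street_network}
#' @param flows data frame with \code{origin_x, origin_y, dest_x, dest_y,
#'   mode} (and any extra columns, carried along)
#' @return list with \code{itineraries} (one per routed flow, in flow
#'   order), \code{flow_idx} (row index of each itinerary's flow) and
#'   \code{dropped} (data frame of unroutable flows)
#' @export
route_flows <- function(net, flows) {
  n <- nrow(flows)
  its <- vector("list", n)
  ok <- rep(FALSE, n)
  adj_cache <- list(); edges_cache <- list()
  for (mode in unique(flows$mode)) {
    edges_cache[[mode]] <- mode_edges(net, mode)
    adj_cache[[mode]] <- adjacency(edges_cache[[mode]], nrow(net$nodes))
  }
  src_nodes <- integer(n); dst_nodes <- integer(n)
  for (i in seq_len(n)) {
    e <- edges_cache[[flows$mode[i]]]
    src_nodes[i] <- nearest_accessible_node(net, e, c(flows$origin_x[i], flows$origin_y[i]))
    dst_nodes[i] <- nearest_accessible_node(net, e, c(flows$dest_x[i], flows$dest_y[i]))
  }
  groups <- split(seq_len(n), paste(flows$mode, src_nodes))
  for (g in groups) {
    mode <- flows$mode[g[1]]; src <- src_nodes[g[1]]
    res <- dijkstra(adj_cache[[mode]], nrow(net$nodes), src)
    for (i in g) {
      origin <- c(flows$origin_x[i], flows$origin_y[i])
      dest <- c(flows$dest_x[i], flows$dest_y[i])
      nd <- dst_nodes[i]
      if (nd == src) {
        its[[i]] <- make_itinerary(net, origin, dest, mode, src, integer(0), 0)
        ok[i] <- TRUE
      } else if (is.finite(res$dist[nd])) {
        path <- integer(0); eids <- integer(0); v <- nd
        while (!is.na(v)) {
          path <- c(v, path)
          if (!is.na(res$prev_edge[v])) eids <- c(res$prev_edge[v], eids)
          v <- res$prev[v]
        }
        its[[i]] <- make_itinerary(net, origin, dest, mode, path, eids, res$dist[nd])
        ok[i] <- TRUE
      }
    }
  }
  list(itineraries = its[ok], flow_idx = which(ok),
       dropped = flows[!ok, , drop = FALSE])
}
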