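# Per-trip exposure accounting: intersect routed itineraries with the hex
# grid, summarise the built environment and noise classes along the way,
# then expand flows so each row is one commuter.

#' Traversed length per grid cell for one itinerary
#'
#' Splits every itinerary segment over the hexagons it crosses. Lengths are
#' conserved (their sum equals \code{total_distance} within 1e-6 relative);
#' a piece lying exactly on a shared cell edge counts once, in the lower
#' \code{cell_id}.
#'
#' @param it an \code{itinerary}
#' @param grid a \code{hex_grid}
#' @return named numeric vector, cell_id -> metres traversed
#' @export
intersect_itinerary <- function(it, grid) {
  coords <- it$coords
  lens <- new.env(parent = emptyenv())
  total <- 0
  assigned <- 0
  for (i in seq_len(nrow(coords) - 1L)) {
    p <- coords[i, ]; q <- coords[i + 1L, ]
    L <- seg_len(p, q)
    if (L < 1e-12) next
    total <- total + L
    a <- assign_segment(grid, p, q)
    if (is.null(a)) next
    assigned <- assigned + sum(a$len)
    for (r in seq_len(nrow(a))) {
      id <- as.character(grid$cells$cell_id[a$j[r]])
      lens[[id]] <- (lens[[id]] %||% 0) + a$len[r]
    }
  }
  if (total > 0 && (total - assigned) > 1e-6 * total + 1e-9)
    rx_stop("out_of_extent",
            sprintf("itinerary leaves the grid extent (%.3g m unassigned of %.3g m)",
                    total - assigned, total))
  ids <- sort(as.integer(ls(lens)))
  stats::setNames(vapply(as.character(ids), function(k) lens[[k]], 0), ids)
}

#' Summarise one itinerary into a trip feature record
#'
#' Produces the per-trip feature vector: total distance, unweighted means of
#' building area, street length and per-category POI counts over the
#' distinct cells crossed, and the share of trip distance spent in each
#' noise class. Zero-distance trips take the origin cell's attributes and a
#' share of 1 for its class. With \code{weighted = TRUE} the means are
#' weighted by traversed length instead (sensitivity variant).
#'
#' @param it an \code{itinerary}
#' @param grid a \code{hex_grid} with aggregated attributes and noise
#'   classes
#' @param scheme the grid's \code{noise_scheme}
#' @param weighted length-weighted means instead of unweighted means over
#'   distinct crossed cells
#' @return one-row data frame (origin_cell, dest_cell, mode, distance_m,
#'   mean_building_area_m2, mean_street_length_m, mean_poi_*,
#'   noise_share_*)
#' @export
trip_features <- function(it, grid, scheme, weighted = FALSE) {
  K <- n_classes(scheme)
  share_cols <- noise_share_cols(scheme)
  cats <- grep("^poi_", names(grid$cells), value = TRUE)
  od <- cell_for_points(grid, rbind(it$origin, it$dest))
  rec <- data.frame(origin_cell = od[1], dest_cell = od[2], mode = it$mode,
                    distance_m = it$total_distance)
  if (it$total_distance <= 0) {
    j <- match(od[1], grid$cells$cell_id)
    if (is.na(j)) rx_stop("out_of_extent", "zero-distance trip outside the grid")
    rec$mean_building_area_m2 <- grid$cells$building_area[j]
    rec$mean_street_length_m <- grid$cells$street_length[j]
    for (cc in cats) rec[[sub("^poi_", "mean_poi_", cc)]] <- grid$cells[[cc]][j]
    share <- numeric(K); share[grid$cells$noise_class[j]] <- 1
  } else {
    lens <- intersect_itinerary(it, grid)
    j <- match(as.integer(names(lens)), grid$cells$cell_id)
    wts <- if (weighted) lens / sum(lens) else rep(1 / length(j), length(j))
    rec$mean_building_area_m2 <- sum(wts * grid$cells$building_area[j])
    rec$mean_street_length_m <- sum(wts * grid$cells$street_length[j])
    for (cc in cats) rec[[sub("^poi_", "mean_poi_", cc)]] <- sum(wts * grid$cells[[cc]][j])
    cls <- grid$cells$noise_class[j]
    if (anyNA(cls)) rx_stop("config", "grid has cells without an assigned noise class")
    share <- vapply(seq_len(K), function(k) sum(lens[cls == k]), 0) / sum(lens)
  }
  for (k in seq_len(K)) rec[[share_cols[k]]] <- share[k]
  rec
}

#' Expand flow-level trip records to one row per commuter
#'
#' @param records data frame of trip features with a \code{count} column
#' @return data frame with \code{individual_id} first and one identical
#'   feature row per commuter; row count equals \code{sum(records$count)}
#' @export
expand_flows <- function(records) {
  if (any(records$count < 1)) rx_stop("invalid_config", "counts must be >= 1")
  idx <- rep(seq_len(nrow(records)), times = records$count)
  out <- records[idx, setdiff(names(records), "count"), drop = FALSE]
  out <- cbind(individual_id = seq_along(idx), out)
  rownames(out) <- NULL
  out
}

#' Build the individual-level trip table for a city
#'
#' Convenience wrapper: route the flows, summarise each routed flow with
#' \code{\link{trip_features}}, and expand by commuter count. Unroutable
#' flows are dropped and counted.
#'
#' @param city a \code{synthetic_city}
#' @param grid an aggregated \code{hex_grid} with noise classes
#' @param net a \code{street_network}
#' @param flows OD flow data frame (after suppression)
#' @param weighted passed to \code{\link{trip_features}}
#' @return the expanded trip table; attributes \code{n_flows},
#'   \code{n_routed}, \code{n_dropped}, \code{n_individuals} record the
#'   stage counts
#' @export
build_trip_table <- function(city, grid, net, flows, weighted = FALSE) {
  routed <- route_flows(net, flows)
  recs <- vector("list", length(routed$itineraries))
  for (i in seq_along(routed$itineraries)) {
    r <- trip_features(routed$itineraries[[i]], grid, city$scheme, weighted = weighted)
    r$count <- flows$count[routed$flow_idx[i]]
    recs[[i]] <- r
  }
  tab <- expand_flows(do.call(rbind, recs))
  attr(tab, "n_flows") <- nrow(flows)
  attr(tab, "n_routed") <- length(routed$itineraries)
  attr(tab, "n_dropped") <- nrow(routed$dropped)
  attr(tab, "n_individuals") <- nrow(tab)
  tab
}
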