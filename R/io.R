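# Readers and writers for the pipeline's interchange artifacts: GeoJSON for
# spatial layers (planar metre coordinates, declared via a named CRS
# member), CSV for flow and trip tables, JSON for configs and reports.

RX_CRS <- list(type = "name", properties = list(name = "urn:routexpose:local-metre-plane"))

geojson_fc <- function(features) {
  list(type = "FeatureCollection", crs = RX_CRS, features = features)
}

gj_feature <- function(type, coords, props) {
  list(type = "Feature", geometry = list(type = type, coordinates = coords),
       properties = props)
}

write_gj <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write city layers as GeoJSON
#'
#' @param city a \code{synthetic_city}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_city_geojson <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- city$streets
  write_gj(geojson_fc(lapply(seq_len(nrow(st)), function(i) {
    gj_feature("LineString",
               list(c(st$x1[i], st$y1[i]), c(st$x2[i], st$y2[i])),
               list(edge_id = st$edge_id[i], class = st$class[i]))
  })), file.path(dir, "streets.geojson"))
  write_gj(geojson_fc(lapply(seq_along(city$buildings), function(i) {
    p <- city$buildings[[i]]
    ring <- lapply(seq_len(nrow(p) + 1L), function(j) p[if (j > nrow(p)) 1L else j, ])
    gj_feature("Polygon", list(ring), list(building_id = i))
  })), file.path(dir, "buildings.geojson"))
  po <- city$pois
  write_gj(geojson_fc(lapply(seq_len(nrow(po)), function(i) {
    gj_feature("Point", c(po$x[i], po$y[i]), list(category = po$category[i]))
  })), file.path(dir, "pois.geojson"))
  nz <- city$noise
  write_gj(geojson_fc(lapply(seq_along(nz$polygons), function(i) {
    p <- nz$polygons[[i]]
    ring <- lapply(seq_len(nrow(p) + 1L), function(j) p[if (j > nrow(p)) 1L else j, ])
    gj_feature("Polygon", list(ring), list(noise_class = nz$class[i]))
  })), file.path(dir, "noise.geojson"))
  invisible(dir)
}

read_gj <- function(path) jsonlite::fromJSON(path, simplifyVector = FALSE)

#' Read city layers back from GeoJSON
#'
#' @param dir directory holding \code{streets.geojson},
#'   \code{buildings.geojson}, \code{pois.geojson}, \code{noise.geojson}
#' @return list with \code{streets}, \code{buildings}, \code{pois},
#'   \code{noise}
#' @export
read_city_geojson <- function(dir) {
  st <- read_gj(file.path(dir, "streets.geojson"))$features
  streets <- do.call(rbind, lapply(st, function(f) {
    cc <- f$geometry$coordinates
    data.frame(x1 = cc[[1]][[1]], y1 = cc[[1]][[2]], x2 = cc[[2]][[1]], y2 = cc[[2]][[2]],
               class = f$properties$class, edge_id = f$properties$edge_id)
  }))
  bd <- read_gj(file.path(dir, "buildings.geojson"))$features
  buildings <- lapply(bd, function(f) ring_to_matrix(f$geometry$coordinates[[1]]))
  po <- read_gj(file.path(dir, "pois.geojson"))$features
  pois <- if (length(po)) do.call(rbind, lapply(po, function(f) {
    data.frame(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]],
               category = f$properties$category)
  })) else data.frame(x = numeric(0), y = numeric(0), category = character(0))
  nz <- read_gj(file.path(dir, "noise.geojson"))$features
  noise <- list(polygons = lapply(nz, function(f) ring_to_matrix(f$geometry$coordinates[[1]])),
                class = vapply(nz, function(f) as.integer(f$properties$noise_class), 1L))
  list(streets = streets, buildings = buildings, pois = pois, noise = noise)
}

ring_to_matrix <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Write/read OD flows as CSV
#'
#' Columns: origin_x, origin_y, dest_x, dest_y, mode, count.
#' @param flows flow data frame
#' @param path CSV path
#' @return \code{read_flows_csv} returns the data frame
#' @export
write_flows_csv <- function(flows, path) {
  utils::write.csv(flows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flows_csv
#' @export
read_flows_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the trip table
#'
#' CSV always; \code{format = "parquet"} additionally requires the
#' \pkg{arrow} package.
#' @param trips trip table
#' @param path output path
#' @param format \code{"csv"} or \code{"parquet"}
#' @return the path, invisibly
#' @export
write_trip_table <- function(trips, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(trips, path, row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      rx_stop("config", "parquet output requires the arrow package")
    arrow::write_parquet(trips, path)
  }
  invisible(path)
}

#' @rdname write_trip_table
#' @export
read_trip_table <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else {
    if (!requireNamespace("arrow", quietly = TRUE))
      rx_stop("config", "parquet input requires the arrow package")
    as.data.frame(arrow::read_parquet(path))
  }
}

#' Persist a hex grid with its attributes
#'
#' \code{write_grid} stores full numeric fidelity as JSON (plus a GeoJSON
#' twin for interop); \code{read_grid} reconstructs the \code{hex_grid},
#' recomputing cell polygons from the axial coordinates.
#'
#' @param grid a \code{hex_grid}
#' @param path JSON path (the GeoJSON twin replaces the extension)
#' @return \code{read_grid} returns the \code{hex_grid}
#' @export
write_grid <- function(grid, path) {
  jsonlite::write_json(list(s = grid$s, cell_area = grid$cell_area, bbox = grid$bbox,
                            scheme_name = grid$scheme_name %||% NA,
                            cells = grid$cells),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  gj <- file.path(dirname(path), sub("\\.json$", ".geojson", basename(path)))
  feats <- lapply(seq_len(nrow(grid$cells)), function(j) {
    p <- grid$polys[[j]]
    ring <- lapply(seq_len(nrow(p) + 1L), function(i) p[if (i > nrow(p)) 1L else i, ])
    gj_feature("Polygon", list(ring), as.list(grid$cells[j, , drop = FALSE]))
  })
  write_gj(geojson_fc(feats), gj)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  x <- jsonlite::fromJSON(path)
  grid <- make_grid(as.numeric(x$bbox), cell_area = as.numeric(x$cell_area))
  cells <- as.data.frame(x$cells)
  key_in <- paste(cells$q, cells$r, sep = ":")
  idx <- match(grid$key, key_in)
  if (anyNA(idx)) rx_stop("config", "stored grid does not match its parameters")
  for (cl in setdiff(names(cells), names(grid$cells))) grid$cells[[cl]] <- cells[[cl]][idx]
  grid$cells$building_area <- cells$building_area[idx]
  grid$cells$street_length <- cells$street_length[idx]
  grid$cells$noise_class <- as.integer(cells$noise_class[idx])
  if (!is.null(x$scheme_name) && !is.na(x$scheme_name)) grid$scheme_name <- x$scheme_name
  grid
}

#' Export itineraries as GeoJSON LineStrings
#'
#' @param itineraries list of \code{itinerary} objects
#' @param path output path
#' @param extra optional data frame of per-itinerary properties
#' @return the path, invisibly
#' @export
write_itineraries_geojson <- function(itineraries, path, extra = NULL) {
  feats <- lapply(seq_along(itineraries), function(i) {
    it <- itineraries[[i]]
    props <- list(mode = it$mode, total_distance = it$total_distance)
    if (!is.null(extra)) props <- c(props, as.list(extra[i, , drop = FALSE]))
    gj_feature("LineString",
               lapply(seq_len(nrow(it$coords)), function(j) it$coords[j, ]),
               props)
  })
  write_gj(geojson_fc(feats), path)
  invisible(path)
}

#' @rdname write_itineraries_geojson
#' @export
read_itineraries_geojson <- function(path) {
  feats <- read_gj(path)$features
  its <- lapply(feats, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, function(pt) c(pt[[1]], pt[[2]])))
    structure(list(origin = coords[1, ], dest = coords[nrow(coords), ],
                   mode = f$properties$mode,
                   total_distance = f$properties$total_distance,
                   coords = coords),
              class = "itinerary")
  })
  extra_names <- setdiff(names(feats[[1]]$properties), c("mode", "total_distance"))
  extra <- if (length(extra_names)) {
    do.call(rbind, lapply(feats, function(f) as.data.frame(f$properties[extra_names])))
  } else NULL
  list(itineraries = its, extra = extra)
}
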