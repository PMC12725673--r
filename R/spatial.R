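#' Fishing-ground polygons
#'
#' Fishing grounds are stored as a tibble with one row per fisher x
#' decade: `fisher_id`, `decade`, `port_id`, a `geometry` list column of
#' two-column lon/lat matrices (outer ring, closed or open), and
#' optionally a `vcc` value attached from the trajectory engine. All
#' coordinates are WGS84 (EPSG:4326) degrees.
#'
#' `read_grounds_geojson()` reads a GeoJSON FeatureCollection of Polygon
#' features carrying `fisher_id`, `decade` and `port_id` properties
#' (only the outer ring of each polygon is used);
#' `write_grounds_geojson()` writes one back.
#'
#' @param path path to a `.geojson` file.
#' @return Tibble of fishing grounds as described above.
#' @export
read_grounds_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  rows <- purrr::map(gj$features, function(f) {
    if (f$geometry$type != "Polygon") {
      stop("only Polygon features are supported (got ", f$geometry$type, ")",
           call. = FALSE)
    }
    ring <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]],
                                      ~ as.numeric(unlist(.x))))
    p <- f$properties
    tibble::tibble(
      fisher_id = as.character(p$fisher_id),
      decade = as.character(p$decade),
      port_id = as.character(p$port_id),
      vcc = if (is.null(p$vcc)) NA_real_ else as.numeric(p$vcc),
      geometry = list(ring)
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_grounds(out)
  out
}

#' @rdname read_grounds_geojson
#' @param grounds fishing-ground tibble.
#' @export
write_grounds_geojson <- function(grounds, path) {
  features <- purrr::pmap(
    list(grounds$fisher_id, grounds$decade, grounds$port_id,
         if ("vcc" %in% names(grounds)) grounds$vcc else
           rep(NA_real_, nrow(grounds)),
         grounds$geometry),
    function(fid, dec, pid, vcc, ring) {
      ring <- close_ring(ring)
      props <- list(fisher_id = fid, decade = dec, port_id = pid)
      if (!is.na(vcc)) props$vcc <- vcc
      list(
        type = "Feature",
        properties = props,
        geometry = list(
          type = "Polygon",
          coordinates = list(unname(apply(ring, 1, as.list, simplify = FALSE)))
        )
      )
    }
  )
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

validate_grounds <- function(grounds) {
  for (i in seq_len(nrow(grounds))) {
    ring <- grounds$geometry[[i]]
    if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
      stop("ground ", i, " (fisher ", grounds$fisher_id[i],
           "): geometry must be an n x 2 lon/lat matrix with n >= 3",
           call. = FALSE)
    }
    if (any(abs(ring[, 1]) > 180) || any(abs(ring[, 2]) > 90)) {
      stop("ground ", i, " (fisher ", grounds$fisher_id[i],
           "): coordinates outside WGS84 bounds", call. = FALSE)
    }
  }
  invisible(grounds)
}

close_ring <- function(ring) {
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
    ring <- rbind(ring, ring[1, ])
  }
  ring
}

open_ring <- function(ring) {
  if (isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  ring
}

#' Read a port registry
#'
#' Ports of origin, one point per village landing site: CSV with columns
#' `port_id`, `name`, `lon`, `lat` (degrees WGS84).
#'
#' @param path path to a CSV file.
#' @return Tibble `(port_id, name, lon, lat)`.
#' @export
read_ports <- function(path) {
  ports <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("port_id", "name", "lon", "lat") %in% names(ports)))
  if (any(abs(ports$lon) > 180) || any(abs(ports$lat) > 90)) {
    stop("port coordinates outside WGS84 bounds", call. = FALSE)
  }
  ports$port_id <- as.character(ports$port_id)
  ports
}

#' Rasterize fishing effort
#'
#' Deposits each polygon onto the grid with weight 1 (or the supplied
#' weight): a cell accrues the weight of every polygon whose interior
#' contains its center. Cell membership is by cell-center containment,
#' not fractional overlap -- the usual raster semantics at 0.01 degrees,
#' and one that admits an exact point-in-polygon oracle. Containment is
#' evaluated with `sp::point.in.polygon` (ray casting); points on an edge
#' or vertex count as inside.
#'
#' @param grounds fishing-ground tibble.
#' @param spec a [grid_spec()]; defaults to [grid_covering()] of the
#'   grounds.
#' @param weights optional numeric vector, one weight per ground
#'   (defaults to all 1 = effort counting).
#' @param kind surface kind label, default `"effort"`.
#' @return Unnormalized `grid_surface` of per-cell sums.
#' @export
rasterize_effort <- function(grounds, spec = grid_covering(grounds),
                             weights = NULL, kind = "effort") {
  validate_grounds(grounds)
  if (is.null(weights)) weights <- rep(1, nrow(grounds))
  stopifnot(length(weights) == nrow(grounds))
  cx <- cell_centers_x(spec)
  cy <- cell_centers_y(spec)
  values <- matrix(0, nrow = spec$nrow, ncol = spec$ncol)
  for (i in seq_len(nrow(grounds))) {
    ring <- open_ring(grounds$geometry[[i]])
    if (min(ring[, 1]) < spec$xmin || max(ring[, 1]) > spec$xmax ||
        min(ring[, 2]) < spec$ymin || max(ring[, 2]) > spec$ymax) {
      stop("polygon outside grid extent (fisher ", grounds$fisher_id[i],
           ", decade ", grounds$decade[i], ")", call. = FALSE)
    }
    # restrict the containment test to the polygon's bounding cells
    ci <- which(cx >= min(ring[, 1]) - spec$cellsize &
                  cx <= max(ring[, 1]) + spec$cellsize)
    rj <- which(cy >= min(ring[, 2]) - spec$cellsize &
                  cy <= max(ring[, 2]) + spec$cellsize)
    if (length(ci) == 0 || length(rj) == 0) next
    px <- rep(cx[ci], times = length(rj))
    py <- rep(cy[rj], each = length(ci))
    inside <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
    if (any(inside)) {
      idx <- cbind(rep(rj, each = length(ci))[inside],
                   rep(ci, times = length(rj))[inside])
      values[idx] <- values[idx] + weights[i]
    }
  }
  new_grid_surface(values, spec, kind)
}

#' Decadal VCC surface
#'
#' Replaces each polygon's unit effort weight with its virtual-catch-change
#' value and deposits additively, then rescales symmetrically onto
#' \[-4, 4\] (sign-preserving; see [normalize_surface()]). The result maps
#' where fishers perceive catches to have gained or lost relative to their
#' baselines in a given decade.
#'
#' @param grounds fishing-ground tibble with a `vcc` column (attach it by
#'   joining [vcc_trajectories()] output on `fisher_id` + `decade`).
#' @param spec a [grid_spec()]; defaults to covering the selected grounds.
#' @param decade optional decade label to subset to.
#' @param normalize apply `symmetric4` normalization, default `TRUE`.
#' @return A `grid_surface` of kind `"vcc"`.
#' @export
vcc_surface <- function(grounds, spec = NULL, decade = NULL,
                        normalize = TRUE) {
  if (!is.null(decade)) {
    check_decade(decade)
    grounds <- dplyr::filter(grounds, .data$decade == !!decade)
  }
  if (nrow(grounds) == 0) stop("no grounds to rasterize", call. = FALSE)
  if (!"vcc" %in% names(grounds) || anyNA(grounds$vcc)) {
    bad <- if ("vcc" %in% names(grounds)) {
      grounds$fisher_id[is.na(grounds$vcc)]
    } else grounds$fisher_id
    stop("ground(s) missing a vcc value: fisher ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(spec)) spec <- grid_covering(grounds)
  surf <- rasterize_effort(grounds, spec, weights = grounds$vcc,
                           kind = "vcc")
  if (normalize) normalize_surface(surf, "symmetric4") else surf
}

#' Planar polygon centroid
#'
#' Area-weighted (shoelace) centroid computed in degree space. At the
#' near-equatorial latitudes these fisheries occupy, the difference from
#' a projected centroid is negligible for polygons up to a couple of
#' degrees across (checked in the test-suite against a locally scaled
#' planar projection).
#'
#' @param ring two-column lon/lat matrix (open or closed ring).
#' @return Named numeric `c(lon = , lat = )`.
#' @export
poly_centroid <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  area2 <- sum(cross)
  if (abs(area2) < 1e-14) {
    stop("degenerate (zero-area) polygon", call. = FALSE)
  }
  c(lon = sum((x[-n] + x[-1]) * cross) / (3 * area2),
    lat = sum((y[-n] + y[-1]) * cross) / (3 * area2))
}

#' Geodesic distance to port
#'
#' WGS84-ellipsoid distance in kilometers from points (typically polygon
#' centroids) to their port of origin, via `geosphere::distGeo`. With a
#' `coast` polyline supplied, distances are instead measured to the
#' nearest point of the line (`geosphere::dist2Line`), for workflows that
#' define "distance from home" as distance to the coastline rather than
#' to the port point; the point-to-port reading is the default.
#'
#' @param points two-column lon/lat matrix (or length-2 vector).
#' @param ports two-column lon/lat matrix recycled against `points` (or a
#'   length-2 vector).
#' @param coast optional two-column lon/lat matrix of coastline vertices;
#'   when given, `ports` is ignored.
#' @return Numeric vector of distances in km.
#' @examples
#' distance_to_port(c(0, 0), c(1, 0))  # ~111.32 km along the equator
#' @export
distance_to_port <- function(points, ports = NULL, coast = NULL) {
  points <- rbind_coords(points)
  if (any(abs(points[, 1]) > 180) || any(abs(points[, 2]) > 90)) {
    stop("coordinates outside WGS84 bounds", call. = FALSE)
  }
  if (!is.null(coast)) {
    return(unname(geosphere::dist2Line(points,
                                       rbind_coords(coast))[, "distance"]) / 1000)
  }
  if (is.null(ports)) stop("supply `ports` or `coast`", call. = FALSE)
  ports <- rbind_coords(ports)
  if (any(abs(ports[, 1]) > 180) || any(abs(ports[, 2]) > 90)) {
    stop("coordinates outside WGS84 bounds", call. = FALSE)
  }
  if (nrow(ports) == 1) ports <- ports[rep(1, nrow(points)), , drop = FALSE]
  geosphere::distGeo(points, ports) / 1000
}

rbind_coords <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 2)
}

#' Decadal centroid-to-port distance summary
#'
#' Computes each ground's centroid-to-port geodesic distance and
#' summarises mean and median kilometers per decade (and per village when
#' the port registry carries names), plus the overall mean across all
#' grounds.
#'
#' @param grounds fishing-ground tibble.
#' @param ports port registry tibble (`port_id`, `name`, `lon`, `lat`).
#' @param by grouping columns for the summary, default `"decade"`; use
#'   `c("name", "decade")` for per-village tables.
#' @return List with `distances` (per-ground tibble with `distance_km`),
#'   `summary` (grouped `(by..., n, mean_km, median_km)`) and
#'   `overall_mean_km`.
#' @export
decadal_distance_summary <- function(grounds, ports, by = "decade") {
  unknown <- setdiff(unique(grounds$port_id), ports$port_id)
  if (length(unknown) > 0) {
    stop("unknown port_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cents <- t(vapply(grounds$geometry, poly_centroid, numeric(2)))
  pidx <- match(grounds$port_id, ports$port_id)
  dist_km <- distance_to_port(cents,
                              cbind(ports$lon, ports$lat)[pidx, , drop = FALSE])
  distances <- grounds |>
    dplyr::mutate(
      name = ports$name[pidx],
      centroid_lon = cents[, 1],
      centroid_lat = cents[, 2],
      distance_km = dist_km
    ) |>
    dplyr::select(-"geometry")
  summary <- distances |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_km = mean(.data$distance_km),
      median_km = stats::median(.data$distance_km),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  list(distances = distances, summary = summary,
       overall_mean_km = mean(dist_km))
}
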