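#' Regular lon/lat grid specification
#'
#' Defines the raster geometry used for effort and VCC surfaces: a
#' cell-center-registered grid of square cells (in degrees) anchored at a
#' lower-left corner. Column `i` runs west to east, row `j` north to
#' south (row 1 is the northern edge), matching the row order of the
#' ASCII grid writer. Cell centers sit at
#' `xmin + (i - 0.5) * cellsize`, `ymax - (j - 0.5) * cellsize`.
#'
#' @param xmin,ymin lower-left corner, degrees WGS84.
#' @param ncol,nrow grid dimensions.
#' @param cellsize cell edge in degrees, default `0.01`.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymin, ncol, nrow, cellsize = 0.01) {
  stopifnot(cellsize > 0, ncol >= 1, nrow >= 1)
  structure(
    list(xmin = xmin, ymin = ymin, ncol = as.integer(ncol),
         nrow = as.integer(nrow), cellsize = cellsize,
         xmax = xmin + ncol * cellsize, ymax = ymin + nrow * cellsize),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows at %g deg, x [%g, %g], y [%g, %g]\n",
              x$ncol, x$nrow, x$cellsize, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

cell_centers_x <- function(spec) spec$xmin + (seq_len(spec$ncol) - 0.5) * spec$cellsize
cell_centers_y <- function(spec) spec$ymax - (seq_len(spec$nrow) - 0.5) * spec$cellsize

#' Grid covering a set of fishing grounds
#'
#' Builds a [grid_spec()] whose extent covers every polygon in `grounds`,
#' snapped outward to whole cells from the padded bounding box.
#'
#' @param grounds fishing-ground tibble (see [read_grounds_geojson()]).
#' @param cellsize cell edge in degrees, default `0.01`.
#' @param pad margin added on every side, in degrees, default one cell.
#' @return A `grid_spec`.
#' @export
grid_covering <- function(grounds, cellsize = 0.01, pad = cellsize) {
  xs <- unlist(lapply(grounds$geometry, function(m) m[, 1]))
  ys <- unlist(lapply(grounds$geometry, function(m) m[, 2]))
  xmin <- floor((min(xs) - pad) / cellsize) * cellsize
  ymin <- floor((min(ys) - pad) / cellsize) * cellsize
  ncol <- ceiling((max(xs) + pad - xmin) / cellsize)
  nrow <- ceiling((max(ys) + pad - ymin) / cellsize)
  grid_spec(xmin, ymin, ncol, nrow, cellsize)
}

new_grid_surface <- function(values, spec, kind, normalization = "none",
                             all_zero = FALSE) {
  stopifnot(nrow(values) == spec$nrow, ncol(values) == spec$ncol)
  structure(
    list(values = values, spec = spec, kind = kind,
         normalization = normalization, all_zero = all_zero),
    class = "grid_surface"
  )
}

#' @export
print.grid_surface <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("grid_surface (%s, normalization = %s): %d x %d cells, values [%g, %g]\n",
              x$kind, x$normalization, x$spec$nrow, x$spec$ncol,
              rng[1], rng[2]))
  invisible(x)
}

#' Normalize a grid surface
#'
#' * `unit`: divides by the maximum, mapping counts onto \[0, 1\] with the
#'   busiest cell exactly 1 (used for effort / spatial-overlap surfaces).
#' * `symmetric4`: multiplies by `4 / max(|values|)`, mapping onto
#'   \[-4, 4\] while preserving sign and zero, so a cell with no net
#'   perceived change stays at 0 (used for VCC surfaces).
#' * `affine4`: min--max affine map of \[min, max\] onto \[-4, 4\];
#'   provided as an alternative reading of a -4..4 scale, but it does not
#'   preserve zero and is not the default.
#'
#' All modes are idempotent. An all-zero surface is returned unchanged
#' with a warning and its `all_zero` flag set.
#'
#' @param surface a `grid_surface`.
#' @param mode `"unit"`, `"symmetric4"` or `"affine4"`.
#' @return A normalized `grid_surface`.
#' @export
normalize_surface <- function(surface, mode = c("unit", "symmetric4",
                                                "affine4")) {
  mode <- match.arg(mode)
  v <- surface$values
  if (all(v == 0)) {
    warning("all-zero surface: normalization is a no-op", call. = FALSE)
    surface$all_zero <- TRUE
    surface$normalization <- mode
    return(surface)
  }
  out <- switch(mode,
    unit = v / max(v),
    symmetric4 = v * (4 / max(abs(v))),
    affine4 = {
      lo <- min(v); hi <- max(v)
      if (hi == lo) v * 0 else -4 + 8 * (v - lo) / (hi - lo)
    }
  )
  new_grid_surface(out, surface$spec, surface$kind, normalization = mode)
}

#' Core fishing-ground cells
#'
#' Identifies the cells of a unit-normalized effort surface whose value
#' meets the core threshold: by default 0.6, i.e. cells where at least
#' 60% of the maximum number of overlapping fisher polygons operate.
#'
#' @param surface a `grid_surface`; normalized to `unit` automatically if
#'   it is not already.
#' @param threshold fraction in (0, 1\], default `0.6`.
#' @return Tibble `(x, y, value)` of core cell centers.
#' @export
core_grounds <- function(surface, threshold = 0.6) {
  if (surface$normalization != "unit") {
    surface <- normalize_surface(surface, "unit")
  }
  dplyr::filter(as_tibble.grid_surface(surface), .data$value >= threshold)
}

#' Tabulate a grid surface
#'
#' @param x a `grid_surface`.
#' @param ... unused.
#' @return Tibble `(x, y, value)` of cell centers, row-major from the
#'   north-west corner.
#' @method as_tibble grid_surface
#' @export
as_tibble.grid_surface <- function(x, ...) {
  cx <- cell_centers_x(x$spec)
  cy <- cell_centers_y(x$spec)
  vals <- as.vector(t(x$values))
  tibble::tibble(
    x = rep(cx, times = length(cy)),
    y = rep(cy, each = length(cx)),
    value = vals
  )
}

#' Write a grid surface as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster: header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value -9999`) followed by rows from
#' north to south. The format is lossless for the full-precision writer
#' used here and readable by any GIS.
#'
#' @param surface a `grid_surface`.
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path) {
  spec <- surface$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", spec$ncol),
    paste("nrows", spec$nrow),
    paste("xllcorner", format(spec$xmin, digits = 15)),
    paste("yllcorner", format(spec$ymin, digits = 15)),
    paste("cellsize", format(spec$cellsize, digits = 15)),
    "NODATA_value -9999"
  ), con)
  for (j in seq_len(spec$nrow)) {
    writeLines(paste(format(surface$values[j, ], digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file written by [write_ascii_grid()] (or
#'   any conforming writer).
#' @param kind surface kind label to attach, default `"effort"`.
#' @return A `grid_surface` (normalization metadata is not stored in the
#'   format and is reported as `"none"`).
#' @export
read_ascii_grid <- function(path, kind = "effort") {
  lines <- readLines(path)
  hdr <- lapply(strsplit(trimws(lines[1:6]), "\\s+"), identity)
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  h <- stats::setNames(vals, keys)
  spec <- grid_spec(h[["xllcorner"]], h[["yllcorner"]],
                    h[["ncols"]], h[["nrows"]], h[["cellsize"]])
  vv <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  vv[vv == -9999] <- NA_real_
  new_grid_surface(vv, spec, kind)
}
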