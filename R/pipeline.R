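#' Run the full reconstruction pipeline
#'
#' Orchestrates the stages end to end: read and validate interviews,
#' apply the consent/experience filter, build fisher-level virtual catch
#' trajectories (with cohort-mean shifting-baseline anchoring by
#' default), aggregate them per decade, tabulate relative changes, fit
#' the cubic trend, and -- when polygons and a port registry are supplied
#' -- rasterize effort and per-decade VCC surfaces and summarise
#' centroid-to-port distances. A manifest records parameters, per-stage
#' row counts and input digests so a run can be reproduced and audited.
#'
#' Inputs may be file paths (CSV/GeoJSON, read with the package readers)
#' or the corresponding in-memory tibbles.
#'
#' @param interviews interview table: path or tibble
#'   (see [read_interviews()]).
#' @param grounds optional fishing grounds: path or tibble
#'   (see [read_grounds_geojson()]).
#' @param ports optional port registry: path or tibble
#'   (see [read_ports()]); required with `grounds`.
#' @param min_experience experience threshold, default 5 years.
#' @param baseline `"cohort"` (shifting-baseline correction, default) or
#'   `"naive"` (every fisher anchored at 1).
#' @param pooling `"fisher"` (default: per-fisher mean signed fraction
#'   across species) or `"species"` (pool species-level trajectories) for
#'   the overall aggregate.
#' @param cellsize raster resolution in degrees, default `0.01`.
#' @param core_threshold core-ground threshold on the unit-normalized
#'   effort surface, default `0.6`.
#' @param impute optional score-midpoint imputation for missing
#'   percentages (see [signed_fraction()]); off by default.
#' @return List of class `vcc_run`: `interviews` (retained),
#'   `trajectories`, `aggregate`, `relative_changes`, `trend`, and, when
#'   spatial inputs were given, `effort`, `effort_by_decade`,
#'   `vcc_surfaces`, `core`, `distances`; plus `manifest`.
#' @export
run_pipeline <- function(interviews, grounds = NULL, ports = NULL,
                         min_experience = 5,
                         baseline = c("cohort", "naive"),
                         pooling = c("fisher", "species"),
                         cellsize = 0.01, core_threshold = 0.6,
                         impute = NULL) {
  baseline <- match.arg(baseline)
  pooling <- match.arg(pooling)
  manifest <- list(parameters = list(
    min_experience = min_experience, baseline = baseline,
    pooling = pooling, cellsize = cellsize,
    core_threshold = core_threshold,
    impute = !is.null(impute)
  ))
  digests <- list()
  if (is.character(interviews)) {
    digests$interviews <- unname(tools::md5sum(interviews))
    interviews <- read_interviews(interviews)
  }
  if (is.character(grounds)) {
    digests$grounds <- unname(tools::md5sum(grounds))
    grounds <- read_grounds_geojson(grounds)
  }
  if (is.character(ports)) {
    digests$ports <- unname(tools::md5sum(ports))
    ports <- read_ports(ports)
  }
  if (!is.null(grounds) && is.null(ports)) {
    stop("`ports` is required when `grounds` are supplied", call. = FALSE)
  }
  manifest$input_digests <- digests
  manifest$counts <- list(contacted = nrow(interviews))

  retained <- filter_eligible(interviews, min_experience)
  manifest$counts$removed <- as.list(attr(retained, "removed"))
  manifest$counts$retained <- nrow(retained)

  long <- unnest_responses(retained)
  resp <- if (pooling == "fisher") {
    fisher_overall_responses(long, impute = impute)
  } else {
    dplyr::mutate(long, fraction = signed_fraction(.data$score,
                                                   .data$perceived_pct,
                                                   impute))
  }
  traj <- vcc_trajectories(
    resp, by = if (pooling == "species") "species" else NULL,
    baseline = baseline)
  agg <- vcc_aggregate(traj)
  manifest$counts$trajectories <- dplyr::n_distinct(traj$fisher_id)

  out <- list(
    interviews = retained,
    trajectories = traj,
    aggregate = agg,
    relative_changes = vcc_relative_changes(agg),
    trend = fit_decadal_trend(agg),
    drivers = driver_frequency(retained)
  )

  if (!is.null(grounds)) {
    keep <- grounds$fisher_id %in% retained$fisher_id
    grounds <- grounds[keep, , drop = FALSE]
    spec <- grid_covering(grounds, cellsize = cellsize)
    effort <- rasterize_effort(grounds, spec)
    vcc_vals <- traj |>
      dplyr::group_by(.data$fisher_id, .data$decade) |>
      dplyr::summarise(vcc = mean(.data$vcc), .groups = "drop")
    grounds_v <- grounds |>
      dplyr::select(-dplyr::any_of("vcc")) |>
      dplyr::inner_join(vcc_vals, by = c("fisher_id", "decade"))
    out$effort <- normalize_surface(effort, "unit")
    out$effort_by_decade <- lapply(
      stats::setNames(nm = intersect(vcc_decades(), unique(grounds$decade))),
      function(d) {
        normalize_surface(
          rasterize_effort(grounds[grounds$decade == d, , drop = FALSE],
                           spec), "unit")
      })
    out$vcc_surfaces <- lapply(
      stats::setNames(nm = intersect(vcc_decades(),
                                     unique(grounds_v$decade))),
      function(d) vcc_surface(grounds_v, spec, decade = d))
    out$core <- core_grounds(out$effort, core_threshold)
    out$distances <- decadal_distance_summary(grounds, ports)
    manifest$counts$grounds <- nrow(grounds)
    manifest$grid <- list(ncol = spec$ncol, nrow = spec$nrow,
                          cellsize = spec$cellsize)
  }

  out$manifest <- manifest
  class(out) <- "vcc_run"
  out
}

#' @export
print.vcc_run <- function(x, ...) {
  cat("VCC reconstruction run\n")
  cat("  retained interviews:", x$manifest$counts$retained, "of",
      x$manifest$counts$contacted, "contacted\n")
  cat("  decadal means:",
      paste(sprintf("%s=%.3f", x$aggregate$decade, x$aggregate$mean),
            collapse = ", "), "\n")
  if (!is.null(x$distances)) {
    s <- x$distances$summary
    cat("  mean distance to port (km):",
        paste(sprintf("%s=%.1f", s$decade, s$mean_km), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export a run's tables, fits and rasters
#'
#' Writes the standard file bundle for a completed [run_pipeline()] run:
#' trajectory and aggregate CSVs, the relative-change table, the driver
#' ranking, trend-fit coefficients as JSON, distance summaries, ESRI
#' ASCII rasters for the effort surface and each decadal VCC surface, and
#' a `manifest.json` listing every written file with its md5 digest.
#'
#' @param run a `vcc_run` object.
#' @param dir output directory (created if missing).
#' @return Tibble `(file, md5)` of written outputs, invisibly.
#' @export
export_summary <- function(run, dir) {
  stopifnot(inherits(run, "vcc_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(rel, writer) {
    path <- file.path(dir, rel)
    writer(path)
    written <<- c(written, path)
  }
  put("trajectories.csv",
      function(p) readr::write_csv(run$trajectories, p))
  put("decadal_aggregate.csv",
      function(p) readr::write_csv(tibble::as_tibble(run$aggregate), p))
  put("relative_changes.csv",
      function(p) readr::write_csv(run$relative_changes, p))
  put("driver_ranking.csv", function(p) readr::write_csv(run$drivers, p))
  put("trend_fit.json", function(p) {
    jsonlite::write_json(
      list(coefficients = as.list(coef(run$trend)),
           points = run$trend$points),
      p, auto_unbox = TRUE, digits = NA)
  })
  if (!is.null(run$effort)) {
    put("effort_surface.asc",
        function(p) write_ascii_grid(run$effort, p))
    for (d in names(run$vcc_surfaces)) {
      local({
        dd <- d
        put(sprintf("vcc_surface_%s.asc", dd),
            function(p) write_ascii_grid(run$vcc_surfaces[[dd]], p))
      })
    }
    put("distance_summary.csv",
        function(p) readr::write_csv(run$distances$summary, p))
    put("core_grounds.csv", function(p) readr::write_csv(run$core, p))
  }
  files <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  jsonlite::write_json(
    list(parameters = run$manifest$parameters,
         counts = run$manifest$counts,
         files = files),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(files)
}
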