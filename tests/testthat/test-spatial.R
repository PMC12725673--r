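square <- function(x0, y0, side = 1) {
  cbind(lon = x0 + c(0, side, side, 0), lat = y0 + c(0, 0, side, side))
}

mk_grounds <- function(geoms, decade = "1980s", port = "p1") {
  tibble::tibble(
    fisher_id = sprintf("f%02d", seq_along(geoms)),
    decade = decade, port_id = port, geometry = geoms
  )
}

test_that("planar centroid matches closed forms and the shoelace oracle", {
  expect_equal(poly_centroid(square(0, 0)), c(lon = 0.5, lat = 0.5))
  tri <- cbind(lon = c(0, 1, 0), lat = c(0, 0, 1))
  expect_equal(poly_centroid(tri), c(lon = 1 / 3, lat = 1 / 3))

  # irregular polygon vs Monte-Carlo integration with an independent
  # point-in-polygon test
  set.seed(8)
  ring <- random_convex_ring(c(-81, -1), 0.8)
  cen <- poly_centroid(ring)
  px <- stats::runif(40000, min(ring[, 1]), max(ring[, 1]))
  py <- stats::runif(40000, min(ring[, 2]), max(ring[, 2]))
  inside <- oracle_point_in_polygon(px, py, ring)
  expect_equal(unname(cen),
               c(mean(px[inside]), mean(py[inside])), tolerance = 0.01)

  expect_error(poly_centroid(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("planar degree-space centroid is adequate at study latitudes", {
  # compare with a centroid computed in a locally scaled (equirectangular)
  # projection for a 2-degree polygon near the equator
  set.seed(9)
  ring <- random_convex_ring(c(-81, -1.5), 1.0)
  cen <- poly_centroid(ring)
  lat0 <- mean(ring[, 2])
  proj <- cbind(ring[, 1] * cospi(lat0 / 180), ring[, 2])
  cen_proj <- poly_centroid(proj)
  cen_back <- c(cen_proj[1] / cospi(lat0 / 180), cen_proj[2])
  size <- max(diff(range(ring[, 1])), diff(range(ring[, 2])))
  expect_lt(sqrt(sum((unname(cen) - cen_back)^2)) / size, 0.001)
})

test_that("effort rasterization matches the brute-force cell-center oracle", {
  set.seed(21)
  spec <- grid_spec(-82, -2, ncol = 50, nrow = 50, cellsize = 0.02)
  geoms <- lapply(1:25, function(i) {
    random_convex_ring(c(stats::runif(1, -81.8, -81.2),
                         stats::runif(1, -1.8, -1.2)), 0.15)
  })
  grounds <- mk_grounds(geoms)
  surf <- rasterize_effort(grounds, spec)
  expect_equal(surf$values, oracle_effort_raster(grounds, spec))
  # and against mgcv's independent in/out routine on the busiest polygon
  cx <- rep(spec$xmin + (1:50 - 0.5) * 0.02, times = 50)
  cy <- rep(spec$ymax - (1:50 - 0.5) * 0.02, each = 50)
  ring_c <- rbind(geoms[[1]], geoms[[1]][1, ])
  io <- mgcv::in.out(ring_c, cbind(cx, cy))
  one <- rasterize_effort(grounds[1, ], spec)
  expect_equal(as.vector(t(one$values)) > 0, io)
})

test_that("rasterization is additive and permutation-invariant", {
  spec <- grid_spec(0, 0, 10, 10, cellsize = 0.2)
  two <- mk_grounds(list(square(0.5, 0.5), square(0.5, 0.5)))
  surf <- rasterize_effort(two, spec)
  expect_true(all(surf$values %in% c(0, 2)))   # identical squares stack
  one <- rasterize_effort(two[1, ], spec)
  expect_true(all(one$values %in% c(0, 1)))
  expect_equal(2 * one$values, surf$values)

  set.seed(3)
  geoms <- lapply(1:6, function(i) random_convex_ring(c(1, 1), 0.6))
  g <- mk_grounds(geoms)
  a <- rasterize_effort(g, spec)
  b <- rasterize_effort(g[sample(6), ], spec)
  expect_equal(a$values, b$values)

  # conservation: total mass = sum over polygons of covered cell centers
  per_poly <- vapply(seq_len(6), function(i) {
    sum(rasterize_effort(g[i, ], spec)$values)
  }, numeric(1))
  expect_equal(sum(a$values), sum(per_poly))

  # polygon outside the grid is an error naming the fisher
  far <- mk_grounds(list(square(30, 30)))
  expect_error(rasterize_effort(far, spec), "outside grid.*f01")
})

test_that("normalization hits its extremes, preserves sign, and is idempotent", {
  spec <- grid_spec(0, 0, 2, 2, cellsize = 1)
  s <- vccr:::new_grid_surface(matrix(c(0, 1, 2, 4), 2, 2), spec, "effort")
  u <- normalize_surface(s, "unit")
  expect_equal(sort(as.vector(u$values)), c(0, 0.25, 0.5, 1))
  expect_equal(normalize_surface(u, "unit")$values, u$values)

  v <- vccr:::new_grid_surface(matrix(c(-2, 0, 1, 0), 2, 2), spec, "vcc")
  sym <- normalize_surface(v, "symmetric4")
  expect_equal(sort(as.vector(sym$values)), c(-4, 0, 0, 2))
  expect_equal(max(abs(sym$values)), 4)
  expect_equal(normalize_surface(sym, "symmetric4")$values, sym$values)

  zero <- vccr:::new_grid_surface(matrix(0, 2, 2), spec, "effort")
  expect_warning(z <- normalize_surface(zero, "unit"), "all-zero")
  expect_equal(z$values, zero$values)
  expect_true(z$all_zero)
})

test_that("vcc surface equals weighted deposition and cancels overlaps", {
  spec <- grid_spec(0, 0, 10, 10, cellsize = 0.2)
  g <- mk_grounds(list(square(0.3, 0.3, 0.5), square(1.1, 1.1, 0.5),
                       square(0.7, 0.7, 0.5)))
  g$vcc <- c(1, 1, 1)
  raw <- vcc_surface(g, spec, normalize = FALSE)
  expect_equal(raw$values, rasterize_effort(g, spec)$values)

  g$vcc <- c(1.5, -2, 0.5)
  raw <- vcc_surface(g, spec, normalize = FALSE)
  expect_equal(raw$values, oracle_effort_raster(g, spec, weights = g$vcc))

  # exact cancellation in the overlap of +1 and -1
  o <- mk_grounds(list(square(0.3, 0.3, 0.5), square(0.3, 0.3, 0.5)))
  o$vcc <- c(1, -1)
  expect_true(all(vcc_surface(o, spec, normalize = FALSE)$values == 0))

  g$vcc[2] <- NA
  expect_error(vcc_surface(g, spec), "missing a vcc value.*f02")
})

test_that("geodesic distances match the WGS84 oracle and are symmetric", {
  d <- distance_to_port(c(0, 0), c(1, 0))
  expect_equal(d, 111.3195, tolerance = 1e-4)       # equatorial arc
  expect_lt(abs(d - 111.19) / d, 0.005)             # spherical approx 0.5%
  expect_equal(distance_to_port(c(5, 5), c(5, 5)), 0)
  set.seed(12)
  for (i in 1:5) {
    a <- c(stats::runif(1, -85, -75), stats::runif(1, -5, 5))
    b <- c(stats::runif(1, -85, -75), stats::runif(1, -5, 5))
    expect_equal(distance_to_port(a, b), distance_to_port(b, a))
  }
  expect_error(distance_to_port(c(200, 0), c(0, 0)), "bounds")
  # point-to-line mode: a point due west of a meridian coastline
  coast <- cbind(lon = c(-80.5, -80.5), lat = c(-3, 1))
  d_line <- distance_to_port(c(-81.5, -1), coast = coast)
  expect_equal(d_line, distance_to_port(c(-81.5, -1), c(-80.5, -1)),
               tolerance = 0.01)
})

test_that("decadal distance summaries match hand computation", {
  ports <- tibble::tibble(port_id = "p1", name = "cove", lon = -80.5,
                          lat = -1)
  at_port <- mk_grounds(list(square(-80.55, -1.05, 0.1)))  # centred on port
  s0 <- decadal_distance_summary(at_port, ports)
  expect_equal(s0$summary$mean_km, 0, tolerance = 1e-6)

  offs <- c(10, 25, 60)  # km due west
  centres <- geosphere::destPoint(c(-80.5, -1), 270, offs * 1000)
  geoms <- lapply(seq_along(offs), function(i) {
    square(centres[i, 1] - 0.05, centres[i, 2] - 0.05, 0.1)
  })
  g <- mk_grounds(geoms, decade = c("1980s", "1980s", "1990s"))
  s <- decadal_distance_summary(g, ports)
  expect_equal(s$summary$mean_km, c(mean(offs[1:2]), offs[3]),
               tolerance = 0.01)
  expect_equal(s$summary$median_km, c(mean(offs[1:2]), offs[3]),
               tolerance = 0.01)
  expect_equal(s$overall_mean_km, mean(offs), tolerance = 0.01)

  bad <- mk_grounds(list(square(0, 0)), port = "nope")
  expect_error(decadal_distance_summary(bad, ports), "unknown port_id")
})

test_that("refining the grid converges the rasterized area to the planar area", {
  set.seed(4)
  ring <- random_convex_ring(c(1, 1), 0.4)
  ring_closed <- rbind(ring, ring[1, ])
  x <- ring_closed[, 1]; y <- ring_closed[, 2]
  n <- nrow(ring_closed)
  true_area <- abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
  areas <- vapply(c(0.02, 0.01, 0.005), function(cs) {
    spec <- grid_spec(0, 0, 2 / cs, 2 / cs, cellsize = cs)
    sum(rasterize_effort(mk_grounds(list(ring)), spec)$values) * cs^2
  }, numeric(1))
  err <- abs(areas - true_area)
  expect_true(all(diff(err) < 0))      # monotone improvement
  expect_lt(err[3] / true_area, 0.02)
})

test_that("ascii grid and geojson round trips preserve data", {
  spec <- grid_spec(-81.005, -2.015, 7, 5, cellsize = 0.01)
  vals <- matrix(stats::rnorm(35), 5, 7)
  s <- vccr:::new_grid_surface(vals, spec, "effort")
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(s, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, vals)
  expect_equal(back$spec$xmin, spec$xmin)
  expect_equal(back$spec$cellsize, spec$cellsize)

  g <- mk_grounds(list(square(-81, -2, 0.3), square(-80.7, -1.8, 0.2)),
                  decade = c("1980s", "2010s"))
  g$vcc <- c(1.25, NA)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_grounds_geojson(g, gj)
  back <- read_grounds_geojson(gj)
  expect_equal(back$fisher_id, g$fisher_id)
  expect_equal(back$decade, g$decade)
  expect_equal(back$vcc, g$vcc)
  for (i in 1:2) {
    expect_equal(vccr:::open_ring(back$geometry[[i]]),
                 vccr:::open_ring(g$geometry[[i]]),
                 ignore_attr = TRUE)
  }
})

test_that("core grounds are the cells above the effort threshold", {
  spec <- grid_spec(0, 0, 10, 10, cellsize = 0.2)
  g <- mk_grounds(list(square(0.2, 0.2, 1.2), square(0.5, 0.5, 0.6),
                       square(0.6, 0.6, 0.3)))
  eff <- rasterize_effort(g, spec)
  core <- core_grounds(eff, threshold = 0.6)
  u <- normalize_surface(eff, "unit")
  expect_equal(nrow(core), sum(u$values >= 0.6))
  expect_true(all(core$value >= 0.6))
})
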