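# Independent oracles kept deliberately naive: these re-derive results by
# first principles so the implementation is checked against a different
# route, not against itself.

# Even-odd ray casting, one point at a time, straight from the textbook
# crossing rule. Independent of sp::point.in.polygon.
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y)) {
        xcross <- xi + (y - yi) * (xj - xi) / (yj - yi)
        if (x < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Brute-force effort raster: test every cell center against every ring.
oracle_effort_raster <- function(grounds, spec, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(grounds))
  cx <- spec$xmin + (seq_len(spec$ncol) - 0.5) * spec$cellsize
  cy <- spec$ymax - (seq_len(spec$nrow) - 0.5) * spec$cellsize
  vals <- matrix(0, nrow = spec$nrow, ncol = spec$ncol)
  for (g in seq_len(nrow(grounds))) {
    ring <- grounds$geometry[[g]]
    for (j in seq_len(spec$nrow)) {
      inside <- oracle_point_in_polygon(cx, rep(cy[j], length(cx)), ring)
      vals[j, inside] <- vals[j, inside] + weights[g]
    }
  }
  vals
}

# Plain loop cascade: anchor times running product of (1 + f).
oracle_cascade <- function(fractions, anchor = 1) {
  v <- numeric(length(fractions))
  x <- anchor
  for (k in seq_along(fractions)) {
    v[k] <- x * (1 + fractions[k])
    x <- v[k]
  }
  v
}

# Cubic least squares through the normal equations.
oracle_cubic_fit <- function(x, y) {
  X <- cbind(1, x, x^2, x^3)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Random convex polygon around a centre: convex hull of random points.
random_convex_ring <- function(centre, radius_deg, n_pts = 8) {
  ang <- sort(stats::runif(n_pts, 0, 2 * pi))
  r <- stats::runif(n_pts, 0.3, 1) * radius_deg
  cbind(lon = centre[1] + r * cos(ang), lat = centre[2] + r * sin(ang))
}

# A tiny interview CSV in the documented long layout.
write_demo_interviews <- function(path, rows = NULL) {
  header <- "fisher_id,village,port_id,interview_year,age,experience,consented,gears,species,decade,score,perceived_pct,drivers"
  if (is.null(rows)) {
    rows <- c(
      "f1,cove,p1,2023,50,30,TRUE,gillnet,shrimp,1990s,I,20,industrial_overfishing",
      "f1,cove,p1,2023,50,30,TRUE,gillnet,shrimp,2000s,S,,industrial_overfishing",
      "f2,cove,p1,2023,44,12,TRUE,gillnet;handline,snapper,2010s,D,40,",
      "f3,bay,p2,2023,61,40,FALSE,spearfishing,,,,,"
    )
  }
  writeLines(c(header, rows), path)
  path
}
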