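#' Decade vocabulary
#'
#' The survey elicits perceptions for four calendar decades, 1980s through
#' 2010s. The 2020s are structurally excluded from the enumeration (the
#' study period ends before pandemic-era distortions), and activity that
#' began before 1980 is flagged separately rather than given its own
#' decade: it anchors the trajectory baseline instead.
#'
#' @return `vcc_decades()` returns the ordered character vector of decade
#'   labels; `decade_start()` maps labels to their first calendar year;
#'   `decade_index()` maps labels to 1-based positions in the enumeration.
#' @examples
#' vcc_decades()
#' decade_start("1990s")
#' @export
vcc_decades <- function() {
  c("1980s", "1990s", "2000s", "2010s")
}

#' @rdname vcc_decades
#' @param decade character vector of decade labels.
#' @export
decade_start <- function(decade) {
  check_decade(decade)
  1980L + 10L * (decade_index(decade) - 1L)
}

#' @rdname vcc_decades
#' @export
decade_index <- function(decade) {
  match(decade, vcc_decades())
}

check_decade <- function(decade, arg = "decade") {
  bad <- setdiff(unique(decade), vcc_decades())
  if (length(bad) > 0) {
    stop(sprintf("unknown %s label(s): %s", arg, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(decade)
}

#' Decades a fisher was active in
#'
#' A career is the interval from `interview_year - experience` (first year
#' fishing) to the interview year. A fisher counts as active in every
#' decade whose ten-year interval intersects that career interval; partial
#' overlap counts. Decades outside 1980s--2010s are dropped. Careers that
#' began before 1980 are reported through the `pre1980s` attribute (and
#' column, for the data-frame method), because those fishers anchor their
#' catch trajectory at the pre-1980s baseline.
#'
#' @param interview_year calendar year of the interview (scalar).
#' @param experience years of fishing experience (scalar, `>= 0`).
#' @return Character vector of active decade labels with a logical
#'   attribute `pre1980s`.
#' @examples
#' active_decades(2023, 5)   # entered 2018: only the 2010s
#' active_decades(2023, 40)  # entered 1983: all four decades
#' @export
active_decades <- function(interview_year, experience) {
  stopifnot(length(interview_year) == 1, length(experience) == 1)
  if (is.na(experience) || experience < 0) {
    stop("`experience` must be a non-negative number of years", call. = FALSE)
  }
  if (experience > interview_year - 1900) {
    stop("`experience` exceeds a plausible career length for `interview_year`",
         call. = FALSE)
  }
  start_year <- interview_year - experience
  dec <- vcc_decades()
  ds <- decade_start(dec)
  keep <- (ds <= interview_year) & (ds + 9 >= start_year)
  out <- dec[keep]
  attr(out, "pre1980s") <- start_year < 1980
  out
}

#' Entry decade of a fisher
#'
#' The first element of [active_decades()], or `"pre1980s"` when the career
#' began before 1980. Vectorised over fishers.
#'
#' @inheritParams active_decades
#' @return Character vector: one of `"pre1980s"`, `"1980s"`, ..., `"2010s"`,
#'   or `NA` when the career begins after the last modelled decade.
#' @export
entry_decade <- function(interview_year, experience) {
  start_year <- interview_year - experience
  out <- rep(NA_character_, length(start_year))
  out[start_year < 1980] <- "pre1980s"
  for (d in vcc_decades()) {
    ds <- decade_start(d)
    hit <- !is.na(start_year) & start_year >= ds & start_year <= ds + 9
    out[hit] <- d
  }
  out
}
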