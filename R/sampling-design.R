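#' Yamane finite-population sample size
#'
#' Computes the classical finite-population sample size
#' \deqn{n = \frac{N}{1 + N e^2}}{n = N / (1 + N e^2)}
#' for population size `N` at precision (sampling error) `e`. At `e = 0`
#' the formula returns a census (`n = N`); for `e > 0` it is strictly
#' increasing in `N` and bounded above by `1/e^2` (100 respondents at the
#' conventional `e = 0.10`).
#'
#' @param N positive population size(s).
#' @param e precision as a fraction in \[0, 1\], default `0.10` (the
#'   conventional plus-or-minus 10% level).
#' @return Unrounded sample size(s), same length as `N`.
#' @examples
#' yamane_sample_size(700)      # 87.5
#' yamane_sample_size(100, 0)   # census
#' @export
yamane_sample_size <- function(N, e = 0.10) {
  if (any(is.na(N)) || any(N < 1)) {
    stop("`N` must contain population sizes >= 1", call. = FALSE)
  }
  if (length(e) != 1 || is.na(e) || e < 0 || e > 1) {
    stop("`e` must be a single fraction in [0, 1]", call. = FALSE)
  }
  N / (1 + N * e^2)
}

#' Aggregate sampling effort across population sources
#'
#' Villages rarely have one authoritative fisher count; censuses, licence
#' registries and association leaders disagree. The design target is then
#' the mean of the Yamane sample sizes computed from each available source,
#' reported with the minimum and maximum as a variability band. Per-source
#' sizes are kept unrounded; mean, min and max are each rounded
#' half-to-even to whole fishers at the end. Missing sources (`NA`) are
#' skipped, not treated as zero.
#'
#' @param sources tibble with columns `village` and `N` (one row per
#'   village x source; `N` may be `NA` for unavailable sources). A bare
#'   numeric vector is accepted for a single village.
#' @param e precision fraction, default `0.10`.
#' @return Tibble `(village, n_sources, mean_n, min_n, max_n, raw_n)`
#'   where `raw_n` is a list column of the unrounded per-source sizes.
#'   For vector input, a single-row tibble with `village = NA`.
#' @examples
#' aggregate_sampling_effort(c(451, 724, 388, 700))  # mean 84, band 80-88
#' @export
aggregate_sampling_effort <- function(sources, e = 0.10) {
  if (is.numeric(sources)) {
    sources <- tibble::tibble(village = NA_character_, N = sources)
  }
  stopifnot(all(c("village", "N") %in% names(sources)))
  sources <- dplyr::filter(sources, !is.na(.data$N))
  if (nrow(sources) == 0) {
    stop("no available population sources", call. = FALSE)
  }
  sources |>
    dplyr::group_by(.data$village) |>
    dplyr::summarise(
      n_sources = dplyr::n(),
      raw_n = list(yamane_sample_size(.data$N, e)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_n = purrr::map_int(.data$raw_n, ~ round_half_even(mean(.x))),
      min_n = purrr::map_int(.data$raw_n, ~ round_half_even(min(.x))),
      max_n = purrr::map_int(.data$raw_n, ~ round_half_even(max(.x)))
    ) |>
    dplyr::select("village", "n_sources", "mean_n", "min_n", "max_n", "raw_n")
}

# Half-to-even integer rounding with a 1e-9 pre-round so that values that
# are exact halves in real arithmetic (e.g. 700/8 = 87.5) are not pushed
# off the tie by binary floating point.
round_half_even <- function(x) {
  as.integer(round(round(x, 9)))
}

#' Sample-size coverage ratio
#'
#' Achieved interviews as a percentage of the village's mean sampling
#' target, rounded to the nearest whole percent. Values above 100 indicate
#' a village sampled beyond its design target.
#'
#' @param interviewed number of completed interviews (`>= 0`), vectorised.
#' @param target_n mean sampling target (`>= 1`), vectorised.
#' @return Integer percentage(s).
#' @examples
#' coverage_ratio(60, 84)   # 71
#' coverage_ratio(107, 79)  # 135
#' @export
coverage_ratio <- function(interviewed, target_n) {
  if (any(is.na(target_n)) || any(target_n < 1)) {
    stop("`target_n` must be >= 1", call. = FALSE)
  }
  if (any(is.na(interviewed)) || any(interviewed < 0)) {
    stop("`interviewed` must be >= 0", call. = FALSE)
  }
  as.integer(round(100 * interviewed / target_n))
}
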