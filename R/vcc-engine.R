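#' Per-fisher virtual catch trajectories
#'
#' The Virtual Catch Change (VCC) model turns each fisher's sequence of
#' categorical trend responses into a dimensionless catch index. A
#' trajectory starts from an anchor `X`: fishers already active in (or
#' before) the 1980s anchor at the standardized pre-1980s catch of 1;
#' fishers who entered later anchor at the mean virtual catch that their
#' cohort (all fishers in the same stratum) had reached in the decade
#' before entry. This cohort-mean anchoring is the shifting-baseline
#' correction -- without it a fisher who started in an already-depleted
#' 2000s would treat that depleted state as "1". Each decade then updates
#' the value multiplicatively,
#' \deqn{V_k = X_{k-1} + X_{k-1} f_k,}{V_k = X_{k-1} (1 + f_k),}
#' where the signed fraction `f_k` comes from the decade's categorical
#' score and perceived percentage ([signed_fraction()]): stable keeps the
#' prior value, declines subtract a percentage of it, increases add one.
#' `V_k` becomes the next decade's `X`.
#'
#' Trajectory units are `fisher_id` crossed with any stratification
#' columns named in `by` (species, gear, ...). Cohort baselines are
#' computed within the same stratum, decade by decade in calendar order,
#' which is well defined because anchors only look backward. A unit's
#' active decades must be contiguous.
#'
#' @param responses long tibble with columns `fisher_id`, `decade`, and
#'   either a precomputed signed `fraction` or `score` +
#'   `perceived_pct`; plus any columns named in `by`.
#' @param by character vector of stratification columns (default none:
#'   one trajectory per fisher).
#' @param baseline `"cohort"` (default) anchors post-1980s entrants at the
#'   previous decade's stratum mean; `"naive"` anchors every unit at 1,
#'   reproducing the uncorrected shifting-baseline behaviour for
#'   comparison experiments.
#' @param impute optional midpoint imputation passed to
#'   [signed_fraction()].
#' @return Long tibble `(by..., fisher_id, decade, fraction, vcc,
#'   entry_decade, anchor)`, where `anchor` is the `X` value the unit's
#'   first active decade started from.
#' @examples
#' r <- tibble::tibble(
#'   fisher_id = "f1",
#'   decade = c("1980s", "1990s", "2000s", "2010s"),
#'   score = c("I", "I", "S", "D"),
#'   perceived_pct = c(46, 20, NA, 60)
#' )
#' vcc_trajectories(r)$vcc  # 1.46, 1.752, 1.752, 0.7008
#' @export
vcc_trajectories <- function(responses, by = NULL,
                             baseline = c("cohort", "naive"),
                             impute = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("fisher_id", "decade") %in% names(responses)))
  check_decade(responses$decade)
  if (!"fraction" %in% names(responses)) {
    responses <- dplyr::mutate(
      responses,
      fraction = signed_fraction(.data$score, .data$perceived_pct, impute)
    )
  }
  if (any(abs(responses$fraction) > 1)) {
    stop("signed fractions must lie in [-1, 1]", call. = FALSE)
  }
  missing_by <- setdiff(by, names(responses))
  if (length(missing_by) > 0) {
    stop("`by` column(s) not in `responses`: ",
         paste(missing_by, collapse = ", "), call. = FALSE)
  }

  responses$.stratum <- if (is.null(by)) "" else
    do.call(paste, c(responses[by], sep = "\r"))
  out <- responses |>
    dplyr::group_by(.data$.stratum) |>
    dplyr::group_modify(~ cascade_stratum(.x, baseline)) |>
    dplyr::ungroup()
  keep <- c(by, "fisher_id", "decade", "fraction", "vcc",
            "entry_decade", "anchor")
  dplyr::select(out, dplyr::all_of(keep))
}

# Runs the cascade for every unit of one stratum, decade by decade, so
# that cohort anchors for decade k entrants use decade k-1 values that are
# already final.
cascade_stratum <- function(resp, baseline) {
  decs <- vcc_decades()
  resp$.k <- decade_index(resp$decade)
  units <- split(resp, resp$fisher_id)
  for (u in units) {
    if (anyDuplicated(u$.k)) {
      stop("duplicate decade response within one trajectory unit (fisher ",
           u$fisher_id[1], ")", call. = FALSE)
    }
    ks <- sort(u$.k)
    if (!identical(ks, seq(min(ks), max(ks)))) {
      stop("non-contiguous active decades for fisher ", u$fisher_id[1],
           call. = FALSE)
    }
  }
  ids <- names(units)
  first_k <- vapply(units, function(u) min(u$.k), integer(1))
  V <- matrix(NA_real_, nrow = length(units), ncol = length(decs),
              dimnames = list(ids, decs))
  frac <- V
  for (i in seq_along(units)) {
    u <- units[[i]]
    frac[i, u$.k] <- u$fraction[order(u$.k)]
  }
  anchor <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (k in seq_along(decs)) {
    entering <- first_k == k
    continuing <- first_k < k & !is.na(frac[, k])
    if (any(entering)) {
      if (k == 1L || baseline == "naive") {
        x0 <- 1
      } else {
        prev <- V[, k - 1L]
        if (all(is.na(prev))) {
          stop("no cohort baseline available for entrants in ", decs[k],
               ": no fisher in this stratum was active in ", decs[k - 1L],
               call. = FALSE)
        }
        x0 <- mean(prev, na.rm = TRUE)
      }
      anchor[entering] <- x0
      V[entering, k] <- x0 * (1 + frac[entering, k])
    }
    if (any(continuing)) {
      V[continuing, k] <- V[continuing, k - 1L] *
        (1 + frac[continuing, k])
    }
  }
  resp |>
    dplyr::mutate(
      vcc = unname(V[cbind(.data$fisher_id, .data$decade)]),
      entry_decade = unname(decs[first_k[.data$fisher_id]]),
      anchor = unname(anchor[.data$fisher_id])
    ) |>
    dplyr::arrange(.data$fisher_id, .data$.k) |>
    dplyr::select(-".k")
}

#' Collapse species responses to a fisher-level response set
#'
#' The questionnaire elicits trends for up to three target species per
#' fisher. For the overall (fisher-level) trajectory, each decade's signed
#' fraction is the mean of the fisher's per-species fractions for that
#' decade; the result is flagged as derived. Use the species rows directly
#' if the pooled (species-level) aggregate is wanted instead.
#'
#' @param responses long tibble as in [vcc_trajectories()], with a
#'   `species` column.
#' @param impute optional midpoint imputation passed to
#'   [signed_fraction()].
#' @return Tibble `(fisher_id, decade, fraction, n_species, derived)`.
#' @export
fisher_overall_responses <- function(responses, impute = NULL) {
  if (!"fraction" %in% names(responses)) {
    responses <- dplyr::mutate(
      responses,
      fraction = signed_fraction(.data$score, .data$perceived_pct, impute)
    )
  }
  responses |>
    dplyr::group_by(.data$fisher_id, .data$decade) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      fraction = mean(.data$fraction),
      .groups = "drop"
    ) |>
    dplyr::mutate(derived = .data$n_species > 1L) |>
    dplyr::select("fisher_id", "decade", "fraction", "n_species", "derived")
}

#' Decadal cohort aggregate of virtual catch
#'
#' Mean, sample standard deviation (n - 1 denominator; reported as 0 when
#' a decade has a single trajectory) and trajectory count per decade,
#' optionally per stratum. Only fishers active in a decade contribute to
#' it, so `n` varies across decades.
#'
#' @param trajectories output of [vcc_trajectories()].
#' @param by character vector of stratification columns present in
#'   `trajectories` (default none).
#' @return Tibble `(by..., decade, mean, sd, n)`, decades in calendar
#'   order; class `vcc_aggregate` for plotting.
#' @export
vcc_aggregate <- function(trajectories, by = NULL) {
  if (nrow(trajectories) == 0) stop("empty trajectory set", call. = FALSE)
  out <- trajectories |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "decade")))) |>
    dplyr::summarise(
      mean = mean(.data$vcc),
      sd = if (dplyr::n() > 1L) stats::sd(.data$vcc) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(
      dplyr::across(dplyr::all_of(by)), decade_index(.data$decade)
    )
  class(out) <- c("vcc_aggregate", class(out))
  out
}

#' Relative change between two values
#'
#' `100 * (new - reference) / reference`, the signed percentage used to
#' compare decadal virtual catch levels (e.g. the 2010s against the
#' pre-1980s baseline of 1).
#'
#' @param new new value(s).
#' @param reference reference value(s); must be nonzero.
#' @return Signed percentage(s).
#' @examples
#' relative_change(1.75, 1.46)  # +19.9 (to one decimal)
#' relative_change(0.7, 1)      # -30
#' @export
relative_change <- function(new, reference) {
  if (any(is.na(reference)) || any(reference == 0)) {
    stop("`reference` must be nonzero", call. = FALSE)
  }
  100 * (new - reference) / reference
}

#' Relative-change table for a decadal aggregate
#'
#' Tabulates consecutive decade-over-decade changes plus every decade's
#' change relative to the pre-1980s baseline.
#'
#' @param aggregate output of [vcc_aggregate()] for one stratum, or any
#'   tibble with `decade` and `mean` columns.
#' @param baseline_value the pre-1980s anchor, default 1.
#' @return Tibble `(decade, reference, change_pct)`.
#' @export
vcc_relative_changes <- function(aggregate, baseline_value = 1) {
  agg <- dplyr::arrange(tibble::as_tibble(aggregate),
                        decade_index(.data$decade))
  m <- agg$mean
  d <- agg$decade
  prev_val <- c(baseline_value, m[-length(m)])
  prev_lab <- c("baseline", d[-length(d)])
  dplyr::bind_rows(
    tibble::tibble(decade = d, reference = prev_lab,
                   change_pct = relative_change(m, prev_val)),
    tibble::tibble(decade = d[-1], reference = "baseline",
                   change_pct = relative_change(m[-1], baseline_value))
  ) |>
    dplyr::distinct(.data$decade, .data$reference, .keep_all = TRUE)
}

#' Cubic trend fit to a decadal aggregate
#'
#' Ordinary least-squares cubic polynomial over (decade index, mean
#' virtual catch), the trend line drawn through decadal VCC means. The
#' abscissa is the decade's position in the enumeration (1 = 1980s ... 4 =
#' 2010s); with `include_baseline = TRUE` (default) the pre-1980s anchor
#' point (0, `baseline_value`) is prepended, giving five points. With
#' exactly four points the cubic interpolates (zero residuals). Raw
#' polynomial coefficients are used; at this scale (abscissa 0--4) no
#' orthogonalization is needed.
#'
#' @param aggregate output of [vcc_aggregate()] for one stratum, or any
#'   tibble with `decade` and `mean` columns.
#' @param include_baseline prepend the pre-1980s point, default `TRUE`.
#' @param baseline_value ordinate of the baseline point, default 1.
#' @return Object of class `vcc_trend`: the underlying `lm` fit plus the
#'   fitted points. Supports `coef()`, `predict()`, [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
fit_decadal_trend <- function(aggregate, include_baseline = TRUE,
                              baseline_value = 1) {
  agg <- dplyr::arrange(tibble::as_tibble(aggregate),
                        decade_index(.data$decade))
  pts <- tibble::tibble(
    index = decade_index(agg$decade),
    label = agg$decade,
    value = agg$mean
  )
  if (include_baseline) {
    pts <- dplyr::bind_rows(
      tibble::tibble(index = 0, label = "baseline", value = baseline_value),
      pts
    )
  }
  if (nrow(pts) < 4) {
    stop("cubic trend fit needs at least 4 points (got ", nrow(pts), ")",
         call. = FALSE)
  }
  fit <- stats::lm(value ~ poly(index, 3, raw = TRUE), data = pts)
  structure(
    list(model = fit,
         coefficients = stats::setNames(unname(stats::coef(fit)),
                                        c("b0", "b1", "b2", "b3")),
         points = pts),
    class = "vcc_trend"
  )
}

#' @export
coef.vcc_trend <- function(object, ...) object$coefficients

#' @export
predict.vcc_trend <- function(object, index = NULL, ...) {
  if (is.null(index)) index <- object$points$index
  b <- object$coefficients
  b[1] + b[2] * index + b[3] * index^2 + b[4] * index^3
}

#' @export
print.vcc_trend <- function(x, ...) {
  cat("Cubic decadal trend fit over", nrow(x$points), "points\n")
  cat("  V(t) =", format(x$coefficients["b0"], digits = 4), "+",
      format(x$coefficients["b1"], digits = 4), "t +",
      format(x$coefficients["b2"], digits = 4), "t^2 +",
      format(x$coefficients["b3"], digits = 4), "t^3\n")
  invisible(x)
}

#' Tidy a cubic trend fit
#'
#' @param x a `vcc_trend` object.
#' @param ... unused.
#' @return Tibble with one row per polynomial term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy vcc_trend
#' @export
tidy.vcc_trend <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("b0", "b1", "b2", "b3")[seq_len(nrow(s))],
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' Glance at a cubic trend fit
#'
#' @param x a `vcc_trend` object.
#' @param ... unused.
#' @return One-row tibble: `r.squared`, `sigma`, `df.residual`, `nobs`.
#' @method glance vcc_trend
#' @export
glance.vcc_trend <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$model$df.residual,
    nobs = nrow(x$points)
  )
}

#' Ranking of perceived decline drivers
#'
#' Counts how many fishers cite each coded decline-driver label, most
#' cited first; ties break alphabetically so the ordering is total and
#' reproducible.
#'
#' @param interviews tibble from [read_interviews()] (uses the `drivers`
#'   list column), or a long tibble with columns `fisher_id` and `driver`.
#' @return Tibble `(driver, n)` in ranking order.
#' @export
driver_frequency <- function(interviews) {
  long <- if ("drivers" %in% names(interviews)) {
    interviews |>
      dplyr::select("fisher_id", "drivers") |>
      tidyr::unnest_longer("drivers", values_to = "driver") |>
      dplyr::filter(!is.na(.data$driver), .data$driver != "")
  } else {
    dplyr::select(interviews, "fisher_id", "driver")
  }
  long |>
    dplyr::distinct(.data$fisher_id, .data$driver) |>
    dplyr::count(.data$driver, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$driver)
}
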