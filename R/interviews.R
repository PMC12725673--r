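#' Read a structured interview table
#'
#' Reads the long-format CSV/TSV export of a LEK survey: one row per
#' fisher x species x decade trend response, with the fisher-level fields
#' repeated on every row. Expected columns:
#'
#' * `fisher_id`, `village`, `port_id`, `interview_year`, `age`,
#'   `experience`, `consented` (logical or 0/1)
#' * `gears`, `drivers` -- `;`-separated labels, constant within a fisher
#' * `species`, `decade` (`"1980s"`..`"2010s"`), `score`
#'   (`MD/D/S/I/MI`), `perceived_pct`
#'
#' Response fields may be empty for fishers who declined (the roster keeps
#' them so that contact/decline accounting is reproducible). Rows that fail
#' validation are dropped and reported -- not silently repaired -- via the
#' `rejected` attribute, a tibble of `(line, fisher_id, reason)`. Fisher
#' order follows first appearance in the file.
#'
#' @param path path to a delimited text file.
#' @param delim field delimiter, default `","`.
#' @return A tibble with one row per fisher: demographic columns, list
#'   columns `gears` and `drivers`, and a `responses` list column of
#'   tibbles `(species, decade, score, perceived_pct)`. Attribute
#'   `rejected` holds the rejected-row report.
#' @seealso [write_interviews()] for the inverse, [filter_eligible()].
#' @export
read_interviews <- function(path, delim = ",") {
  if (!file.exists(path)) stop("interview file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("fisher_id", "village", "port_id", "interview_year", "age",
                "experience", "consented", "gears", "species", "decade",
                "score", "perceived_pct", "drivers")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("interview table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_interview_rows(raw)
}

# Shared by read_interviews() and in-memory constructors: row-level
# validation, rejection reporting, and nesting to one row per fisher.
validate_interview_rows <- function(raw) {
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  reason <- rep(NA_character_, n)

  num <- function(x) suppressWarnings(as.numeric(x))
  interview_year <- num(raw$interview_year)
  age <- num(raw$age)
  experience <- num(raw$experience)
  consented <- parse_logical_flag(raw$consented)
  pct <- num(raw$perceived_pct)
  has_response <- !is.na(raw$score) & raw$score != ""

  flag <- function(cond, why) {
    hit <- which(cond & is.na(reason))
    reason[hit] <<- why
  }
  flag(is.na(raw$fisher_id) | raw$fisher_id == "", "missing fisher_id")
  flag(is.na(consented), "unparseable consented flag")
  flag(is.na(interview_year), "unparseable interview_year")
  flag(is.na(experience) | experience < 0, "invalid experience")
  flag(!is.na(age) & !is.na(experience) & age < experience,
       "age below experience")
  flag(has_response & !(raw$score %in% trend_scores()), "unknown trend score")
  flag(has_response & !(raw$decade %in% vcc_decades()), "unknown decade label")
  flag(has_response & raw$score != "S" & (is.na(pct) | pct < 0 | pct > 100),
       "perceived_pct outside [0,100]")

  rejected <- tibble::tibble(
    line = line[!is.na(reason)],
    fisher_id = raw$fisher_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep <- is.na(reason)

  clean <- tibble::tibble(
    fisher_id = raw$fisher_id[keep],
    village = raw$village[keep],
    port_id = raw$port_id[keep],
    interview_year = interview_year[keep],
    age = age[keep],
    experience = experience[keep],
    consented = consented[keep],
    gears_chr = dplyr::coalesce(raw$gears[keep], ""),
    drivers_chr = dplyr::coalesce(raw$drivers[keep], ""),
    species = raw$species[keep],
    decade = raw$decade[keep],
    score = raw$score[keep],
    perceived_pct = pct[keep],
    has_response = has_response[keep]
  )

  ids <- unique(clean$fisher_id)
  resp_cols <- clean[clean$has_response,
                     c("fisher_id", "species", "decade", "score",
                       "perceived_pct")]
  resp_by_id <- split(resp_cols[-1], factor(resp_cols$fisher_id,
                                            levels = ids))
  fishers <- clean |>
    dplyr::distinct(.data$fisher_id, .keep_all = TRUE) |>
    dplyr::mutate(
      gears = lapply(.data$gears_chr, split_labels),
      drivers = lapply(.data$drivers_chr, split_labels),
      responses = unname(lapply(resp_by_id[.data$fisher_id],
                                tibble::as_tibble))
    ) |>
    dplyr::select("fisher_id", "village", "port_id", "interview_year",
                  "age", "experience", "consented", "gears", "drivers",
                  "responses") |>
    dplyr::arrange(match(.data$fisher_id, ids))

  attr(fishers, "rejected") <- rejected
  fishers
}

parse_logical_flag <- function(x) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

split_labels <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Write an interview table back to delimited text
#'
#' Inverse of [read_interviews()]: flattens the nested per-fisher tibble to
#' the long one-row-per-response layout. Fishers without responses are kept
#' as a single row with empty response fields so the contacted/declined
#' roster survives a round trip.
#'
#' @param interviews tibble from [read_interviews()] or [generate_survey()].
#' @param path output file path.
#' @param delim field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_interviews <- function(interviews, path, delim = ",") {
  long <- interviews |>
    dplyr::mutate(
      gears = purrr::map_chr(.data$gears, paste, collapse = ";"),
      drivers = purrr::map_chr(.data$drivers, paste, collapse = ";"),
      responses = purrr::map(.data$responses, function(r) {
        if (nrow(r) == 0) {
          tibble::tibble(species = "", decade = "", score = "",
                         perceived_pct = NA_real_)
        } else r
      })
    ) |>
    tidyr::unnest("responses")
  readr::write_delim(long, path, delim = delim, na = "")
  invisible(path)
}

#' Filter interviews to the analysable roster
#'
#' Keeps consented fishers with at least `min_experience` years of fishing
#' experience (set `strict = TRUE` for a strictly-greater-than rule).
#' Short-experience LEK holders are excluded because they are less likely
#' to have witnessed the trends being reconstructed. The operation is
#' idempotent; removal counts per reason are attached as attribute
#' `removed` and can be printed for survey accounting.
#'
#' @param interviews tibble from [read_interviews()].
#' @param min_experience experience threshold in years, default 5
#'   (inclusive: surveyed experience ranges start at exactly 5 years).
#' @param strict if `TRUE`, require experience strictly greater than
#'   `min_experience`.
#' @return Filtered tibble with attribute `removed`, a named integer
#'   vector `c(declined = ..., inexperienced = ...)`.
#' @export
filter_eligible <- function(interviews, min_experience = 5, strict = FALSE) {
  ok_exp <- if (strict) interviews$experience > min_experience
            else interviews$experience >= min_experience
  declined <- !interviews$consented
  removed <- c(
    declined = sum(declined),
    inexperienced = sum(!declined & !ok_exp)
  )
  out <- interviews[interviews$consented & ok_exp, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "rejected") <- NULL
  out
}

#' Flatten interviews to one row per trend response
#'
#' Joins fisher-level fields onto the nested `responses`, yielding the long
#' tibble consumed by [vcc_trajectories()]. Gear labels stay as a list
#' column; use `tidyr::unnest(gears)` for per-gear stratification (a fisher
#' using two gears then contributes a trajectory to both strata).
#'
#' @param interviews tibble from [read_interviews()].
#' @return Long tibble: fisher fields plus `species`, `decade`, `score`,
#'   `perceived_pct`.
#' @export
unnest_responses <- function(interviews) {
  interviews |>
    dplyr::select(-"drivers") |>
    tidyr::unnest("responses")
}

#' Tally of fishers active per decade
#'
#' Counts, for each modelled decade, the fishers whose career interval
#' (interview year minus experience, through interview year) intersects it.
#'
#' @param interviews tibble from [read_interviews()].
#' @return Tibble `(decade, n)` over the four modelled decades.
#' @export
decade_activity <- function(interviews) {
  start <- interviews$interview_year - interviews$experience
  purrr::map_dfr(vcc_decades(), function(d) {
    ds <- decade_start(d)
    tibble::tibble(
      decade = d,
      n = sum(ds <= interviews$interview_year & ds + 9 >= start)
    )
  })
}
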