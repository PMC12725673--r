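#' Categorical trend scores
#'
#' Fishers rate each decade's catch of a species with one of five
#' categorical scores: major decline (`MD`), decline (`D`), stable (`S`),
#' increase (`I`), major increase (`MI`), and attach the percentage the
#' category means to them (e.g. "decline" may mean a 25% drop, "major
#' increase" a 70% gain). The sign is a pure function of the code:
#' declines are negative, increases positive, stable is zero.
#'
#' @param score character vector of score codes.
#' @return `trend_scores()`: the five valid codes, most negative first.
#'   `score_sign()`: integer vector in `{-1, 0, 1}`.
#' @examples
#' score_sign(c("MD", "S", "MI"))
#' @export
trend_scores <- function() {
  c("MD", "D", "S", "I", "MI")
}

#' @rdname trend_scores
#' @export
score_sign <- function(score) {
  check_score(score)
  unname(c(MD = -1L, D = -1L, S = 0L, I = 1L, MI = 1L)[score])
}

check_score <- function(score) {
  bad <- setdiff(unique(score[!is.na(score)]), trend_scores())
  if (length(bad) > 0) {
    stop(sprintf("unknown trend score(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(score)
}

#' Signed fractional catch change of a trend response
#'
#' Converts a (score, perceived percentage) pair into the signed fraction
#' applied by the virtual-catch cascade: stable maps to 0, declines to
#' `-pct/100`, increases to `+pct/100`. Percentages must lie in
#' \[0, 100\] -- a decline cannot remove more than the whole catch --
#' so the result lies in \[-1, 1\].
#'
#' A missing percentage on a non-stable score is an error by default,
#' because the survey always elicits one. Passing `impute` (named numeric
#' midpoints, e.g. `c(MD = 70, D = 25, I = 25, MI = 70)`) substitutes
#' category midpoints instead; this mode is off by default.
#'
#' @param score character vector of score codes (`MD, D, S, I, MI`).
#' @param perceived_pct numeric vector of percentages in \[0, 100\];
#'   ignored (may be `NA`) where `score == "S"`.
#' @param impute optional named numeric vector of fallback percentages per
#'   non-stable score code.
#' @return Numeric vector of signed fractions in \[-1, 1\].
#' @examples
#' signed_fraction("D", 25)   # -0.25
#' signed_fraction("MI", 70)  # +0.70
#' signed_fraction("S", NA)   # 0
#' @export
signed_fraction <- function(score, perceived_pct, impute = NULL) {
  check_score(score)
  perceived_pct <- rep_len(as.numeric(perceived_pct), length(score))
  sgn <- score_sign(score)
  missing_pct <- sgn != 0L & is.na(perceived_pct)
  if (any(missing_pct)) {
    if (is.null(impute)) {
      stop("missing perceived_pct for non-stable score(s); ",
           "supply `impute` midpoints to allow imputation", call. = FALSE)
    }
    fill <- impute[score[missing_pct]]
    if (anyNA(fill)) {
      stop("`impute` lacks a midpoint for some score present in the data",
           call. = FALSE)
    }
    perceived_pct[missing_pct] <- fill
  }
  out_of_range <- sgn != 0L &
    (perceived_pct < 0 | perceived_pct > 100)
  if (any(out_of_range, na.rm = TRUE)) {
    stop("perceived_pct outside [0, 100]", call. = FALSE)
  }
  out <- sgn * perceived_pct / 100
  out[sgn == 0L] <- 0
  out
}
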