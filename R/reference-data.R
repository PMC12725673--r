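#' Worked-example reference bundle
#'
#' Small in-memory dataset bundle of the published summary figures the
#' package is validated against, for use in examples and acceptance
#' checks without any download:
#'
#' * `population_sources`: per-village fisher counts from the four survey
#'   sources (2013 census, 2023 licences, 2024 census, association
#'   leaders; `NA` where a source did not report), with the reported
#'   sampling-effort triple (`reported_mean`, `reported_min`,
#'   `reported_max`) alongside.
#' * `interview_roster`: per-village contacted and completed interview
#'   counts with the reported coverage percentage.
#' * `roster_totals`: contacted (1436), declined (275) and completed
#'   (1161) interview totals.
#' * `vcc_means`: the reconstructed overall decadal virtual-catch means
#'   (baseline 1, then 1.46, 1.75, 1.73, 0.7).
#' * `distance_means_km` / `distance_medians_km`: reported decadal
#'   centroid-to-port distance summaries.
#'
#' One village (Cañaveral) prints a sampling-effort mean of 24 that is
#' inconsistent with its own sources -- the mean of the unrounded Yamane
#' sizes for counts 20/25/39/50 is 24.51, which rounds to 25, and the
#' village's reported 164% coverage equals 41/25, not 41/24. The
#' reproduction tests treat that row as a documented known mismatch; see
#' the methods vignette.
#'
#' @return Named list as described above.
#' @export
reference_survey <- function() {
  population_sources <- tibble::tribble(
    ~village,            ~province,      ~census_2013, ~licensed_2023, ~census_2024, ~leaders, ~reported_mean, ~reported_min, ~reported_max,
    "Cojimies",          "Manabi",       451,  724,  388,  700, 84, 80, 88,
    "Canaveral",         "Manabi",        20,   25,   39,   50, 24, 17, 33,
    "La Chorrera",       "Manabi",       230,  231,  128,  750, 71, 56, 88,
    "Jama",              "Manabi",       272,  358,  633,   NA, 79, 73, 86,
    "Puerto Cabuyal",    "Manabi",        22,   24,   60,   65, 29, 18, 39,
    "Canoa",             "Manabi",       149,  181,  210,  300, 67, 60, 75,
    "Bahia de Caraquez", "Manabi",       374,  371,   NA,  400, 79, 79, 80,
    "San Clemente",      "Manabi",       260,  272,  444,  400, 77, 72, 82,
    "Crucita",           "Manabi",       352,  471,   62,   NA, 66, 38, 82,
    "Jaramijo",          "Manabi",      3102, 1224, 1448,   NA, 94, 92, 97,
    "Santa Rosa (M)",    "Manabi",       110,   99,   22,   NA, 40, 18, 52,
    "Puerto Cayo",       "Manabi",       323,  393,  341,   NA, 78, 76, 80,
    "Machalilla",        "Manabi",       741,  229,  179,  200, 72, 64, 88,
    "Puerto Lopez",      "Manabi",      1109,  531,  521,   NA, 87, 84, 92,
    "San Pedro",         "Santa Elena",   45,  215,  133, 1000, 62, 31, 91,
    "Ayangue",           "Santa Elena",  196,   91,   32,  250, 52, 24, 71,
    "Jambeli",           "Santa Elena",  184,  108,  255,  400, 67, 52, 80,
    "Salinas",           "Santa Elena",  110,   39,   NA,   70, 41, 28, 52,
    "Santa Rosa (SE)",   "Santa Elena", 1984,  507,  338, 1500, 87, 77, 95,
    "Anconcito",         "Santa Elena", 1603,  554,  641,   NA, 88, 85, 94
  )
  interview_roster <- tibble::tribble(
    ~village,            ~contacted, ~interviewed, ~target_n, ~reported_coverage,
    "Cojimies",           79,  60, 84,  71,
    "Canaveral",          49,  41, 24, 164,
    "La Chorrera",        71,  60, 71,  85,
    "Jama",              120, 107, 79, 135,
    "Puerto Cabuyal",     27,  27, 29,  93,
    "Canoa",              64,  57, 67,  85,
    "Bahia de Caraquez",  81,  65, 79,  82,
    "San Clemente",       75,  54, 77,  70,
    "Crucita",           137, 112, 66, 170,
    "Jaramijo",           45,  26, 94,  28,
    "Santa Rosa (M)",     52,  24, 40,  60,
    "Puerto Cayo",        67,  49, 78,  63,
    "Machalilla",         73,  56, 72,  78,
    "Puerto Lopez",      135, 107, 87, 123,
    "San Pedro",          58,  51, 62,  82,
    "Ayangue",            50,  48, 52,  92,
    "Jambeli",            47,  30, 67,  45,
    "Salinas",            42,  42, 41, 102,
    "Santa Rosa (SE)",    78,  69, 87,  79,
    "Anconcito",          86,  76, 88,  86
  )
  list(
    population_sources = population_sources,
    interview_roster = interview_roster,
    roster_totals = c(contacted = 1436L, declined = 275L,
                      completed = 1161L),
    decade_activity = c(`1980s` = 350L, `1990s` = 608L, `2000s` = 914L,
                        `2010s` = 1125L),
    vcc_means = c(baseline = 1, `1980s` = 1.46, `1990s` = 1.75,
                  `2000s` = 1.73, `2010s` = 0.7),
    distance_means_km = c(`1980s` = 36.8, `1990s` = 37.1, `2000s` = 46.6,
                          `2010s` = 54.4),
    distance_medians_km = c(`1980s` = 12.2, `1990s` = 12.9,
                            `2000s` = 14.5, `2010s` = 15.7)
  )
}

#' Synthetic contacted/declined roster at reference scale
#'
#' Builds a minimal interview roster with the reference totals -- 1,436
#' contacted fishers of whom 275 declined -- so that the consent-filter
#' accounting can be exercised end to end. Demographics are filled with
#' neutral placeholder values; it is a synthetic stand-in for the real
#' roster, not survey data.
#'
#' @param contacted roster size, default 1436.
#' @param declined number of non-consenting fishers, default 275.
#' @return Interview tibble in the [read_interviews()] shape.
#' @export
reference_roster <- function(contacted = 1436, declined = 275) {
  stopifnot(declined <= contacted)
  consented <- rep(TRUE, contacted)
  if (declined > 0) {
    consented[seq(1, contacted, length.out = declined)] <- FALSE
  }
  resp <- tibble::tibble(
    species = "species_a", decade = vcc_decades(), score = "S",
    perceived_pct = NA_real_
  )
  empty <- resp[0, ]
  tibble::tibble(
    fisher_id = sprintf("r%04d", seq_len(contacted)),
    village = "roster", port_id = "port_01", interview_year = 2023,
    age = 60, experience = 45, consented = consented,
    gears = rep(list("gillnet"), contacted),
    drivers = rep(list(character(0)), contacted),
    responses = lapply(consented, function(ok) if (ok) resp else empty)
  )
}
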