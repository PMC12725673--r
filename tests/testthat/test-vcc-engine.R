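test_that("signed fractions follow the score logic rule", {
  expect_equal(signed_fraction("D", 25), -0.25)
  expect_equal(signed_fraction("MI", 70), 0.70)
  expect_equal(signed_fraction("S", NA), 0)
  expect_equal(signed_fraction(c("MD", "S", "I"), c(80, NA, 10)),
               c(-0.8, 0, 0.1))
  expect_error(signed_fraction("D", NA), "missing perceived_pct")
  expect_equal(signed_fraction("D", NA, impute = c(D = 25)), -0.25)
  expect_error(signed_fraction("D", 120), "outside")
  expect_error(signed_fraction("Q", 10), "unknown trend score")
})

resp4 <- function(id, scores, pcts) {
  tibble::tibble(fisher_id = id, decade = vcc_decades()[seq_along(scores)],
                 score = scores, perceived_pct = pcts)
}

test_that("the cascade reproduces hand-computed trajectories", {
  # stable fixpoint
  expect_equal(vcc_trajectories(resp4("a", rep("S", 4), rep(NA, 4)))$vcc,
               rep(1, 4))
  # hand cascade: 1 -> 1.46 -> 1.46*1.2 -> *1 -> *0.4
  tr <- vcc_trajectories(resp4("a", c("I", "I", "S", "D"),
                               c(46, 20, NA, 60)))
  expect_equal(tr$vcc, c(1.46, 1.752, 1.752, 0.7008))
  expect_equal(tr$anchor, rep(1, 4))
})

test_that("late entrants anchor at the cohort mean of the previous decade", {
  veteran <- resp4("vet", c("I", "I", "S", "D"), c(46, 20, NA, 60))
  late <- tibble::tibble(fisher_id = "late", decade = "1990s",
                         score = "D", perceived_pct = 50)
  tr <- vcc_trajectories(dplyr::bind_rows(veteran, late))
  expect_equal(tr$vcc[tr$fisher_id == "late"], 1.46 * 0.5)  # 0.73
  expect_equal(tr$anchor[tr$fisher_id == "late"], 1.46)
  # naive mode anchors everyone at 1
  tr0 <- vcc_trajectories(dplyr::bind_rows(veteran, late),
                          baseline = "naive")
  expect_equal(tr0$vcc[tr0$fisher_id == "late"], 0.5)
  # no cohort available -> error
  orphan <- tibble::tibble(fisher_id = "o", decade = "2000s",
                           score = "S", perceived_pct = NA)
  expect_error(vcc_trajectories(orphan), "no cohort baseline")
})

test_that("gapped or duplicated decade sequences are rejected", {
  gap <- tibble::tibble(fisher_id = "g", decade = c("1980s", "2000s"),
                        score = "S", perceived_pct = NA)
  expect_error(vcc_trajectories(gap), "non-contiguous")
  dup <- tibble::tibble(fisher_id = "d", decade = c("1980s", "1980s"),
                        score = "S", perceived_pct = NA)
  expect_error(vcc_trajectories(dup), "duplicate decade")
})

test_that("trajectories match exhaustive enumeration over all score sequences", {
  # all 5^4 score sequences; percentages cycle over a 5-point grid so
  # every category/percentage pairing occurs
  grid_pct <- c(5, 25, 50, 75, 100)
  seqs <- expand.grid(s1 = trend_scores(), s2 = trend_scores(),
                      s3 = trend_scores(), s4 = trend_scores(),
                      stringsAsFactors = FALSE)
  scores <- as.matrix(seqs)
  pcts <- matrix(grid_pct[(seq_len(length(scores)) - 1) %% 5 + 1],
                 nrow = nrow(scores))
  resp <- tibble::tibble(
    fisher_id = rep(sprintf("e%03d", seq_len(nrow(scores))), each = 4),
    decade = rep(vcc_decades(), nrow(scores)),
    score = as.vector(t(scores)),
    perceived_pct = as.vector(t(pcts))
  )
  resp$perceived_pct[resp$score == "S"] <- NA
  tr <- vcc_trajectories(resp)
  for (i in seq_len(nrow(scores))) {
    f <- ifelse(scores[i, ] == "S", 0,
                ifelse(scores[i, ] %in% c("MD", "D"), -1, 1) * pcts[i, ] / 100)
    want <- oracle_cascade(f)
    got <- tr$vcc[tr$fisher_id == sprintf("e%03d", i)]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("trajectories are non-negative, prefix-consistent and scale-equivariant", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    scores <- sample(trend_scores(), k, replace = TRUE)
    pcts <- ifelse(scores == "S", NA, sample(0:100, k, replace = TRUE))
    full <- vcc_trajectories(resp4("a", scores, pcts))$vcc
    expect_true(all(full >= 0))
    # prefix consistency: running on the first k-1 decades gives the same
    # leading values
    pre <- vcc_trajectories(resp4("a", scores[-k], pcts[-k]))$vcc
    expect_equal(pre, full[-k], tolerance = 1e-12)
  }
  # scale equivariance: scaling the anchor scales every value; exercised
  # through a late entrant whose cohort is scaled by c
  mk <- function(f1) {
    dplyr::bind_rows(
      resp4("vet", c("I", "S", "S", "S"), c(f1, NA, NA, NA)),
      tibble::tibble(fisher_id = "late", decade = c("1990s", "2000s"),
                     score = c("D", "I"), perceived_pct = c(30, 10))
    )
  }
  base <- vcc_trajectories(mk(0))    # veteran constant at 1
  scaled <- vcc_trajectories(mk(50)) # veteran constant at 1.5
  expect_equal(scaled$vcc[scaled$fisher_id == "late"],
               1.5 * base$vcc[base$fisher_id == "late"],
               tolerance = 1e-12)
})

test_that("fisher-level responses average species fractions", {
  resp <- tibble::tibble(
    fisher_id = "a", species = c("x", "y"), decade = "1980s",
    score = c("I", "D"), perceived_pct = c(40, 20)
  )
  ov <- fisher_overall_responses(resp)
  expect_equal(ov$fraction, (0.4 - 0.2) / 2)
  expect_true(ov$derived)
})

test_that("cohort aggregation gives means, sample sd, and n per decade", {
  tr <- dplyr::bind_rows(
    vcc_trajectories(resp4("a", c("S", "S"), c(NA, NA))),
    vcc_trajectories(resp4("b", c("I", "S"), c(100, NA)))
  )
  agg <- vcc_aggregate(tr)
  expect_equal(agg$mean, c(1.5, 1.5))
  expect_equal(agg$sd, rep(stats::sd(c(1, 2)), 2))
  expect_equal(agg$n, c(2L, 2L))
  solo <- vcc_aggregate(vcc_trajectories(resp4("a", "S", NA)))
  expect_equal(solo$sd, 0)
  expect_equal(solo$n, 1L)
})

test_that("cohort mean recovers the analytic expectation on simulated fishers", {
  # 500 veterans drawing i.i.d. fractions with known means per decade:
  # E[V_k] = prod_j (1 + E f_j); check within 3 standard errors
  set.seed(99)
  n <- 500
  f_mean <- c(0.2, 0.05, -0.1, -0.4)
  f_draw <- function() pmax(pmin(stats::rnorm(4, f_mean, 0.15), 1), -1)
  resp <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(fisher_id = sprintf("m%03d", i), decade = vcc_decades(),
                   fraction = f_draw())
  })
  agg <- vcc_aggregate(vcc_trajectories(resp))
  # truncation at +-1 is negligible at these means/sd
  expectation <- cumprod(1 + f_mean)
  tr <- vcc_trajectories(resp)
  for (k in seq_along(vcc_decades())) {
    v <- tr$vcc[tr$decade == vcc_decades()[k]]
    se <- stats::sd(v) / sqrt(n)
    expect_lt(abs(agg$mean[k] - expectation[k]), 3 * se + 1e-3)
  }
})

test_that("relative change reproduces the reconstructed decadal shifts", {
  m <- reference_survey()$vcc_means
  expect_equal(round(relative_change(m[["1990s"]], m[["1980s"]]), 1), 19.9)
  expect_equal(round(relative_change(m[["2000s"]], m[["1990s"]]), 2), -1.14)
  expect_equal(relative_change(m[["2010s"]], m[["baseline"]]), -30)
  expect_equal(round(relative_change(m[["2010s"]], m[["2000s"]]), 1), -59.5)
  expect_equal(relative_change(3.7, 3.7), 0)
  expect_error(relative_change(1, 0), "nonzero")

  agg <- tibble::tibble(decade = vcc_decades(),
                        mean = unname(m[vcc_decades()]))
  tab <- vcc_relative_changes(agg)
  expect_equal(
    tab$change_pct[tab$decade == "2010s" & tab$reference == "2000s"],
    relative_change(0.7, 1.73))
  expect_equal(
    tab$change_pct[tab$decade == "2010s" & tab$reference == "baseline"],
    -30)
})

test_that("cubic trend fit interpolates 4 points and matches normal equations", {
  const <- tibble::tibble(decade = vcc_decades(), mean = 1)
  fit <- fit_decadal_trend(const, include_baseline = FALSE)
  expect_equal(unname(coef(fit)), c(1, 0, 0, 0), tolerance = 1e-8)

  pts <- tibble::tibble(decade = vcc_decades(), mean = c(1.3, 2.2, 0.7, 0.4))
  fit4 <- fit_decadal_trend(pts, include_baseline = FALSE)
  expect_equal(predict(fit4), pts$mean, tolerance = 1e-8)  # zero residuals

  set.seed(5)
  x <- c(0:4, seq(0.5, 3.5, by = 0.5))
  beta <- c(1, -0.4, 0.3, -0.05)
  y <- beta[1] + beta[2] * x + beta[3] * x^2 + beta[4] * x^3 +
    stats::rnorm(length(x), 0, 1e-3)
  fit_lm <- stats::lm(y ~ poly(x, 3, raw = TRUE))
  expect_equal(unname(stats::coef(fit_lm)), oracle_cubic_fit(x, y),
               tolerance = 1e-6)
  expect_equal(oracle_cubic_fit(x, y), beta, tolerance = 0.01)

  expect_error(fit_decadal_trend(pts[1:3, ], include_baseline = FALSE),
               "at least 4")
})

test_that("trend fit supports tidy, glance and plotting", {
  agg <- tibble::tibble(decade = vcc_decades(),
                        mean = c(1.46, 1.75, 1.73, 0.7))
  fit <- fit_decadal_trend(agg)  # baseline point prepended -> 5 points
  td <- generics::tidy(fit)
  expect_equal(td$term, c("b0", "b1", "b2", "b3"))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, 5L)
  expect_gt(gl$r.squared, 0.5)
  p <- ggplot2::autoplot(vcc_aggregate(vcc_trajectories(tibble::tibble(
    fisher_id = "a", decade = vcc_decades(), fraction = c(0.4, 0.2, 0, -0.6)
  ))))
  expect_s3_class(p, "ggplot")
})

test_that("driver ranking counts fishers and breaks ties alphabetically", {
  iv <- tibble::tibble(
    fisher_id = c("a", "b", "c"),
    drivers = list(c("industrial_overfishing", "b_driver"),
                   c("industrial_overfishing", "a_driver"),
                   c("industrial_overfishing", "a_driver", "b_driver"))
  )
  rk <- driver_frequency(iv)
  expect_equal(rk$driver[1], "industrial_overfishing")
  expect_equal(rk$n[1], 3)
  expect_equal(rk$driver[2:3], c("a_driver", "b_driver"))  # tie: 2 each
  # duplicate labels within a fisher count once
  iv2 <- tibble::tibble(fisher_id = "a", drivers = list(rep("x", 3)))
  expect_equal(driver_frequency(iv2)$n, 1)
})
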