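rep_points <- function(years, coverage, country = "egy", vaccine = "dtp3",
                       source = "reported") {
  data.frame(country = country, vaccine = vaccine, year = as.integer(years),
             source = source, coverage = coverage, stringsAsFactors = FALSE)
}

no_decisions <- function() {
  data.frame(country = character(), vaccine = character(), year = integer(),
             action = character(), coverage = numeric(),
             explanation = character(), stringsAsFactors = FALSE)
}

decision <- function(action, year, coverage = NA_real_,
                     explanation = "Working-group rationale.",
                     country = "egy", vaccine = "dtp3") {
  data.frame(country = country, vaccine = vaccine, year = as.integer(year),
             action = action, coverage = coverage,
             explanation = explanation, stringsAsFactors = FALSE)
}

test_that("reported filters: plausible values accepted, >=100 excluded", {
  g <- filter_reported(rep_points(2004, 97), no_decisions())
  expect_equal(g$status, "accepted")
  g <- filter_reported(rep_points(2004:2006, c(99.9, 100, 104)),
                       no_decisions())
  expect_equal(g$status, c("accepted", "excluded", "excluded"))
  expect_equal(g$reason_code[2:3], c("ge100", "ge100"))
})

test_that("one-year spikes are excluded, and a decision reinstates them", {
  cfg <- wuenic_config(jump_threshold = 25)
  pts <- rep_points(2000:2002, c(90, 45, 92))
  g <- filter_reported(pts, no_decisions(), cfg)
  expect_equal(g$status, c("accepted", "excluded", "accepted"))
  expect_equal(g$reason_code[2], "spike")

  g2 <- filter_reported(pts, decision("acceptReported", 2001,
                                      explanation = "Genuine decline."), cfg)
  expect_equal(g2$status, rep("accepted", 3))
  expect_equal(g2$reason_text[2], "Genuine decline.")
})

test_that("sustained jumps are flagged by default, excluded when configured", {
  pts <- rep_points(2000:2003, c(50, 85, 86, 87))
  g <- filter_reported(pts, no_decisions())
  expect_equal(g$status, rep("accepted", 4))
  expect_equal(g$reason_code[1:2], c("jump_flagged", "jump_flagged"))
  g2 <- filter_reported(pts, no_decisions(),
                        wuenic_config(exclude_sustained_jumps = TRUE))
  expect_equal(g2$status, c("excluded", "excluded", "accepted", "accepted"))
})

test_that("ignoreReported dominates an otherwise-accepted point", {
  g <- filter_reported(rep_points(2004, 97),
                       decision("ignoreReported", 2004,
                                explanation = "Denominator problem."))
  expect_equal(g$status, "excluded")
  expect_equal(g$reason_text, "Denominator problem.")
})

test_that("coexisting sources resolve by precedence, others graded too", {
  pts <- rbind(rep_points(2004, 97, source = "admin"),
               rep_points(2004, 95, source = "gov"))
  g <- filter_reported(pts, no_decisions())
  expect_equal(nrow(g), 2)  # every input point graded exactly once
  expect_equal(g$status[g$ref == "gov"], "accepted")
  expect_equal(g$status[g$ref == "admin"], "excluded")
  expect_equal(g$reason_code[g$ref == "admin"], "superseded_source")
})

surv_fixture <- function(sample_size = 1000L, cohort = c(12L, 23L),
                         coverage = 80, vaccine = "dtp3",
                         evidence = NA_character_) {
  list(results = data.frame(survey_id = "s1", country = "egy",
                            vaccine = vaccine, cohort_year = 2004L,
                            coverage = coverage, evidence = evidence,
                            stringsAsFactors = FALSE),
       desc = data.frame(survey_id = "s1", title = "t", type = "DHS",
                         collection_year = 2006L, percent_cards_seen = 80,
                         confirmation_method = "either",
                         cohort_min_months = cohort[1],
                         cohort_max_months = cohort[2],
                         sample_size = sample_size,
                         stringsAsFactors = FALSE))
}

test_that("survey sample-size rule: strict <300, decisions dominate", {
  f <- surv_fixture(sample_size = 299L)
  f$results$evidence <- "either"
  g <- filter_surveys(f$results, f$desc, no_decisions())
  expect_equal(g$status, "excluded")
  expect_equal(g$reason_code, "small_sample")

  g2 <- filter_surveys(f$results, f$desc,
                       decision("acceptSurvey", 2004,
                                explanation = "Survey judged sound."))
  expect_equal(g2$status, "accepted")
  expect_equal(g2$reason_text, "Survey judged sound.")

  f300 <- surv_fixture(sample_size = 300L)
  f300$results$evidence <- "either"
  g3 <- filter_surveys(f300$results, f300$desc, no_decisions())
  expect_false(g3$reason_code == "small_sample")
  expect_equal(g3$status, "accepted")
})

test_that("surveys outside the valid age cohort are excluded", {
  f <- surv_fixture(cohort = c(6L, 11L))
  f$results$evidence <- "either"
  g <- filter_surveys(f$results, f$desc, no_decisions())
  expect_equal(g$status, "excluded")
  expect_equal(g$reason_code, "age_cohort")
})

test_that("ignoreSurvey excludes an otherwise-accepted survey", {
  f <- surv_fixture()
  g <- filter_surveys(f$results, f$desc,
                      decision("ignoreSurvey", 2004,
                               explanation = "Cards kept at clinics."))
  expect_equal(g$status, "excluded")
  expect_equal(g$reason_text, "Cards kept at clinics.")
})

test_that("recall bias: dose-1 ratio scales card-only multi-dose results", {
  # dtp3 card-only 80; dtp1 either 90, card-only 85 -> 80 * 90/85
  rows <- data.frame(
    survey_id = "s1", country = "egy",
    vaccine = c("dtp3", "dtp1", "dtp1"), cohort_year = 2004L,
    coverage = c(80, 90, 85), evidence = c("card", "either", "card"),
    stringsAsFactors = FALSE)
  adj <- adjust_recall_bias(rows[1, ], rows)
  expect_equal(adj$status, "modified")
  expect_equal(adj$adjusted_coverage, 80 * 90 / 85, tolerance = 1e-12)

  # dose 1 is never adjusted
  adj1 <- adjust_recall_bias(rows[2, ], rows)
  expect_equal(adj1$status, "accepted")
  expect_true(is.na(adj1$adjusted_coverage))

  # guards: no card-only dose-1 data, and zero card-only dose-1 coverage
  adj2 <- adjust_recall_bias(rows[1, ], rows[1:2, ])
  expect_equal(adj2$status, "accepted")
  expect_equal(adj2$reason_code, "no_recall_adjustment")
  rows0 <- rows; rows0$coverage[3] <- 0
  adj3 <- adjust_recall_bias(rows0[1, ], rows0)
  expect_equal(adj3$status, "accepted")
  expect_equal(adj3$reason_code, "no_recall_adjustment")
})

test_that("series completion: interpolation interior, nearest value outside", {
  g <- filter_reported(rep_points(c(2004, 2006), c(97, 85)), no_decisions())
  s <- complete_reported_series(g, 2003:2007)
  expect_equal(s$year, 2003:2007)
  expect_equal(s$coverage, c(97, 97, 91, 85, 85))
  expect_equal(s$origin, c("extrapolated", "reported", "interpolated",
                           "reported", "extrapolated"))

  g1 <- filter_reported(rep_points(2005, 96), no_decisions())
  s1 <- complete_reported_series(g1, 2004:2006)
  expect_equal(s1$coverage, c(96, 96, 96))

  g2 <- filter_reported(rep_points(2004:2006, c(90, 91, 92)), no_decisions())
  s2 <- complete_reported_series(g2, 2004:2006)
  expect_equal(s2$coverage, c(90, 91, 92))
  expect_equal(s2$origin, rep("reported", 3))

  # undefined when nothing accepted
  g3 <- filter_reported(rep_points(2004, 100), no_decisions())
  expect_null(complete_reported_series(g3, 2004))
})

test_that("interpolation follows the printed formula", {
  expect_equal(interpolate_coverage(2000, 80, 2004, 88, 2002), 84)
  expect_equal(interpolate_coverage(2004, 97, 2006, 85, 2005), 91)
  expect_equal(interpolate_coverage(2001, 77, 2009, 77, 2004), 77)
  expect_error(interpolate_coverage(2004, 97, 2006, 85, 2006))
})

test_that("interpolation matches a two-point line fit and stays bracketed", {
  set.seed(42)
  for (i in 1:1000) {
    y1 <- sample(1997:2005, 1); y2 <- y1 + sample(2:6, 1)
    p1 <- runif(1, 0, 100); p2 <- runif(1, 0, 100)
    ys <- (y1 + 1):(y2 - 1)
    y <- if (length(ys) == 1) ys else sample(ys, 1)
    got <- interpolate_coverage(y1, p1, y2, p2, y)
    oracle <- unname(stats::approx(c(y1, y2), c(p1, p2), xout = y)$y)
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_gte(got, min(p1, p2) - 1e-12)
    expect_lte(got, max(p1, p2) + 1e-12)
  }
})

test_that("grading partitions the input: every point appears exactly once", {
  for (seed in 1:20) {
    kb <- random_kb(seed, n_countries = 1, years = 2000:2009,
                    p_decision = 0.15)
    res <- suppressWarnings(wuenic_run(kb))
    expect_equal(nrow(res$audit), nrow(kb$reported) + nrow(kb$surveys))
    expect_true(all(res$audit$status %in%
                      c("accepted", "modified", "excluded")))
    expect_true(all(res$audit$adjusted_coverage[res$audit$status == "modified"]
                    >= 0))
    excl <- res$audit[res$audit$status == "excluded", ]
    expect_true(all(nzchar(excl$reason_text)))
  }
})
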