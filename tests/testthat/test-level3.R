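series_df <- function(years, coverage, origin = "reported") {
  data.frame(year = as.integer(years), coverage = coverage, origin = origin,
             stringsAsFactors = FALSE)
}

anchor_df <- function(year, resolution, coverage) {
  data.frame(country = "egy", vaccine = "dtp3", year = as.integer(year),
             resolution = resolution, coverage = coverage,
             reported_coverage = NA_real_, survey_coverage = NA_real_,
             explanation = NA_character_, stringsAsFactors = FALSE)
}

no_dec3 <- function() {
  data.frame(country = character(), vaccine = character(), year = integer(),
             action = character(), coverage = numeric(),
             explanation = character(), stringsAsFactors = FALSE)
}

test_that("single-source estimates pass the completed series through", {
  s <- series_df(2004:2005, c(97, 96))
  est <- estimate_single_source("egy", "dtp3", s, no_dec3(), 2004:2005)
  expect_equal(est$coverage_raw, c(97, 96))
  expect_equal(est$rule_code, c("R", "R"))

  s2 <- series_df(2004:2006, c(90, 92, 94), origin = c("reported",
                                                       "interpolated",
                                                       "reported"))
  est2 <- estimate_single_source("egy", "dtp3", s2, no_dec3(), 2004:2006)
  expect_equal(est2$rule_code, c("R", "I", "R"))
  expect_equal(est2$coverage_raw[2], 92)

  dec <- data.frame(country = "egy", vaccine = "dtp3", year = 2005L,
                    action = "assignWUENIC", coverage = 90,
                    explanation = "Assigned.", stringsAsFactors = FALSE)
  est3 <- estimate_single_source("egy", "dtp3", s, dec, 2004:2005)
  expect_equal(est3$coverage_raw[est3$year == 2005], 90)
  expect_equal(est3$rule_code[est3$year == 2005], "W")
  expect_equal(est3$explanation[est3$year == 2005], "Assigned.")
})

test_that("calibration: constant ratio from a single anchor", {
  seg <- series_df(2000:2002, c(90, 92, 94))
  a <- anchor_df(2002, "AP:S", 84.6)
  cal <- calibrate_segment(seg, a)
  expect_equal(cal$coverage, c(90, 92, 94) * 0.9, tolerance = 1e-12)
  expect_equal(cal$coverage[3], 84.6)   # anchor fidelity, exact
  expect_equal(cal$method, rep("ratio", 3))
})

test_that("calibration: blended ratios between two anchors; identity when both match", {
  seg <- series_df(2000:2004, c(80, 80, 80, 80, 80))
  a <- rbind(anchor_df(2000, "AP:S", 60), anchor_df(2004, "AP:R", 80))
  cal <- calibrate_segment(seg, a)
  lam <- (0:4) / 4
  expect_equal(cal$coverage, 80 * ((1 - lam) * 0.75 + lam * 1),
               tolerance = 1e-12)
  expect_equal(cal$coverage[c(1, 5)], c(60, 80))

  ident <- calibrate_segment(seg, rbind(anchor_df(2000, "AP:R", 80),
                                        anchor_df(2004, "AP:R", 80)))
  expect_equal(ident$coverage, seg$coverage)
})

test_that("calibration falls back to an additive shift at a zero denominator", {
  seg <- series_df(2000:2001, c(0, 40))
  a <- anchor_df(2000, "AP:S", 12)
  cal <- calibrate_segment(seg, a)
  expect_equal(cal$method, rep("shift", 2))
  expect_equal(cal$coverage, c(12, 52))
  expect_equal(cal$coverage[1], 12)     # anchor fidelity holds either way
})

test_that("between anchors: AP:R pairs pass reported through, others calibrate", {
  s <- series_df(2002:2005, c(76, 78, 80, 82))
  both_r <- rbind(anchor_df(2002, "AP:R", 76), anchor_df(2005, "AP:R", 82))
  est <- complete_between_anchors("egy", "dtp3", both_r, s, no_dec3(),
                                  2003:2004)
  expect_equal(est$coverage_raw, c(78, 80))
  expect_equal(est$rule_code, c("R", "R"))

  mixed <- rbind(anchor_df(2002, "AP:S", 62), anchor_df(2005, "AP:R", 82))
  est2 <- complete_between_anchors("egy", "dtp3", mixed, s, no_dec3(),
                                   2003:2004)
  r1 <- 62 / 76
  expect_equal(est2$coverage_raw,
               c(78 * (2 / 3 * r1 + 1 / 3), 80 * (1 / 3 * r1 + 2 / 3)),
               tolerance = 1e-12)
  expect_equal(est2$rule_code, c("C", "C"))

  # a decision-fixed anchor does not certify the reported series
  wmix <- rbind(anchor_df(2002, "AP:W", 70), anchor_df(2005, "AP:R", 82))
  est3 <- complete_between_anchors("egy", "dtp3", wmix, s, no_dec3(),
                                   2003:2004)
  expect_equal(est3$rule_code, c("C", "C"))
})

test_that("an interpolate decision replaces the span with a straight line", {
  s <- series_df(2002:2005, c(76, 10, 10, 82))
  anchors <- rbind(anchor_df(2002, "AP:R", 76), anchor_df(2005, "AP:R", 82))
  dec <- data.frame(country = "egy", vaccine = "dtp3", year = 2003L,
                    action = "interpolate", coverage = NA_real_,
                    explanation = "Reports unusable in between.",
                    stringsAsFactors = FALSE)
  est <- complete_between_anchors("egy", "dtp3", anchors, s, dec, 2003:2004)
  expect_equal(est$coverage_raw, c(78, 80))
  expect_equal(est$rule_code, c("W:I", "W:I"))
  expect_match(est$explanation[1], "Reports unusable in between",
               fixed = TRUE)
})

test_that("beyond anchors: passthrough after AP:R, calibration otherwise, E without reports", {
  s <- series_df(2000:2005, c(72, 74, 76, 78, 80, 80),
                 origin = c("reported", "reported", "reported", "reported",
                            "reported", "extrapolated"))
  anchors <- anchor_df(2002, "AP:S", 62)
  est <- complete_beyond_anchors("egy", "dtp3", anchors, s, no_dec3(),
                                 c(2000, 2001, 2003, 2004, 2005))
  r <- 62 / 76
  expect_equal(est$coverage_raw[est$year %in% 2000:2001], c(72, 74) * r,
               tolerance = 1e-12)
  expect_equal(est$rule_code[est$year %in% 2000:2001], c("C", "C"))
  # the report-less 2005 takes the value closest in time, scaled like it
  expect_equal(est$rule_code[est$year == 2005], "E")
  expect_equal(est$coverage_raw[est$year == 2005],
               est$coverage_raw[est$year == 2004])

  ap_r <- anchor_df(2004, "AP:R", 80)
  est2 <- complete_beyond_anchors("egy", "dtp3", ap_r, s, no_dec3(),
                                  c(2002, 2003, 2005))
  expect_equal(est2$coverage_raw, c(76, 78, 80))
  expect_equal(est2$rule_code, c("R", "R", "E"))
})

test_that("calibration approaches the reported series as anchors approach it", {
  seg <- series_df(2000:2002, c(90, 92, 94))
  for (eps in c(5, 1, 0.1, 0.001)) {
    cal <- calibrate_segment(seg, anchor_df(2002, "AP:S", 94 - eps))
    expect_lte(max(abs(cal$coverage - seg$coverage)), eps + 1e-12)
  }
})

test_that("anchor fidelity holds end to end on random knowledge bases", {
  for (seed in 1:15) {
    kb <- random_kb(seed, n_countries = 1, years = 2000:2009,
                    p_decision = 0.1)
    res <- suppressWarnings(wuenic_run(kb))
    for (i in seq_len(nrow(res$anchors))) {
      a <- res$anchors[i, ]
      if (!any(kb$required$country == a$country &
                 kb$required$vaccine == a$vaccine &
                 kb$required$year == a$year)) next
      e <- res$estimates[res$estimates$country == a$country &
                           res$estimates$vaccine == a$vaccine &
                           res$estimates$year == a$year, ]
      # reconciliation may overwrite a non-assigned dtp1 anchor
      if (e$rule_code == "RMF") next
      expect_equal(e$coverage_raw, a$coverage, tolerance = 1e-12)
    }
  }
})
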