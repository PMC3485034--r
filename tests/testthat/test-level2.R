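graded_rep <- function(year, coverage, status = "accepted") {
  data.frame(country = "egy", vaccine = "dtp3", year = as.integer(year),
             origin = "reported", ref = "reported", coverage = coverage,
             adjusted_coverage = NA_real_, status = status,
             reason_code = "accepted", reason_text = "ok",
             stringsAsFactors = FALSE)
}

graded_surv <- function(year, coverage, status = "accepted",
                        adjusted = NA_real_, id = "s1") {
  data.frame(country = "egy", vaccine = "dtp3", year = as.integer(year),
             origin = "survey", ref = paste0(id, "/either"),
             coverage = coverage, adjusted_coverage = adjusted,
             status = status, reason_code = "accepted", reason_text = "ok",
             stringsAsFactors = FALSE)
}

no_dec <- function() {
  data.frame(country = character(), vaccine = character(), year = integer(),
             action = character(), coverage = numeric(),
             explanation = character(), stringsAsFactors = FALSE)
}

test_that("survey support is a strict 10-point window", {
  expect_true(survey_supports_reported(93.5, 97))
  expect_false(survey_supports_reported(85, 97))
  expect_false(survey_supports_reported(80, 90))  # exactly 10 apart fails
  expect_true(survey_supports_reported(63.2, 63.2))
  expect_true(survey_supports_reported(90, 80.1))
})

test_that("anchor precedence: decision, then support, then survey", {
  a1 <- resolve_anchor("egy", "dtp3", 2004, graded_rep(2004, 97),
                       graded_surv(2004, 93.5), no_dec())
  expect_equal(a1$resolution, "AP:R")
  expect_equal(a1$coverage, 97)

  a2 <- resolve_anchor("egy", "dtp3", 2006, graded_rep(2006, 97),
                       graded_surv(2006, 85), no_dec())
  expect_equal(a2$resolution, "AP:S")
  expect_equal(a2$coverage, 85)

  dec <- data.frame(country = "egy", vaccine = "dtp3", year = 2007L,
                    action = "assignWUENIC", coverage = 94,
                    explanation = "Expert override.",
                    stringsAsFactors = FALSE)
  a3 <- resolve_anchor("egy", "dtp3", 2007, graded_rep(2007, 50),
                       graded_surv(2007, 20), dec)
  expect_equal(a3$resolution, "AP:W")
  expect_equal(a3$coverage, 94)
  expect_equal(a3$explanation, "Expert override.")
})

test_that("several same-year surveys are combined before the support test", {
  surv <- rbind(graded_surv(2004, 92, id = "s1"),
                graded_surv(2004, 84, id = "s2"))
  # unweighted mean 88, |88 - 97| = 9 < 10 -> supported
  a <- resolve_anchor("egy", "dtp3", 2004, graded_rep(2004, 97), surv,
                      no_dec())
  expect_equal(a$resolution, "AP:R")
  expect_equal(a$survey_coverage, 88)
  # a recall-adjusted value enters through its adjusted coverage
  surv$adjusted_coverage[2] <- 70; surv$status[2] <- "modified"
  a2 <- resolve_anchor("egy", "dtp3", 2004, graded_rep(2004, 97), surv,
                       no_dec())
  expect_equal(a2$survey_coverage, mean(c(92, 70)))
  expect_equal(a2$resolution, "AP:S")
})

test_that("sample-size weighting is available for same-year surveys", {
  cfg <- wuenic_config(survey_weighting = "sample_size")
  surv <- rbind(graded_surv(2004, 92, id = "s1"),
                graded_surv(2004, 84, id = "s2"))
  a <- resolve_anchor("egy", "dtp3", 2004, graded_rep(2004, 97), surv,
                      no_dec(), cfg, weights = c(3000, 1000))
  expect_equal(a$survey_coverage, (92 * 3000 + 84 * 1000) / 4000)
})

test_that("anchor years are the multi-source years plus decision years", {
  g_rep <- rbind(graded_rep(2004, 97), graded_rep(2005, 96),
                 graded_rep(2006, 95))
  g_sur <- rbind(graded_surv(2004, 93.5), graded_surv(2005, 95))
  a <- find_anchor_years(g_rep, g_sur, no_dec())
  expect_equal(a$year, c(2004L, 2005L))

  expect_equal(nrow(find_anchor_years(g_rep, g_sur[0, ], no_dec())), 0)

  dec <- data.frame(country = "egy", vaccine = "dtp3", year = 2006L,
                    action = "assignWUENIC", coverage = 90,
                    explanation = "Override with no survey.",
                    stringsAsFactors = FALSE)
  a2 <- find_anchor_years(g_rep, g_sur[0, ], dec)
  expect_equal(a2$year, 2006L)
  expect_equal(a2$resolution, "AP:W")

  # excluded points never create anchors
  g_rep2 <- graded_rep(2004, 100, status = "excluded")
  expect_equal(nrow(find_anchor_years(g_rep2, g_sur, no_dec())), 0)
})

test_that("exactly one resolution fires per anchor, independent of order", {
  for (seed in 1:25) {
    kb <- random_kb(seed, n_countries = 1, years = 2000:2008,
                    p_decision = 0.2)
    res <- suppressWarnings(wuenic_run(kb))
    expect_true(all(res$anchors$resolution %in% c("AP:R", "AP:S", "AP:W")))
    wgd <- kb$decisions[kb$decisions$action == "assignWUENIC", ]
    for (i in seq_len(nrow(wgd))) {
      sel <- res$anchors$country == wgd$country[i] &
        res$anchors$vaccine == wgd$vaccine[i] &
        res$anchors$year == wgd$year[i]
      expect_equal(res$anchors$resolution[sel], "AP:W")
      expect_equal(res$anchors$coverage[sel], wgd$coverage[i])
    }
  }
})
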