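# Synthetic knowledge bases with known ground truth: the Egypt worked
# examples, a 12-year scenario exercising every estimation behaviour, and
# a seeded random generator for property tests.

#' Egypt DTP3 worked-example knowledge base
#'
#' Builds the small Egypt DTP3 knowledge bases used throughout the
#' documentation and tests.  The \code{"base"} variant holds reported
#' coverage of 97 (2004) and 96 (2005) with survey results of 93.5 and 95
#' for the same birth cohorts; the surveys support the reports, so the
#' expected estimates are the reported values.  The \code{"y2006"} variant
#' has reported 97 against a survey of 85 (not supporting; the survey
#' value is the estimate), and the \code{"y2007"} variant carries a
#' working-group decision assigning 94, which overrides the data outright.
#'
#' @param variant one of \code{"base"}, \code{"y2006"}, \code{"y2007"}.
#' @param config a [wuenic_config()] list.
#' @return a \code{"wuenic_kb"} with attribute \code{"expected"}: the
#'   analytically derived estimates (country, vaccine, year, coverage,
#'   rule_code).
#' @export
#' @examples
#' kb <- egypt_fixture()
#' attr(kb, "expected")
egypt_fixture <- function(variant = c("base", "y2006", "y2007"),
                          config = wuenic_config()) {
  variant <- match.arg(variant)
  desc <- data.frame(survey_id = "egy_dhs", title = "Egypt DHS",
                     type = "DHS", collection_year = 2006L,
                     percent_cards_seen = 85, confirmation_method = "either",
                     cohort_min_months = 12L, cohort_max_months = 23L,
                     sample_size = 5000L, stringsAsFactors = FALSE)
  no_dec <- empty_table("decisions")
  kb <- switch(variant,
    base = {
      wuenic_kb(
        reported = data.frame(country = "egy", vaccine = "dtp3",
                              year = c(2004L, 2005L), source = "reported",
                              coverage = c(97, 96)),
        surveys = data.frame(survey_id = "egy_dhs", country = "egy",
                             vaccine = "dtp3", cohort_year = c(2004L, 2005L),
                             coverage = c(93.5, 95)),
        survey_descriptions = desc, decisions = no_dec,
        required = data.frame(country = "egy", vaccine = "dtp3",
                              year = c(2004L, 2005L)),
        config = config)
    },
    y2006 = {
      wuenic_kb(
        reported = data.frame(country = "egy", vaccine = "dtp3",
                              year = 2006L, source = "reported",
                              coverage = 97),
        surveys = data.frame(survey_id = "egy_dhs", country = "egy",
                             vaccine = "dtp3", cohort_year = 2006L,
                             coverage = 85),
        survey_descriptions = desc, decisions = no_dec,
        required = data.frame(country = "egy", vaccine = "dtp3",
                              year = 2006L),
        config = config)
    },
    y2007 = {
      wuenic_kb(
        reported = data.frame(country = "egy", vaccine = "dtp3",
                              year = 2007L, source = "reported",
                              coverage = 97),
        surveys = data.frame(survey_id = "egy_dhs", country = "egy",
                             vaccine = "dtp3", cohort_year = 2007L,
                             coverage = 90),
        survey_descriptions = desc,
        decisions = data.frame(
          country = "egy", vaccine = "dtp3", year = 2007L,
          action = "assignWUENIC", coverage = 94,
          explanation = paste("While the reported coverage seems to be",
                              "supported by survey results, the same survey",
                              "does not support the reported coverage for",
                              "other vaccines. The estimate is based on the",
                              "survey results.")),
        required = data.frame(country = "egy", vaccine = "dtp3",
                              year = 2007L),
        config = config)
    })
  attr(kb, "expected") <- switch(variant,
    base = data.frame(country = "egy", vaccine = "dtp3",
                      year = c(2004L, 2005L), coverage = c(97, 96),
                      rule_code = "AP:R", stringsAsFactors = FALSE),
    y2006 = data.frame(country = "egy", vaccine = "dtp3", year = 2006L,
                       coverage = 85, rule_code = "AP:S",
                       stringsAsFactors = FALSE),
    y2007 = data.frame(country = "egy", vaccine = "dtp3", year = 2007L,
                       coverage = 94, rule_code = "AP:W",
                       stringsAsFactors = FALSE))
  kb
}

#' Twelve-year scenario knowledge base
#'
#' A single-country DTP3 knowledge base constructed so that each year
#' 2000-2011 exercises one distinct estimation behaviour:
#' an under-powered survey in 2000 (n = 250, excluded), a 2002 survey that
#' does not support the reported data (anchor resolved to the survey),
#' supporting surveys in 2005 and 2009 (anchors resolved to reported
#' data), a genuine one-year collapse of reported coverage in 2007 that
#' the jump filter would exclude but a working-group decision reinstates,
#' and no report at all for 2011 (nearest-neighbour extrapolation).  The
#' numbers are synthetic; what the fixture pins down is which rule fires
#' in each year.
#'
#' @param config a [wuenic_config()] list.
#' @return a \code{"wuenic_kb"} with attribute \code{"expected_codes"}
#'   (year, rule_code) giving the rule expected to fire for every year.
#' @export
scenario_twelve_year <- function(config = wuenic_config()) {
  country <- "nar"
  rep_years <- 2000:2010
  rep_cov <- c(72, 74, 76, 78, 80, 82, 84, 50, 85, 87, 88)
  desc <- data.frame(
    survey_id = c("s2000", "s2002", "s2005", "s2009"),
    title = c("2000 EPI cluster survey", "2002 MICS", "2005 DHS",
              "2009 DHS"),
    type = c("EPI-cluster", "MICS", "DHS", "DHS"),
    collection_year = c(2001L, 2003L, 2006L, 2010L),
    percent_cards_seen = c(60, 75, 85, 88),
    confirmation_method = "either",
    cohort_min_months = 12L, cohort_max_months = 23L,
    sample_size = c(250L, 2500L, 4000L, 4500L),
    stringsAsFactors = FALSE)
  kb <- wuenic_kb(
    reported = data.frame(country = country, vaccine = "dtp3",
                          year = rep_years, source = "reported",
                          coverage = rep_cov),
    surveys = data.frame(survey_id = c("s2000", "s2002", "s2005", "s2009"),
                         country = country, vaccine = "dtp3",
                         cohort_year = c(2000L, 2002L, 2005L, 2009L),
                         coverage = c(70, 62, 80, 90)),
    survey_descriptions = desc,
    decisions = data.frame(
      country = country, vaccine = "dtp3", year = 2007L,
      action = "acceptReported", coverage = NA_real_,
      explanation = paste("The decline is not a reporting artefact but a",
                          "real decline in coverage due to a shortage of",
                          "vaccine.")),
    required = data.frame(country = country, vaccine = "dtp3",
                          year = 2000:2011),
    config = config)
  attr(kb, "expected_codes") <- data.frame(
    year = 2000:2011,
    rule_code = c("C", "C", "AP:S", "C", "C", "AP:R", "R", "R", "R",
                  "AP:R", "R", "E"),
    stringsAsFactors = FALSE)
  kb
}

#' Random knowledge-base generator
#'
#' Generates a reproducible knowledge base around latent true coverage
#' trajectories (bounded random walks), for property-style testing.
#' Reported coverage is truth plus a systematic bias and noise, surveys
#' are truth plus noise with sample sizes straddling the 300-child
#' exclusion boundary, and working-group decisions of every kind are
#' sprinkled in at a configurable rate, each with a synthetic explanation.
#' The latent truth is attached so recovery-style assertions are possible.
#'
#' @param seed integer seed; the same seed always yields the same
#'   knowledge base.
#' @param n_countries number of countries (codes \code{c01}, \code{c02},
#'   ...).
#' @param vaccines vaccine codes to simulate.
#' @param years calendar years (must lie in the configured window).
#' @param report_bias systematic over-reporting of administrative data, in
#'   percentage points.
#' @param report_noise_sd,survey_noise_sd noise standard deviations.
#' @param p_missing_report probability a year's report is absent.
#' @param p_survey probability a survey measures a given
#'   country/vaccine/year.
#' @param p_decision probability a key carries a working-group decision.
#' @param decision_actions pool of decision actions to draw from; set to
#'   \code{"assignWUENIC"} alone to make every decision an override.
#' @param config a [wuenic_config()] list.
#' @return a \code{"wuenic_kb"} with attribute \code{"truth"}: data frame
#'   (country, vaccine, year, truth).
#' @export
random_kb <- function(seed, n_countries = 2,
                      vaccines = c("dtp1", "dtp3", "mcv"),
                      years = 1997:2011, report_bias = 2,
                      report_noise_sd = 3, survey_noise_sd = 3,
                      p_missing_report = 0.1, p_survey = 0.25,
                      p_decision = 0.05,
                      decision_actions = c("assignWUENIC", "ignoreReported",
                                           "acceptReported", "ignoreSurvey",
                                           "acceptSurvey", "interpolate",
                                           "comment"),
                      config = wuenic_config()) {
  stopifnot(all(decision_actions %in% kb_actions),
            seed == floor(seed), n_countries >= 1, length(years) >= 2,
            all(vaccines %in% config$vaccines),
            all(years >= config$window[1] & years <= config$window[2]),
            p_missing_report >= 0, p_missing_report <= 1,
            p_survey >= 0, p_survey <= 1, p_decision >= 0, p_decision <= 1)
  set.seed(as.integer(seed))
  countries <- sprintf("c%02d", seq_len(n_countries))
  years <- sort(as.integer(years))

  truth <- list(); rep_rows <- list(); sur_rows <- list(); desc_rows <- list()
  dec_rows <- list()
  for (co in countries) for (v in vaccines) {
    walk <- numeric(length(years))
    walk[1] <- stats::runif(1, 50, 95)
    for (k in seq_along(years)[-1])
      walk[k] <- min(98, max(5, walk[k - 1] + stats::rnorm(1, 0, 3)))
    truth[[paste(co, v)]] <- data.frame(country = co, vaccine = v,
                                        year = years, truth = walk,
                                        stringsAsFactors = FALSE)
    present <- stats::runif(length(years)) >= p_missing_report
    if (any(present)) {
      rcov <- pmax(0, walk[present] + report_bias +
                     stats::rnorm(sum(present), 0, report_noise_sd))
      rep_rows[[paste(co, v)]] <- data.frame(
        country = co, vaccine = v, year = years[present],
        source = "reported", coverage = round(rcov, 1),
        stringsAsFactors = FALSE)
    }
    has_survey <- stats::runif(length(years)) < p_survey
    for (y in years[has_survey]) {
      sid <- sprintf("%s_%s_%d", co, v, y)
      scov <- clamp01(walk[years == y] + stats::rnorm(1, 0, survey_noise_sd))
      sur_rows[[sid]] <- data.frame(survey_id = sid, country = co,
                                    vaccine = v, cohort_year = y,
                                    coverage = round(scov, 1),
                                    stringsAsFactors = FALSE)
      desc_rows[[sid]] <- data.frame(
        survey_id = sid, title = paste("Synthetic survey", sid),
        type = sample(c("DHS", "MICS", "EPI-cluster", "other"), 1),
        collection_year = min(max(years), y + 2L),
        percent_cards_seen = round(stats::runif(1, 40, 95), 1),
        confirmation_method = "either",
        cohort_min_months = 12L,
        cohort_max_months = sample(c(23L, 23L, 23L, 71L), 1),
        sample_size = sample(c(150L, 250L, 299L, 300L, 600L, 1500L, 4000L),
                             1, prob = c(.08, .08, .08, .16, .2, .2, .2)),
        stringsAsFactors = FALSE)
    }
    has_dec <- stats::runif(length(years)) < p_decision
    for (y in years[has_dec]) {
      action <- sample(decision_actions, 1)
      dec_rows[[paste(co, v, y)]] <- data.frame(
        country = co, vaccine = v, year = y, action = action,
        coverage = if (action == "assignWUENIC")
          round(stats::runif(1, 20, 99), 1) else NA_real_,
        explanation = sprintf("Synthetic working-group decision (%s) for %s %s %d.",
                              action, co, v, y),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(rows, name) if (length(rows)) do.call(rbind, rows) else
    empty_table(name)
  kb <- wuenic_kb(
    reported = bind(rep_rows, "reported"),
    surveys = bind(sur_rows, "surveys"),
    survey_descriptions = bind(desc_rows, "survey_descriptions"),
    decisions = bind(dec_rows, "decisions"),
    required = expand.grid(country = countries, vaccine = vaccines,
                           year = years, KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE),
    config = config)
  attr(kb, "truth") <- do.call(rbind, truth)
  kb
}
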