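# Level 1: accept, modify or exclude each reported and survey data point,
# then complete the reported time series per country/vaccine.

graded_point <- function(country, vaccine, year, origin, ref, coverage,
                         status, reason_code, reason_text,
                         adjusted_coverage = NA_real_) {
  data.frame(country = country, vaccine = vaccine, year = as.integer(year),
             origin = origin, ref = ref, coverage = coverage,
             adjusted_coverage = adjusted_coverage, status = status,
             reason_code = reason_code, reason_text = reason_text,
             stringsAsFactors = FALSE)
}

empty_graded <- function() {
  graded_point(character(), character(), integer(), character(), character(),
               numeric(), character(), character(), character(), numeric())
}

# The coverage a graded point contributes downstream (adjusted if modified).
graded_value <- function(graded) {
  ifelse(graded$status == "modified", graded$adjusted_coverage,
         graded$coverage)
}

decision_rows <- function(decisions, country, vaccine, action,
                          year = NULL) {
  sel <- decisions$country == country & decisions$vaccine == vaccine &
    decisions$action == action
  if (!is.null(year)) sel <- sel & decisions$year == year
  decisions[sel, , drop = FALSE]
}

# Parse a vaccine-dose code: trailing digits are the dose index, anything
# else is a single-dose antigen (dose 1).
vaccine_dose <- function(vaccine) {
  m <- regmatches(vaccine, regexpr("[0-9]+$", vaccine))
  if (length(m) && nzchar(m)) as.integer(m) else 1L
}

vaccine_base <- function(vaccine) sub("[0-9]+$", "", vaccine)

#' Grade reported coverage points
#'
#' Passes each reported data point for one country/vaccine through the
#' exclusion filters: implausible coverage (>= 100 percent), one-year
#' spikes larger than the configured jump threshold, and lower-precedence
#' duplicate sources.  Working-group decisions are applied last so they
#' always dominate: an \code{acceptReported} decision reinstates an
#' otherwise-excluded point, an \code{ignoreReported} decision excludes an
#' otherwise-accepted one, each carrying the decision's explanation.
#'
#' @param points rows of the knowledge base \code{reported} table, all for
#'   the same country and vaccine.
#' @param decisions the knowledge base \code{decisions} table.
#' @param config a [wuenic_config()] list.
#' @return a graded-point data frame: one row per input point with
#'   \code{status} (accepted/modified/excluded), \code{reason_code} and
#'   \code{reason_text}.
#' @export
filter_reported <- function(points, decisions, config = wuenic_config()) {
  if (!nrow(points)) return(empty_graded())
  stopifnot(length(unique(points$country)) == 1,
            length(unique(points$vaccine)) == 1)
  country <- points$country[1]; vaccine <- points$vaccine[1]

  points <- sort_df(points, c("year", "source"))
  prec <- match(points$source, config$source_precedence)
  prec[is.na(prec)] <- length(config$source_precedence) + 1L
  # one candidate point per year, chosen by source precedence
  keep <- !logical(nrow(points))
  for (y in unique(points$year)) {
    idx <- which(points$year == y)
    if (length(idx) > 1) keep[idx[-which.min(prec[idx])]] <- FALSE
  }

  g <- graded_point(country, vaccine, points$year, "reported", points$source,
                    points$coverage, status = "accepted",
                    reason_code = "accepted", reason_text = "Reported data accepted.")
  g$status[!keep] <- "excluded"
  g$reason_code[!keep] <- "superseded_source"
  g$reason_text[!keep] <-
    "Superseded by a higher-precedence source for the same year."

  ge100 <- keep & g$coverage >= 100
  g$status[ge100] <- "excluded"
  g$reason_code[ge100] <- "ge100"
  g$reason_text[ge100] <-
    "Reported coverage of 100% or more excluded as implausible."

  # jump filter on the surviving per-year series, consecutive calendar years
  alive <- which(g$status == "accepted")
  if (length(alive) >= 2) {
    yrs <- g$year[alive]; val <- g$coverage[alive]
    thr <- config$jump_threshold
    d <- ifelse(diff(yrs) == 1, diff(val), NA_real_)  # NA across gaps
    spike <- logical(length(alive))
    if (length(alive) >= 3)
      for (i in 2:(length(alive) - 1))
        spike[i] <- !is.na(d[i - 1]) && !is.na(d[i]) &&
          abs(d[i - 1]) > thr && abs(d[i]) > thr &&
          sign(d[i - 1]) != sign(d[i])
    for (i in which(spike)) {
      j <- alive[i]
      g$status[j] <- "excluded"; g$reason_code[j] <- "spike"
      g$reason_text[j] <- sprintf(
        "One-year spike: coverage changes by more than %g points against both neighbouring years.",
        thr)
    }
    # sustained jumps (no recovery) flank two years; flagged, excluded only
    # when configured
    for (i in seq_along(d)) {
      if (is.na(d[i]) || abs(d[i]) <= thr) next
      if (spike[i] || spike[i + 1]) next      # already attributed to a spike
      for (j in alive[c(i, i + 1)]) {
        if (g$status[j] != "accepted") next
        if (config$exclude_sustained_jumps) {
          g$status[j] <- "excluded"; g$reason_code[j] <- "jump"
          g$reason_text[j] <- sprintf(
            "Adjacent to a sustained change of more than %g points.", thr)
        } else {
          g$reason_code[j] <- "jump_flagged"
          g$reason_text[j] <- sprintf(
            "Accepted but flagged: adjacent to a change of more than %g points.",
            thr)
        }
      }
    }
  }

  # decisions are evaluated last so they dominate every filter
  for (i in seq_len(nrow(g))) {
    if (g$reason_code[i] == "superseded_source") next
    acc <- decision_rows(decisions, country, vaccine, "acceptReported",
                         g$year[i])
    ign <- decision_rows(decisions, country, vaccine, "ignoreReported",
                         g$year[i])
    if (nrow(ign)) {
      g$status[i] <- "excluded"; g$reason_code[i] <- "wgd_ignore"
      g$reason_text[i] <- ign$explanation[1]
    } else if (nrow(acc)) {
      g$status[i] <- "accepted"; g$reason_code[i] <- "wgd_accept"
      g$reason_text[i] <- acc$explanation[1]
    }
  }
  g
}

#' Grade survey results
#'
#' Applies the survey exclusion filters for one country/vaccine: sample
#' sizes below the configured minimum and age cohorts outside the valid
#' range are excluded; where one survey reports both a card-only and a
#' card-or-history figure for the same vaccine, the redundant row is set
#' aside so each survey contributes one result.  \code{acceptSurvey} and
#' \code{ignoreSurvey} decisions are applied last and dominate the
#' filters.  Survivors of multi-dose antigens are then passed through
#' [adjust_recall_bias()].
#'
#' @param results rows of the knowledge base \code{surveys} table, all for
#'   one country and vaccine.
#' @param descriptions the \code{survey_descriptions} table.
#' @param decisions the \code{decisions} table.
#' @param config a [wuenic_config()] list.
#' @param all_results all survey rows for the same country (any vaccine),
#'   used by the recall-bias adjustment to locate dose-1 coverages from the
#'   same survey; defaults to \code{results}.
#' @return a graded-point data frame (origin \code{"survey"}; \code{ref} is
#'   \code{survey_id/evidence}).
#' @export
filter_surveys <- function(results, descriptions, decisions,
                           config = wuenic_config(), all_results = results) {
  if (!nrow(results)) return(empty_graded())
  stopifnot(length(unique(results$country)) == 1,
            length(unique(results$vaccine)) == 1)
  country <- results$country[1]; vaccine <- results$vaccine[1]
  results <- sort_df(results, c("cohort_year", "survey_id", "evidence"))

  di <- match(results$survey_id, descriptions$survey_id)
  if (anyNA(di)) stop("survey result references unknown survey_id: ",
                      paste(unique(results$survey_id[is.na(di)]), collapse = ", "),
                      call. = FALSE)
  desc <- descriptions[di, , drop = FALSE]

  g <- graded_point(country, vaccine, results$cohort_year, "survey",
                    paste(results$survey_id, results$evidence, sep = "/"),
                    results$coverage, status = "accepted",
                    reason_code = "accepted",
                    reason_text = "Survey result accepted.")

  small <- desc$sample_size < config$min_sample_size
  g$status[small] <- "excluded"
  g$reason_code[small] <- "small_sample"
  g$reason_text[small] <- sprintf(
    "Survey sample size %d below the minimum of %d children.",
    desc$sample_size[small], as.integer(config$min_sample_size))

  bad_cohort <- desc$cohort_min_months < config$cohort_min_months |
    desc$cohort_max_months > config$cohort_max_months
  sel <- bad_cohort & g$status == "accepted"
  g$status[sel] <- "excluded"
  g$reason_code[sel] <- "age_cohort"
  g$reason_text[sel] <- sprintf(
    "Survey age cohort %d-%d months outside the valid range %d-%d months.",
    desc$cohort_min_months[sel], desc$cohort_max_months[sel],
    as.integer(config$cohort_min_months), as.integer(config$cohort_max_months))

  # where one survey carries both evidence bases for the same vaccine, keep
  # the headline row: card-or-history for dose 1, card-only (to be
  # recall-adjusted) for later doses
  dose <- vaccine_dose(vaccine)
  grp <- paste(results$survey_id, results$cohort_year)
  for (gkey in unique(grp)) {
    idx <- which(grp == gkey & g$status == "accepted")
    if (length(idx) < 2) next
    ev <- results$evidence[idx]
    if (!all(c("card", "either") %in% ev)) next
    drop_ev <- if (dose > 1) "either" else "card"
    j <- idx[ev == drop_ev]
    g$status[j] <- "excluded"
    g$reason_code[j] <- "redundant_evidence"
    g$reason_text[j] <- if (dose > 1)
      "Card-or-history row set aside in favour of the recall-adjusted card-only result." else
      "Card-only row retained only to support recall-bias adjustment."
  }

  for (i in seq_len(nrow(g))) {
    if (g$reason_code[i] == "redundant_evidence") next
    acc <- decision_rows(decisions, country, vaccine, "acceptSurvey",
                         g$year[i])
    ign <- decision_rows(decisions, country, vaccine, "ignoreSurvey",
                         g$year[i])
    if (nrow(ign)) {
      g$status[i] <- "excluded"; g$reason_code[i] <- "wgd_ignore"
      g$reason_text[i] <- ign$explanation[1]
    } else if (nrow(acc) && g$status[i] == "excluded") {
      g$status[i] <- "accepted"; g$reason_code[i] <- "wgd_accept"
      g$reason_text[i] <- acc$explanation[1]
    }
  }

  # recall-bias adjustment for accepted multi-dose results
  for (i in which(g$status == "accepted")) {
    adj <- adjust_recall_bias(results[i, , drop = FALSE], all_results, config)
    g$status[i] <- adj$status
    g$adjusted_coverage[i] <- adj$adjusted_coverage
    if (adj$status == "modified" ||
        (adj$reason_code == "no_recall_adjustment" &&
           g$reason_code[i] == "accepted")) {
      g$reason_code[i] <- adj$reason_code
      g$reason_text[i] <- adj$reason_text
    }
  }
  g
}

#' Recall-bias adjustment for multi-dose antigens
#'
#' Caretaker recall under-reports later doses of a multi-dose series.  When
#' a survey's dose-k result (k > 1) is a card-only figure and the same
#' survey also reports the dose-1 coverage both by card-or-history and by
#' card only, the dose-k result is scaled by the dose-1 ratio:
#' \deqn{P_k' = P_k^{card} \times P_1^{either} / P_1^{card}}
#' In every other situation (dose 1, missing dose-1 figures, card-only
#' dose-1 coverage of zero) the result is accepted unchanged and the
#' missing-data reason is recorded.
#'
#' @param result one row of the \code{surveys} table (the dose-k result).
#' @param all_results all survey rows from the same country, searched for
#'   the dose-1 figures of the same survey and birth cohort.
#' @param config a [wuenic_config()] list (unused thresholds reserved).
#' @return one graded-point row with status \code{"modified"} (and
#'   \code{adjusted_coverage}) or \code{"accepted"}.
#' @export
adjust_recall_bias <- function(result, all_results, config = wuenic_config()) {
  stopifnot(nrow(result) == 1)
  out <- graded_point(result$country, result$vaccine, result$cohort_year,
                      "survey",
                      paste(result$survey_id, result$evidence, sep = "/"),
                      result$coverage, status = "accepted",
                      reason_code = "accepted",
                      reason_text = "Survey result accepted.")
  dose <- vaccine_dose(result$vaccine)
  if (dose == 1L) return(out)
  no_adjust <- function(txt) {
    out$reason_code <- "no_recall_adjustment"
    out$reason_text <- paste("Insufficient data for recall adjustment:", txt)
    out
  }
  if (is.na(result$evidence) || result$evidence != "card")
    return(no_adjust("dose result is not a card-only figure."))
  dose1 <- paste0(vaccine_base(result$vaccine), 1)
  same <- all_results[all_results$survey_id == result$survey_id &
                        all_results$cohort_year == result$cohort_year &
                        all_results$vaccine == dose1, , drop = FALSE]
  e1 <- same$coverage[same$evidence == "either"]
  c1 <- same$coverage[same$evidence == "card"]
  if (!length(e1) || !length(c1))
    return(no_adjust("dose-1 card-only and card-or-history coverages not both available."))
  if (c1[1] <= 0)
    return(no_adjust("dose-1 card-only coverage is zero."))
  out$status <- "modified"
  out$adjusted_coverage <- min(100, result$coverage * e1[1] / c1[1])
  out$reason_code <- "recall_adjusted"
  out$reason_text <- sprintf(
    "Recall-bias adjustment: %.4g x (%.4g / %.4g) = %.4g.",
    result$coverage, e1[1], c1[1], out$adjusted_coverage)
  out
}

#' Complete the reported time series
#'
#' Builds a coverage value for every required year from the accepted
#' reported points: accepted years keep their value exactly, interior gaps
#' are filled by linear interpolation ([interpolate_coverage()]), and years
#' before the earliest or after the latest accepted point take the nearest
#' accepted value (nearest-neighbour extrapolation).
#'
#' @param graded graded reported points for one country/vaccine (output of
#'   [filter_reported()]).
#' @param required_years integer years the series must cover.
#' @return a data frame (year, coverage, origin) with origin one of
#'   \code{"reported"}, \code{"interpolated"}, \code{"extrapolated"}; or
#'   \code{NULL} when no point is accepted (the series is undefined).
#' @export
complete_reported_series <- function(graded, required_years) {
  acc <- graded[graded$status == "accepted" & graded$origin == "reported", ,
                drop = FALSE]
  if (!nrow(acc)) return(NULL)
  acc <- acc[order(acc$year), , drop = FALSE]
  years <- sort(unique(c(as.integer(required_years), acc$year)))
  cov <- numeric(length(years)); origin <- character(length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    if (y %in% acc$year) {
      cov[k] <- acc$coverage[acc$year == y]; origin[k] <- "reported"
    } else if (y < min(acc$year)) {
      cov[k] <- acc$coverage[1]; origin[k] <- "extrapolated"
    } else if (y > max(acc$year)) {
      cov[k] <- acc$coverage[nrow(acc)]; origin[k] <- "extrapolated"
    } else {
      before <- max(acc$year[acc$year < y]); after <- min(acc$year[acc$year > y])
      cov[k] <- interpolate_coverage(before, acc$coverage[acc$year == before],
                                     after, acc$coverage[acc$year == after], y)
      origin[k] <- "interpolated"
    }
  }
  data.frame(year = years, coverage = cov, origin = origin,
             stringsAsFactors = FALSE)
}
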