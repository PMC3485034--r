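# Level 2: resolve anchor points at years with more than one source of
# data, honouring working-group overrides via deterministic precedence.

#' Does a survey result support the reported coverage?
#'
#' True iff the absolute difference between survey and reported coverage is
#' strictly below the support threshold (default 10 percentage points).
#'
#' @param p_surv survey coverage, percentage points.
#' @param p_rpt reported coverage, percentage points.
#' @param config a [wuenic_config()] list.
#' @return logical.
#' @export
#' @examples
#' survey_supports_reported(93.5, 97)  # TRUE
#' survey_supports_reported(85, 97)    # FALSE
#' survey_supports_reported(80, 90)    # FALSE: difference of exactly 10
survey_supports_reported <- function(p_surv, p_rpt,
                                     config = wuenic_config()) {
  stopifnot(is.finite(p_surv), is.finite(p_rpt))
  abs(p_surv - p_rpt) < config$support_threshold
}

# Combine the accepted/adjusted survey coverages observed at one year into
# a single value: unweighted mean by default, sample-size weighted when
# configured.
anchor_survey_value <- function(survey_rows, config, weights = NULL) {
  v <- graded_value(survey_rows)
  if (!length(v)) return(NA_real_)
  if (config$survey_weighting == "sample_size" && !is.null(weights) &&
      length(weights) == length(v) && sum(weights) > 0)
    sum(v * weights) / sum(weights)
  else mean(v)
}

empty_anchors <- function() {
  data.frame(country = character(), vaccine = character(), year = integer(),
             resolution = character(), coverage = numeric(),
             reported_coverage = numeric(), survey_coverage = numeric(),
             explanation = character(), stringsAsFactors = FALSE)
}

anchor_row <- function(country, vaccine, year, resolution, coverage,
                       reported_coverage = NA_real_,
                       survey_coverage = NA_real_,
                       explanation = NA_character_) {
  data.frame(country = country, vaccine = vaccine, year = as.integer(year),
             resolution = resolution, coverage = coverage,
             reported_coverage = reported_coverage,
             survey_coverage = survey_coverage, explanation = explanation,
             stringsAsFactors = FALSE)
}

#' Resolve one anchor point
#'
#' Applies the anchor precedence for one country/vaccine/year:
#' \enumerate{
#'   \item an \code{assignWUENIC} working-group decision fixes the estimate
#'     (\code{AP:W}) — the closed-world guard \emph{no decision exists} on
#'     the data-driven rules is realized as this if/else order;
#'   \item otherwise, if the survey value supports the reported coverage
#'     ([survey_supports_reported()]), the estimate is the reported
#'     coverage (\code{AP:R});
#'   \item otherwise the estimate is the survey value (\code{AP:S}).
#' }
#' When several surveys fall in the same year their accepted (or
#' recall-adjusted) coverages are combined before the support test.
#'
#' @param country,vaccine,year the key.
#' @param reported_row the accepted graded reported point for the key (one
#'   row), or \code{NULL} for a decision-only anchor.
#' @param survey_rows accepted/modified graded survey points for the key
#'   (possibly zero rows).
#' @param decisions the decisions table.
#' @param config a [wuenic_config()] list.
#' @param weights optional survey sample sizes aligned with
#'   \code{survey_rows} (used only under sample-size weighting).
#' @return a one-row anchor data frame (resolution, coverage, supporting
#'   values, explanation).
#' @export
resolve_anchor <- function(country, vaccine, year, reported_row, survey_rows,
                           decisions, config = wuenic_config(),
                           weights = NULL) {
  p_surv <- anchor_survey_value(survey_rows, config, weights)
  p_rpt <- if (!is.null(reported_row) && nrow(reported_row))
    reported_row$coverage[1] else NA_real_
  wgd <- decision_rows(decisions, country, vaccine, "assignWUENIC", year)
  if (nrow(wgd))
    return(anchor_row(country, vaccine, year, "AP:W", wgd$coverage[1],
                      p_rpt, p_surv, wgd$explanation[1]))
  if (is.na(p_rpt) || is.na(p_surv))
    stop("anchor at ", paste(country, vaccine, year),
         " needs accepted reported data and at least one accepted survey",
         call. = FALSE)
  if (survey_supports_reported(p_surv, p_rpt, config))
    anchor_row(country, vaccine, year, "AP:R", p_rpt, p_rpt, p_surv)
  else
    anchor_row(country, vaccine, year, "AP:S", p_surv, p_rpt, p_surv)
}

#' Find and resolve all anchor years for one country/vaccine
#'
#' Anchor years are the years with both an accepted reported point and at
#' least one accepted survey result, plus every year carrying an
#' \code{assignWUENIC} decision (an anchor by fiat).  Each is resolved with
#' [resolve_anchor()]; the result is sorted by year.
#'
#' @param graded_reported graded reported points ([filter_reported()]).
#' @param graded_surveys graded survey points ([filter_surveys()]).
#' @param decisions the decisions table.
#' @param config a [wuenic_config()] list.
#' @param sample_sizes optional named lookup \code{survey_id -> sample size}
#'   for sample-size weighting.
#' @return an anchor data frame, zero rows when the country/vaccine has no
#'   multi-source years and no assign decisions.
#' @export
find_anchor_years <- function(graded_reported, graded_surveys, decisions,
                              config = wuenic_config(), sample_sizes = NULL) {
  if (nrow(graded_reported)) {
    country <- graded_reported$country[1]; vaccine <- graded_reported$vaccine[1]
  } else if (nrow(graded_surveys)) {
    country <- graded_surveys$country[1]; vaccine <- graded_surveys$vaccine[1]
  } else {
    dec <- decisions[decisions$action == "assignWUENIC", , drop = FALSE]
    if (!nrow(dec)) return(empty_anchors())
    country <- dec$country[1]; vaccine <- dec$vaccine[1]
  }
  rep_acc <- graded_reported[graded_reported$status == "accepted", ,
                             drop = FALSE]
  sur_acc <- graded_surveys[graded_surveys$status %in% c("accepted", "modified"), ,
                            drop = FALSE]
  wgd_years <- decision_rows(decisions, country, vaccine, "assignWUENIC")$year
  years <- sort(unique(c(intersect(rep_acc$year, sur_acc$year), wgd_years)))
  out <- lapply(years, function(y) {
    srows <- sur_acc[sur_acc$year == y, , drop = FALSE]
    w <- if (!is.null(sample_sizes) && nrow(srows))
      unname(sample_sizes[sub("/.*$", "", srows$ref)]) else NULL
    rrow <- rep_acc[rep_acc$year == y, , drop = FALSE]
    resolve_anchor(country, vaccine, y,
                   if (nrow(rrow)) rrow[1, , drop = FALSE] else NULL,
                   srows, decisions, config, w)
  })
  if (!length(out)) return(empty_anchors())
  do.call(rbind, out)
}
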