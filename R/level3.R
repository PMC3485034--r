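# Level 3: estimates for every required year between and beyond anchor
# points, and the single-source (reported-only) case.

est_row <- function(country, vaccine, year, coverage_raw, rule_code,
                    explanation) {
  data.frame(country = country, vaccine = vaccine, year = as.integer(year),
             coverage_raw = coverage_raw, rule_code = rule_code,
             explanation = explanation, stringsAsFactors = FALSE)
}

empty_estimates <- function() {
  est_row(character(), character(), integer(), numeric(), character(),
          character())
}

series_at <- function(series, year) series$coverage[match(year, series$year)]

series_code <- function(series, year) {
  switch(series$origin[match(year, series$year)],
         reported = "R", interpolated = "I", extrapolated = "E")
}

# Human wording for an anchor when naming it in explanations.
anchor_noun <- function(resolution) {
  switch(resolution, "AP:R" = "reported", "AP:S" = "survey",
         "AP:W" = "working-group")
}

#' Estimates from a single data source
#'
#' When a country/vaccine has no anchor points (reported data are the only
#' source), the estimates are the completed reported time series itself:
#' rule code \code{R} at reported years, \code{I} at interpolated years,
#' \code{E} at extrapolated years.  An \code{assignWUENIC} decision still
#' overrides its year (code \code{W}).
#'
#' @param country,vaccine the series key.
#' @param series completed reported series ([complete_reported_series()]).
#' @param decisions the decisions table.
#' @param required_years years to emit estimates for.
#' @param config a [wuenic_config()] list.
#' @return an estimates data frame (unrounded \code{coverage_raw}).
#' @export
estimate_single_source <- function(country, vaccine, series, decisions,
                                   required_years,
                                   config = wuenic_config()) {
  required_years <- sort(unique(as.integer(required_years)))
  if (is.null(series) || !nrow(series)) return(empty_estimates())
  out <- lapply(required_years, function(y) {
    wgd <- decision_rows(decisions, country, vaccine, "assignWUENIC", y)
    if (nrow(wgd))
      return(est_row(country, vaccine, y, wgd$coverage[1], "W",
                     wgd$explanation[1]))
    code <- series_code(series, y)
    est_row(country, vaccine, y, series_at(series, y), code,
            explain_rule(code, year = nearest_reported_year(series, y)))
  })
  do.call(rbind, out)
}

nearest_reported_year <- function(series, year) {
  rep_years <- series$year[series$origin == "reported"]
  if (!length(rep_years)) return(year)
  rep_years[which.min(abs(rep_years - year))]
}

#' Calibrate a reported-series segment to anchor estimates
#'
#' Scales the completed reported series so that it passes exactly through
#' the anchor estimates.  With two anchors the per-anchor ratios (anchor
#' estimate over reported value at the anchor year) are blended linearly in
#' time; with a single anchor the one constant ratio applies.  If a
#' reported value at an anchor year is zero the ratio is undefined and the
#' calibration falls back to an additive shift (differences instead of
#' ratios); the additive form can also be selected in the configuration.
#' Results are clamped to [0, 100].
#'
#' @param segment rows of a completed reported series (year, coverage,
#'   origin) covering the years to calibrate.
#' @param anchors one or two anchor rows whose years are present in
#'   \code{segment}.
#' @param config a [wuenic_config()] list.
#' @return \code{segment} with calibrated \code{coverage} and an added
#'   \code{method} column (\code{"ratio"} or \code{"shift"}).
#' @export
calibrate_segment <- function(segment, anchors, config = wuenic_config()) {
  stopifnot(nrow(anchors) >= 1, nrow(anchors) <= 2)
  anchors <- anchors[order(anchors$year), , drop = FALSE]
  denom <- series_at(segment, anchors$year)
  if (anyNA(denom))
    stop("segment does not cover the anchor year(s)", call. = FALSE)
  additive <- config$calibration == "additive" || any(denom == 0)
  method <- if (additive) "shift" else "ratio"
  factors <- if (additive) anchors$coverage - denom else anchors$coverage / denom
  f <- if (nrow(anchors) == 1) {
    rep(factors, nrow(segment))
  } else if (anchors$year[1] == anchors$year[2]) {
    rep(mean(factors), nrow(segment))
  } else {
    lambda <- (segment$year - anchors$year[1]) /
      (anchors$year[2] - anchors$year[1])
    lambda <- pmin(1, pmax(0, lambda))
    (1 - lambda) * factors[1] + lambda * factors[2]
  }
  segment$coverage <- clamp01(if (additive) segment$coverage + f
                              else segment$coverage * f)
  segment$method <- method
  segment
}

interpolate_decision_for <- function(decisions, country, vaccine, y1, y2) {
  dec <- decision_rows(decisions, country, vaccine, "interpolate")
  dec <- dec[dec$year >= y1 & dec$year <= y2, , drop = FALSE]
  if (nrow(dec)) dec[1, , drop = FALSE] else NULL
}

#' Estimates between adjacent anchor points
#'
#' For each pair of adjacent anchors: if both are resolved to reported data
#' (\code{AP:R}) the surveys certify the reported series and the estimates
#' between them are the reported series itself (code \code{R}/\code{I});
#' otherwise the reported series is calibrated to the two anchor estimates
#' ([calibrate_segment()], code \code{C}).  A working-group
#' \code{interpolate} decision falling in the span replaces either
#' behaviour with straight-line interpolation between the two anchor
#' estimates (code \code{W:I}).  A decision-fixed anchor (\code{AP:W}) does
#' not certify the reported series and behaves like \code{AP:S} here.
#'
#' @param country,vaccine the key.
#' @param anchors resolved anchors ([find_anchor_years()]), at least two
#'   rows.
#' @param series completed reported series.
#' @param decisions the decisions table.
#' @param required_years years for which estimates are wanted.
#' @param config a [wuenic_config()] list.
#' @return estimates data frame for the required years strictly between
#'   anchors.
#' @export
complete_between_anchors <- function(country, vaccine, anchors, series,
                                     decisions, required_years,
                                     config = wuenic_config()) {
  anchors <- anchors[order(anchors$year), , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(anchors) - 1)) {
    a1 <- anchors[k, ]; a2 <- anchors[k + 1, ]
    years <- intersect(seq(a1$year + 1, length.out = max(0, a2$year - a1$year - 1)),
                       required_years)
    if (!length(years)) next
    wdec <- interpolate_decision_for(decisions, country, vaccine,
                                     a1$year, a2$year)
    if (!is.null(wdec)) {
      vals <- vapply(years, function(y)
        interpolate_coverage(a1$year, a1$coverage, a2$year, a2$coverage, y),
        numeric(1))
      out[[length(out) + 1]] <- est_row(country, vaccine, years, vals, "W:I",
                                        explain_rule("W:I", y1 = a1$year,
                                                     y2 = a2$year,
                                                     text = wdec$explanation[1]))
    } else if (a1$resolution == "AP:R" && a2$resolution == "AP:R") {
      codes <- vapply(years, function(y) series_code(series, y), character(1))
      out[[length(out) + 1]] <- est_row(
        country, vaccine, years, series_at(series, years), codes,
        explain_rule("R", anchor_years = c(a1$year, a2$year)))
    } else {
      seg <- series[series$year >= a1$year & series$year <= a2$year, ,
                    drop = FALSE]
      cal <- calibrate_segment(seg, rbind(a1, a2), config)
      out[[length(out) + 1]] <- est_row(
        country, vaccine, years, cal$coverage[match(years, cal$year)], "C",
        explain_rule("C", anchors = rbind(a1, a2)))
    }
  }
  if (!length(out)) return(empty_estimates())
  do.call(rbind, out)
}

#' Estimates beyond the earliest and latest anchor points
#'
#' Years before the earliest anchor follow the reported series when that
#' anchor is resolved to reported data (\code{AP:R}); otherwise they are
#' the reported series calibrated to the anchor estimate by a constant
#' ratio (code \code{C}).  The years after the latest anchor are handled
#' symmetrically.  Years with no reported data at all take the value
#' closest in time (nearest-neighbour extrapolation, code \code{E}).
#'
#' @inheritParams complete_between_anchors
#' @return estimates data frame for the required years outside the anchor
#'   range.
#' @export
complete_beyond_anchors <- function(country, vaccine, anchors, series,
                                    decisions, required_years,
                                    config = wuenic_config()) {
  anchors <- anchors[order(anchors$year), , drop = FALSE]
  out <- list()
  sides <- list(before = list(anchor = anchors[1, ],
                              years = required_years[required_years < anchors$year[1]]),
                after = list(anchor = anchors[nrow(anchors), ],
                             years = required_years[required_years > anchors$year[nrow(anchors)]]))
  for (side in sides) {
    a <- side$anchor; years <- sort(side$years)
    if (!length(years)) next
    passthrough <- a$resolution == "AP:R"
    if (passthrough) {
      vals <- series_at(series, years)
    } else {
      span <- series[series$year >= min(c(years, a$year)) &
                       series$year <= max(c(years, a$year)), , drop = FALSE]
      cal <- calibrate_segment(span, a, config)
      vals <- cal$coverage[match(years, cal$year)]
    }
    codes <- vapply(years, function(y) series_code(series, y), character(1))
    codes[codes != "E" & !passthrough] <- "C"
    texts <- vapply(seq_along(years), function(i) {
      if (codes[i] == "E")
        explain_rule("E", year = nearest_reported_year(series, years[i]))
      else if (passthrough) explain_rule(codes[i], anchor_years = a$year)
      else explain_rule("C", anchors = a)
    }, character(1))
    out[[length(out) + 1]] <- est_row(country, vaccine, years, vals, codes,
                                      texts)
  }
  if (!length(out)) return(empty_estimates())
  do.call(rbind, out)
}
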