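# Pipeline orchestration: run levels 1-4 for every required
# country/vaccine/year, enforce the global contracts (exactly one estimate
# per required key with available data), and emit artifacts.

anchor_explanation <- function(a) {
  switch(a$resolution,
         "AP:R" = explain_rule("AP:R"),
         "AP:S" = explain_rule("AP:S"),
         "AP:W" = explain_rule("AP:W", text = a$explanation))
}

# Levels 1-3 for one country/vaccine: returns list(estimates, audit, anchors,
# gaps) with unrounded estimates.
estimate_country_vaccine <- function(kb, country, vaccine, verbose = FALSE) {
  config <- kb$config
  dec <- kb$decisions[kb$decisions$country == country &
                        kb$decisions$vaccine == vaccine, , drop = FALSE]
  req_years <- sort(kb$required$year[kb$required$country == country &
                                       kb$required$vaccine == vaccine])
  pts <- kb$reported[kb$reported$country == country &
                       kb$reported$vaccine == vaccine, , drop = FALSE]
  g_rep <- filter_reported(pts, dec, config)
  sur <- kb$surveys[kb$surveys$country == country &
                      kb$surveys$vaccine == vaccine, , drop = FALSE]
  all_sur <- kb$surveys[kb$surveys$country == country, , drop = FALSE]
  g_sur <- filter_surveys(sur, kb$survey_descriptions, dec, config,
                          all_results = all_sur)
  sizes <- stats::setNames(kb$survey_descriptions$sample_size,
                           kb$survey_descriptions$survey_id)
  anchors <- find_anchor_years(g_rep, g_sur, dec, config, sizes)
  # the series must also cover anchor years outside the required window
  series <- complete_reported_series(g_rep, c(req_years, anchors$year))

  gaps <- data.frame(country = character(), vaccine = character(),
                     year = integer(), reason = character(),
                     stringsAsFactors = FALSE)
  if (!nrow(anchors)) {
    if (is.null(series)) {
      est <- empty_estimates()
      if (length(req_years))
        gaps <- data.frame(country = country, vaccine = vaccine,
                           year = req_years,
                           reason = "no accepted data of any kind",
                           stringsAsFactors = FALSE)
    } else {
      est <- estimate_single_source(country, vaccine, series, dec,
                                    req_years, config)
    }
  } else {
    anchor_req <- anchors[anchors$year %in% req_years, , drop = FALSE]
    est_anchor <- if (nrow(anchor_req)) {
      est_row(country, vaccine, anchor_req$year, anchor_req$coverage,
              anchor_req$resolution,
              vapply(seq_len(nrow(anchor_req)), function(i)
                anchor_explanation(anchor_req[i, ]), character(1)))
    } else empty_estimates()
    other_years <- setdiff(req_years, anchors$year)
    if (is.null(series)) {
      # decision-fixed anchors with no reported series at all: the assigned
      # estimates stand, remaining years take the nearest anchor estimate
      fill <- if (length(other_years)) {
        near <- vapply(other_years, function(y)
          anchors$year[which.min(abs(anchors$year - y))], integer(1))
        est_row(country, vaccine, other_years,
                anchors$coverage[match(near, anchors$year)], "E",
                vapply(near, function(n) explain_rule("E", year = n),
                       character(1)))
      } else empty_estimates()
      est <- rbind(est_anchor, fill)
    } else {
      est <- rbind(est_anchor,
                   complete_between_anchors(country, vaccine, anchors, series,
                                            dec, other_years, config),
                   complete_beyond_anchors(country, vaccine, anchors, series,
                                           dec, other_years, config))
    }
  }
  est <- sort_df(est, c("country", "vaccine", "year"))
  if (verbose && nrow(est))
    for (i in seq_len(nrow(est)))
      message(sprintf("rule %-4s -> %s %s %d = %.4g", est$rule_code[i],
                      country, vaccine, est$year[i], est$coverage_raw[i]))
  list(estimates = est, audit = rbind(g_rep, g_sur), anchors = anchors,
       gaps = gaps)
}

finalize_estimates <- function(est, decisions) {
  if (!nrow(est)) {
    est$coverage <- numeric(0)
    return(est)
  }
  # working-group comments are appended to the explanation of their key
  com <- decisions[decisions$action == "comment", , drop = FALSE]
  if (nrow(com)) {
    key_e <- paste(est$country, est$vaccine, est$year)
    key_c <- paste(com$country, com$vaccine, com$year)
    hit <- match(key_e, key_c)
    sel <- !is.na(hit)
    est$explanation[sel] <- paste0(est$explanation[sel],
                                   " Working group comment: ",
                                   com$explanation[hit[sel]])
  }
  est$coverage_raw <- clamp01(est$coverage_raw)
  est$coverage <- round_half_away(est$coverage_raw)
  est[c("country", "vaccine", "year", "coverage", "coverage_raw",
        "rule_code", "explanation")]
}

#' Check the global output contracts
#'
#' Verifies that the estimates are consistent with the required set:
#' no duplicate estimates for a key, and an estimate for every required
#' key (keys recorded as data gaps are exempt).
#'
#' @param estimates estimates data frame.
#' @param required the required-keys table.
#' @param gaps optional data frame of logged gaps (country, vaccine, year).
#' @return a data frame of violations (zero rows when all contracts hold).
#' @export
check_consistency <- function(estimates, required, gaps = NULL) {
  v <- list()
  key_e <- paste(estimates$country, estimates$vaccine, estimates$year)
  dup <- duplicated(key_e)
  if (any(dup))
    v[[length(v) + 1]] <- data.frame(
      type = "multiple estimates",
      key = unique(key_e[dup]),
      message = "more than one estimate for the key",
      stringsAsFactors = FALSE)
  key_r <- paste(required$country, required$vaccine, required$year)
  key_g <- if (!is.null(gaps) && nrow(gaps))
    paste(gaps$country, gaps$vaccine, gaps$year) else character()
  missing <- setdiff(setdiff(key_r, key_e), key_g)
  if (length(missing))
    v[[length(v) + 1]] <- data.frame(
      type = "missing estimate", key = missing,
      message = "required key has no estimate and no logged gap",
      stringsAsFactors = FALSE)
  if (!length(v))
    return(data.frame(type = character(), key = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Run the full estimation pipeline
#'
#' Executes levels 1-4 for every country/vaccine in the required set:
#' grades every reported and survey point, resolves anchor years, completes
#' the time series, reconciles DTP1 against DTP3, attaches rule codes and
#' explanations, and checks the output contracts.  Countries never
#' influence one another, and identical knowledge bases yield identical
#' output regardless of input row order.
#'
#' @param kb a \code{"wuenic_kb"} knowledge base.
#' @param out_dir optional output directory; when given,
#'   \code{estimates.csv}, \code{audit.csv}, \code{anchors.csv} and
#'   \code{gaps.csv} are written there (plus country reports when
#'   \code{report = TRUE}).
#' @param countries optional subset of country codes to run.
#' @param report emit per-country HTML/PNG reports under \code{out_dir}.
#' @param verbose log one line per rule firing.
#' @param post_hook function applied to the finalized estimates before the
#'   consistency check; intended for testing contract enforcement.
#' @return an object of class \code{"wuenic_result"}: list with
#'   \code{estimates} (one row per estimated key, with integer
#'   \code{coverage} and full-precision \code{coverage_raw}),
#'   \code{audit} (every graded point), \code{anchors}, \code{gaps} and
#'   \code{violations}.  A contract violation raises an error.
#' @export
#' @examples
#' kb <- egypt_fixture()
#' res <- wuenic_run(kb)
#' res$estimates[, c("vaccine", "year", "coverage", "rule_code")]
wuenic_run <- function(kb, out_dir = NULL, countries = NULL, report = FALSE,
                       verbose = FALSE, post_hook = identity) {
  stopifnot(inherits(kb, "wuenic_kb"))
  check_rule_registry()
  groups <- unique(kb$required[c("country", "vaccine")])
  if (!is.null(countries))
    groups <- groups[groups$country %in% countries, , drop = FALSE]
  groups <- sort_df(groups, c("country", "vaccine"))

  all_est <- list(); all_audit <- list(); all_anchor <- list()
  all_gaps <- list()
  for (co in unique(groups$country)) {
    co_est <- list()
    for (v in groups$vaccine[groups$country == co]) {
      r <- estimate_country_vaccine(kb, co, v, verbose = verbose)
      co_est[[v]] <- r$estimates
      all_audit[[paste(co, v)]] <- r$audit
      all_anchor[[paste(co, v)]] <- r$anchors
      all_gaps[[paste(co, v)]] <- r$gaps
    }
    est_co <- do.call(rbind, unname(co_est))
    # level 4: cross-vaccine reconciliation within the country
    est_co <- reconcile_dtp1(est_co, kb$required, kb$config)
    all_est[[co]] <- est_co
  }
  est <- do.call(rbind, c(unname(all_est), list(empty_estimates())))
  est <- finalize_estimates(est, kb$decisions)
  est <- post_hook(est)
  gaps <- do.call(rbind, c(unname(all_gaps),
                           list(data.frame(country = character(),
                                           vaccine = character(),
                                           year = integer(),
                                           reason = character(),
                                           stringsAsFactors = FALSE))))
  # DTP1 gaps that level 4 has since filled are no longer gaps
  if (nrow(gaps)) {
    key_g <- paste(gaps$country, gaps$vaccine, gaps$year)
    key_e <- paste(est$country, est$vaccine, est$year)
    gaps <- gaps[!(key_g %in% key_e), , drop = FALSE]
  }
  req <- if (is.null(countries)) kb$required else
    kb$required[kb$required$country %in% countries, , drop = FALSE]
  violations <- check_consistency(est, req, gaps)
  if (nrow(violations))
    stop("output contract violated:\n",
         paste(sprintf("  [%s] %s: %s", violations$type, violations$key,
                       violations$message), collapse = "\n"), call. = FALSE)
  audit <- do.call(rbind, c(unname(all_audit), list(empty_graded())))
  anchors <- do.call(rbind, c(unname(all_anchor), list(empty_anchors())))
  if (nrow(gaps))
    warning(sprintf("%d required key(s) have no data; logged as gaps",
                    nrow(gaps)), call. = FALSE)

  res <- list(estimates = sort_df(est, c("country", "vaccine", "year")),
              audit = sort_df(audit, c("country", "vaccine", "year",
                                       "origin", "ref")),
              anchors = sort_df(anchors, c("country", "vaccine", "year")),
              gaps = sort_df(gaps, c("country", "vaccine", "year")),
              violations = violations)
  class(res) <- "wuenic_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_estimates(res$estimates, file.path(out_dir, "estimates.csv"))
    utils::write.csv(res$audit, file.path(out_dir, "audit.csv"),
                     row.names = FALSE)
    utils::write.csv(res$anchors, file.path(out_dir, "anchors.csv"),
                     row.names = FALSE)
    utils::write.csv(res$gaps, file.path(out_dir, "gaps.csv"),
                     row.names = FALSE)
    if (report)
      for (co in unique(groups$country))
        render_country_report(co, res$estimates, res$audit, kb$decisions,
                              file.path(out_dir, "reports"))
  }
  res
}

#' @export
print.wuenic_result <- function(x, ...) {
  cat("<wuenic_result>\n")
  cat(sprintf("  estimates : %d (%d countries)\n", nrow(x$estimates),
              length(unique(x$estimates$country))))
  cat(sprintf("  anchors   : %d\n", nrow(x$anchors)))
  cat(sprintf("  gaps      : %d\n", nrow(x$gaps)))
  if (nrow(x$estimates)) {
    cat("  rule codes:\n")
    tab <- table(x$estimates$rule_code)
    for (code in names(tab))
      cat(sprintf("    %-4s %d\n", code, tab[[code]]))
  }
  invisible(x)
}
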