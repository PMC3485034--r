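# Rule-code registry and explanation generation.  Every estimate carries a
# short rule code naming the rule that produced it and a deterministic,
# human-readable explanation; working-group explanations are propagated
# verbatim.

#' Rule-code registry
#'
#' The registered taxonomy of rule codes emitted by the pipeline, each with
#' a one-line description.  Adding a refinement rule means registering its
#' code here and its template in the explanation generator.
#'
#' @return a data frame (code, description).
#' @export
rule_codes <- function() {
  data.frame(
    code = c("AP:R", "AP:S", "AP:W", "R", "I", "E", "C", "W", "W:I", "RMF"),
    description = c(
      "Anchor point resolved to reported data (survey supports it)",
      "Anchor point resolved to survey results",
      "Anchor point fixed by working-group decision",
      "Reported data (accepted in level one)",
      "Interpolated between accepted reported data",
      "Extrapolated from the nearest estimate",
      "Reported data calibrated to anchor estimate(s)",
      "Working-group decision (non-anchor year)",
      "Interpolated between anchor estimates by working-group decision",
      "Reconciled: DTP1 derived from DTP3"),
    stringsAsFactors = FALSE)
}

# Templates are functions of named context arguments; unknown extras are
# ignored so callers can pass whatever context they have.
rule_templates <- list(
  "AP:R" = function(...) "Reported coverage is supported by survey",
  "AP:S" = function(...)
    "Estimate based on survey results; the survey does not support the reported coverage.",
  "AP:W" = function(text, ...) text,
  "W" = function(text, ...) text,
  "R" = function(anchor_years = NULL, ...) {
    if (is.null(anchor_years))
      "Estimate based on accepted reported data."
    else if (length(anchor_years) == 1)
      sprintf("Estimate based on reported data; survey results support reported data in %d.",
              anchor_years)
    else
      sprintf("Estimate based on reported data because surveys support reported data in %s.",
              paste(anchor_years, collapse = " and "))
  },
  "I" = function(...) "Estimate interpolated between accepted reported data.",
  "E" = function(year, ...)
    sprintf("Estimate extrapolated from the value closest in time (%d).", year),
  "C" = function(anchors, ...) {
    parts <- sprintf("the %d %s estimate", anchors$year,
                     vapply(anchors$resolution, anchor_noun, character(1)))
    sprintf("Estimate based on reported data calibrated to the level of %s.",
            paste(parts, collapse = " and "))
  },
  "W:I" = function(y1, y2, text, ...)
    sprintf("Interpolated between the %d and %d anchor estimates by working-group decision: %s",
            y1, y2, text),
  "RMF" = function(trigger, ...)
    sprintf("DTP1 estimate derived from the DTP3 estimate by the modelled DTP1-DTP3 relationship (%s).",
            trigger)
)

#' Generate the explanation for a rule code
#'
#' Renders the deterministic explanation template registered for
#' \code{code} with the supplied context.  Working-group codes
#' (\code{AP:W}, \code{W}) propagate the decision's explanation verbatim
#' through the \code{text} argument.
#'
#' @param code a registered rule code (see [rule_codes()]).
#' @param ... template context (e.g. \code{anchors}, \code{year},
#'   \code{text}, \code{trigger}).
#' @return explanation text, length 1.
#' @export
#' @examples
#' explain_rule("AP:R")
explain_rule <- function(code, ...) {
  tpl <- rule_templates[[code]]
  if (is.null(tpl))
    stop("unregistered rule code: ", code, call. = FALSE)
  tpl(...)
}

# Sanity check used at pipeline start: every advertised code has a
# template and vice versa.
check_rule_registry <- function() {
  advertised <- rule_codes()$code
  templated <- names(rule_templates)
  if (!setequal(advertised, templated))
    stop("rule-code registry and explanation templates disagree: ",
         paste(c(setdiff(advertised, templated),
                 setdiff(templated, advertised)), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a country report
#'
#' Emits the transparency surface for one country: a per-vaccine plot
#' overlaying reported data, survey results and the final estimates (PNG),
#' a combined CSV table of data and estimates, a per-year explanation
#' list, and a single HTML page tying them together.  Given identical
#' inputs the CSV and HTML outputs are byte-identical.
#'
#' @param country ISO3-style lowercase country code.
#' @param estimates final estimates table (with \code{coverage} and
#'   \code{rule_code}).
#' @param graded the grading audit table ([wuenic_run()]'s \code{audit}).
#' @param decisions the decisions table.
#' @param out_dir output directory (created if needed).
#' @param plots emit PNG plots (set \code{FALSE} for text-only output).
#' @return invisible character vector of files written.
#' @export
render_country_report <- function(country, estimates, graded, decisions,
                                  out_dir, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  est <- sort_df(estimates[estimates$country == country, , drop = FALSE],
                 c("vaccine", "year"))
  gr <- graded[graded$country == country, , drop = FALSE]
  files <- character()

  tab_path <- file.path(out_dir, sprintf("%s_table.csv", country))
  tab <- est[c("country", "vaccine", "year", "coverage", "rule_code",
               "explanation")]
  utils::write.csv(tab, tab_path, row.names = FALSE, quote = TRUE)
  files <- c(files, tab_path)

  if (plots) {
    for (v in unique(est$vaccine)) {
      png_path <- file.path(out_dir, sprintf("%s_%s.png", country, v))
      grDevices::png(png_path, width = 800, height = 500)
      ev <- est[est$vaccine == v, ]
      rp <- gr[gr$vaccine == v & gr$origin == "reported", ]
      sv <- gr[gr$vaccine == v & gr$origin == "survey", ]
      plot(ev$year, ev$coverage, type = "b", pch = 19, ylim = c(0, 100),
           xlab = "Year", ylab = "Coverage (%)",
           main = sprintf("%s - %s", toupper(country), v))
      if (nrow(rp)) points(rp$year, rp$coverage, pch = 2, col = "blue")
      if (nrow(sv)) points(sv$year, graded_value(sv), pch = 0, col = "red")
      legend("bottomleft", legend = c("estimate", "reported", "survey"),
             pch = c(19, 2, 0), col = c("black", "blue", "red"), bty = "n")
      grDevices::dev.off()
      files <- c(files, png_path)
    }
  }

  html_path <- file.path(out_dir, sprintf("%s.html", country))
  lines <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
             sprintf("<title>Coverage estimates: %s</title></head><body>",
                     html_escape(country)),
             sprintf("<h1>Immunization coverage estimates: %s</h1>",
                     html_escape(toupper(country))))
  if (!nrow(est)) {
    lines <- c(lines, "<p><strong>No estimate produced.</strong></p>")
  } else {
    for (v in unique(est$vaccine)) {
      ev <- est[est$vaccine == v, ]
      lines <- c(lines, sprintf("<h2>%s</h2>", html_escape(v)))
      if (plots)
        lines <- c(lines, sprintf("<img src='%s_%s.png' alt='%s series'>",
                                  country, v, html_escape(v)))
      lines <- c(lines, "<table border='1'><tr><th>Year</th><th>Estimate (%)</th><th>Rule</th></tr>",
                 sprintf("<tr><td>%d</td><td>%g</td><td>%s</td></tr>",
                         ev$year, ev$coverage, html_escape(ev$rule_code)),
                 "</table>", "<h3>Explanations</h3>", "<ul>",
                 sprintf("<li><strong>%d</strong> [%s]: %s</li>", ev$year,
                         html_escape(ev$rule_code),
                         html_escape(ev$explanation)),
                 "</ul>")
    }
  }
  lines <- c(lines, "</body></html>")
  writeLines(lines, html_path)
  files <- c(files, html_path)
  invisible(files)
}
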