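#' @section Knowledge-base tables:
#' A knowledge base is five relational tables, mirroring how the estimation
#' inputs are maintained in practice:
#' \describe{
#'   \item{reported}{coverage reported by national authorities, one row per
#'     country/vaccine/year/source; \code{source} distinguishes plain
#'     reports, administrative tallies (\code{admin}) and official
#'     government estimates (\code{gov}).}
#'   \item{surveys}{household/community survey results, one row per
#'     survey/vaccine/birth-cohort-year (and evidence basis).}
#'   \item{survey_descriptions}{survey-level metadata (type, sample size,
#'     age cohort, card confirmation) keyed by \code{survey_id}.}
#'   \item{decisions}{working-group decisions: overrides and reinstatements,
#'     each with a mandatory written explanation.}
#'   \item{required}{the country/vaccine/year keys for which estimates must
#'     be produced.}
#' }
#' @name wuenicr-kb
#' @keywords internal
NULL

kb_schemas <- list(
  reported = c(country = "character", vaccine = "character",
               year = "integer", source = "character", coverage = "numeric"),
  surveys = c(survey_id = "character", country = "character",
              vaccine = "character", cohort_year = "integer",
              coverage = "numeric", evidence = "character"),
  survey_descriptions = c(survey_id = "character", title = "character",
                          type = "character", collection_year = "integer",
                          percent_cards_seen = "numeric",
                          confirmation_method = "character",
                          cohort_min_months = "integer",
                          cohort_max_months = "integer",
                          sample_size = "integer"),
  decisions = c(country = "character", vaccine = "character",
                year = "integer", action = "character",
                coverage = "numeric", explanation = "character"),
  required = c(country = "character", vaccine = "character",
               year = "integer")
)

kb_actions <- c("assignWUENIC", "ignoreReported", "ignoreSurvey",
                "acceptReported", "acceptSurvey", "interpolate", "comment")
kb_sources <- c("reported", "admin", "gov")
kb_survey_types <- c("DHS", "MICS", "EPI-cluster", "other")
kb_confirmation <- c("card", "caretaker", "either")

empty_table <- function(name) {
  sch <- kb_schemas[[name]]
  out <- lapply(sch, function(cl) vector(cl, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Assemble and validate a knowledge base
#'
#' Builds the in-memory knowledge base from its five component tables and
#' enforces every structural invariant (enumerations, uniqueness, foreign
#' keys, mandatory explanations).  Tables are brought into a canonical sort
#' order so that the knowledge base — and everything derived from it — is
#' independent of input row order.
#'
#' @param reported data frame with columns country, vaccine, year, source,
#'   coverage.
#' @param surveys data frame with columns survey_id, country, vaccine,
#'   cohort_year, coverage and optionally evidence ("card" or "either";
#'   when absent it is derived from the survey's confirmation method).
#' @param survey_descriptions data frame keyed by survey_id (see
#'   \link{wuenicr-kb}).
#' @param decisions data frame of working-group decisions.
#' @param required data frame of keys to estimate; must be non-empty.
#' @param config a [wuenic_config()] list.
#' @return an object of class \code{"wuenic_kb"}.
#' @export
wuenic_kb <- function(reported = empty_table("reported"),
                      surveys = empty_table("surveys"),
                      survey_descriptions = empty_table("survey_descriptions"),
                      decisions = empty_table("decisions"),
                      required = empty_table("required"),
                      config = wuenic_config()) {
  kb <- list(reported = coerce_table(reported, "reported"),
             surveys = coerce_table(surveys, "surveys"),
             survey_descriptions = coerce_table(survey_descriptions,
                                                "survey_descriptions"),
             decisions = coerce_table(decisions, "decisions"),
             required = coerce_table(required, "required"))
  kb <- validate_kb(kb, config)
  kb$config <- config
  class(kb) <- "wuenic_kb"
  kb
}

# Coerce a raw table to the declared schema, tolerating the optional
# surveys$evidence column and a missing decisions$coverage on non-assign rows.
coerce_table <- function(df, name) {
  sch <- kb_schemas[[name]]
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  optional <- if (name == "surveys") "evidence" else character()
  missing_cols <- setdiff(setdiff(names(sch), optional), names(df))
  if (length(missing_cols))
    stop(sprintf("table '%s': missing column(s) %s", name,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), names(sch))
  if (length(extra))
    stop(sprintf("table '%s': unexpected column(s) %s", name,
                 paste(extra, collapse = ", ")), call. = FALSE)
  for (opt in setdiff(optional, names(df))) df[[opt]] <- NA_character_
  df <- df[names(sch)]
  for (col in names(sch)) {
    target <- sch[[col]]
    # empty strings from CSV become NA quietly (legitimate for optional
    # decision coverages); genuinely bad values are caught by validation
    df[[col]] <- suppressWarnings(switch(target,
                                         integer = as.integer(df[[col]]),
                                         numeric = as.numeric(df[[col]]),
                                         character = as.character(df[[col]])))
  }
  df
}

row_err <- function(table, rows, msg) {
  stop(sprintf("table '%s', row(s) %s: %s", table,
               paste(rows, collapse = ", "), msg), call. = FALSE)
}

check_keys <- function(df, table, config, year_col = "year") {
  bad <- which(!(df$vaccine %in% config$vaccines))
  if (length(bad))
    row_err(table, bad, paste0("vaccine code(s) not in configured vocabulary: ",
                               paste(unique(df$vaccine[bad]), collapse = ", ")))
  yr <- df[[year_col]]
  bad <- which(is.na(yr) | yr < config$window[1] | yr > config$window[2])
  if (length(bad))
    row_err(table, bad,
            sprintf("%s outside estimation window %d-%d", year_col,
                    config$window[1], config$window[2]))
  invisible(df)
}

validate_kb <- function(kb, config) {
  rep <- kb$reported
  check_keys(rep, "reported", config)
  bad <- which(!(rep$source %in% kb_sources))
  if (length(bad)) row_err("reported", bad, "source must be reported/admin/gov")
  bad <- which(is.na(rep$coverage) | rep$coverage < 0)
  if (length(bad)) row_err("reported", bad, "coverage must be >= 0")
  key <- with(rep, paste(country, vaccine, year, source))
  if (anyDuplicated(key))
    row_err("reported", which(duplicated(key)),
            "duplicate (country, vaccine, year, source)")

  des <- kb$survey_descriptions
  if (anyDuplicated(des$survey_id))
    row_err("survey_descriptions", which(duplicated(des$survey_id)),
            "duplicate survey_id")
  bad <- which(!(des$type %in% kb_survey_types))
  if (length(bad)) row_err("survey_descriptions", bad,
                           "type must be DHS/MICS/EPI-cluster/other")
  bad <- which(!(des$confirmation_method %in% kb_confirmation))
  if (length(bad)) row_err("survey_descriptions", bad,
                           "confirmation_method must be card/caretaker/either")
  bad <- which(is.na(des$sample_size) | des$sample_size < 1)
  if (length(bad)) row_err("survey_descriptions", bad, "sample_size must be >= 1")
  bad <- which(des$cohort_min_months > des$cohort_max_months)
  if (length(bad)) row_err("survey_descriptions", bad, "empty age cohort range")

  sur <- kb$surveys
  check_keys(sur, "surveys", config, year_col = "cohort_year")
  bad <- which(is.na(sur$coverage) | sur$coverage < 0 | sur$coverage > 100)
  if (length(bad)) row_err("surveys", bad, "coverage must be in [0, 100]")
  bad <- which(!(sur$survey_id %in% des$survey_id))
  if (length(bad))
    row_err("surveys", bad, paste0("survey_id not in survey_descriptions: ",
                                   paste(unique(sur$survey_id[bad]), collapse = ", ")))
  # default evidence basis from the survey's confirmation method
  if (nrow(sur)) {
    method <- des$confirmation_method[match(sur$survey_id, des$survey_id)]
    fill <- is.na(sur$evidence) | sur$evidence == ""
    sur$evidence[fill] <- ifelse(method[fill] == "card", "card", "either")
    bad <- which(!(sur$evidence %in% c("card", "either")))
    if (length(bad)) row_err("surveys", bad, "evidence must be card or either")
  }
  key <- with(sur, paste(survey_id, vaccine, cohort_year, evidence))
  if (anyDuplicated(key))
    row_err("surveys", which(duplicated(key)),
            "duplicate (survey_id, vaccine, cohort_year, evidence)")
  kb$surveys <- sur

  dec <- kb$decisions
  check_keys(dec, "decisions", config)
  bad <- which(!(dec$action %in% kb_actions))
  if (length(bad))
    row_err("decisions", bad, paste0("unknown action; must be one of ",
                                     paste(kb_actions, collapse = ", ")))
  bad <- which(is.na(dec$explanation) | !nzchar(trimws(dec$explanation)))
  if (length(bad)) row_err("decisions", bad, "explanation must be non-empty")
  assign_rows <- dec$action == "assignWUENIC"
  bad <- which(assign_rows & (is.na(dec$coverage) | dec$coverage < 0 |
                                dec$coverage > 100))
  if (length(bad))
    row_err("decisions", bad,
            "assignWUENIC requires an assigned coverage in [0, 100]")
  key <- with(dec[assign_rows, , drop = FALSE], paste(country, vaccine, year))
  if (anyDuplicated(key))
    row_err("decisions", which(assign_rows)[duplicated(key)],
            "more than one assignWUENIC decision for the same key")

  req <- kb$required
  if (!nrow(req)) stop("table 'required': must contain at least one key",
                       call. = FALSE)
  check_keys(req, "required", config)
  kb$required <- unique(req)

  kb$reported <- sort_df(kb$reported, c("country", "vaccine", "year", "source"))
  kb$surveys <- sort_df(kb$surveys,
                        c("country", "vaccine", "cohort_year", "survey_id",
                          "evidence"))
  kb$survey_descriptions <- sort_df(kb$survey_descriptions, "survey_id")
  kb$decisions <- sort_df(kb$decisions,
                          c("country", "vaccine", "year", "action"))
  kb$required <- sort_df(kb$required, c("country", "vaccine", "year"))
  kb
}

#' @export
print.wuenic_kb <- function(x, ...) {
  cat("<wuenic_kb>\n")
  cat(sprintf("  reported points : %d\n", nrow(x$reported)))
  cat(sprintf("  survey results  : %d (from %d surveys)\n",
              nrow(x$surveys), nrow(x$survey_descriptions)))
  cat(sprintf("  wg decisions    : %d\n", nrow(x$decisions)))
  cat(sprintf("  required keys   : %d (%d countries, %d vaccines)\n",
              nrow(x$required), length(unique(x$required$country)),
              length(unique(x$required$vaccine))))
  invisible(x)
}

kb_read_csv <- function(path, name) {
  if (!file.exists(path))
    stop(sprintf("input file for table '%s' not found: %s", name, path),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  tryCatch(coerce_table(df, name),
           error = function(e) stop(sprintf("%s (file %s)",
                                            conditionMessage(e), path),
                                    call. = FALSE))
}

#' Load a knowledge base from delimited text files
#'
#' Reads the five comma-separated tables (\code{reported.csv},
#' \code{surveys.csv}, \code{survey_descriptions.csv}, \code{decisions.csv},
#' \code{required.csv}) from a directory, validates every invariant and
#' returns the knowledge base.  Loading is order-insensitive: permuting
#' rows in the input files yields an identical knowledge base.
#'
#' @param dir directory containing the CSV files, or a named list/character
#'   vector of explicit file paths with names \code{reported}, \code{surveys},
#'   \code{survey_descriptions}, \code{decisions}, \code{required}.
#' @param config a [wuenic_config()] list.
#' @return a \code{"wuenic_kb"} object.
#' @export
load_knowledge_base <- function(dir, config = wuenic_config()) {
  tables <- setdiff(names(kb_schemas), character())
  if (is.character(dir) && length(dir) == 1 && is.null(names(dir))) {
    paths <- file.path(dir, paste0(tables, ".csv"))
    names(paths) <- tables
  } else {
    paths <- unlist(dir)
    missing <- setdiff(tables, names(paths))
    if (length(missing))
      stop("no path given for table(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  wuenic_kb(reported = kb_read_csv(paths[["reported"]], "reported"),
            surveys = kb_read_csv(paths[["surveys"]], "surveys"),
            survey_descriptions = kb_read_csv(paths[["survey_descriptions"]],
                                              "survey_descriptions"),
            decisions = kb_read_csv(paths[["decisions"]], "decisions"),
            required = kb_read_csv(paths[["required"]], "required"),
            config = config)
}

#' Write a knowledge base to delimited text files
#'
#' Writes the five canonical CSV tables into \code{dir}; the inverse of
#' [load_knowledge_base()] (round-trips exactly).
#'
#' @param kb a \code{"wuenic_kb"} object.
#' @param dir destination directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_knowledge_base <- function(kb, dir) {
  stopifnot(inherits(kb, "wuenic_kb"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(kb_schemas))
    utils::write.csv(kb[[name]], file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, quote = TRUE)
  invisible(dir)
}

#' Write final estimates to CSV
#'
#' Emits the canonical estimates table with deterministic column and row
#' order (sorted by country, vaccine, year) so repeated runs are
#' byte-identical.  [read_estimates()] round-trips the file exactly.
#'
#' @param estimates a data frame of estimates as produced by [wuenic_run()].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  cols <- c("country", "vaccine", "year", "coverage", "rule_code",
            "explanation")
  missing_cols <- setdiff(cols, names(estimates))
  if (length(missing_cols))
    stop("estimates table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- sort_df(estimates[cols], c("country", "vaccine", "year"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(country = "character",
                                       vaccine = "character",
                                       year = "integer",
                                       coverage = "numeric",
                                       rule_code = "character",
                                       explanation = "character"))
  sort_df(df, c("country", "vaccine", "year"))
}
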