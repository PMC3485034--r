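#' Default pipeline configuration
#'
#' Every numeric threshold and behavioural switch used by the estimation
#' rules lives in the configuration, so that refining a rule is a config
#' edit rather than a code change.  Values not supplied keep their
#' defaults.
#'
#' @param ... named overrides of the default settings (see Details).
#'
#' @details Settings and defaults:
#' \describe{
#'   \item{window}{integer length-2, first and last calendar year for which
#'     estimates may be required; default \code{c(1997, 2011)}.}
#'   \item{vaccines}{character vocabulary of vaccine-dose codes; keys using
#'     other codes are rejected at load time.}
#'   \item{support_threshold}{percentage points; a survey supports reported
#'     data iff the absolute difference is strictly below this. Default 10.}
#'   \item{min_sample_size}{surveys with fewer respondents are excluded
#'     unless reinstated by a working-group decision. Default 300.}
#'   \item{jump_threshold}{percentage points; a year-over-year change in
#'     reported coverage larger than this is treated as a jump. Default 20.}
#'   \item{exclude_sustained_jumps}{if \code{TRUE}, both years flanking a
#'     sustained (non-recovering) jump are excluded rather than merely
#'     flagged. Default \code{FALSE}.}
#'   \item{cohort_min_months, cohort_max_months}{inclusive bounds of the
#'     age cohort (in months) a survey must fall inside to be usable.
#'     Defaults 12 and 59.}
#'   \item{survey_weighting}{\code{"none"} (unweighted mean of same-year
#'     surveys, the default) or \code{"sample_size"}.}
#'   \item{dtp1_poly}{named numeric \code{c(a=, b=, c=)} coefficients of the
#'     second-degree polynomial relating DTP3 coverage to the modelled
#'     DTP1-DTP3 difference. Defaults \code{a=-0.0066, b=0.4799, c=16.67}.}
#'   \item{calibration}{\code{"multiplicative"} (default) or
#'     \code{"additive"} functional form for anchor calibration; the
#'     additive form is always the fallback when a reported value of 0
#'     would make a ratio undefined.}
#'   \item{source_precedence}{order in which coexisting reported-data
#'     sources for the same key are preferred. Default
#'     \code{c("reported", "gov", "admin")}.}
#' }
#'
#' @return a named list of class \code{"wuenic_config"}.
#' @export
#' @examples
#' cfg <- wuenic_config(jump_threshold = 25)
#' cfg$jump_threshold
wuenic_config <- function(...) {
  cfg <- list(
    window = c(1997L, 2011L),
    vaccines = c("bcg", "dtp1", "dtp2", "dtp3", "hepb3", "hib3",
                 "mcv", "mcv1", "mcv2", "pol1", "pol3", "pcv3", "rcv1",
                 "yfv", "rotac"),
    support_threshold = 10,
    min_sample_size = 300L,
    jump_threshold = 20,
    exclude_sustained_jumps = FALSE,
    cohort_min_months = 12L,
    cohort_max_months = 59L,
    survey_weighting = "none",
    dtp1_poly = c(a = -0.0066, b = 0.4799, c = 16.67),
    calibration = "multiplicative",
    source_precedence = c("reported", "gov", "admin")
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown configuration setting(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    length(cfg$window) == 2, cfg$window[1] <= cfg$window[2],
    is.character(cfg$vaccines), length(cfg$vaccines) >= 1,
    is.numeric(cfg$support_threshold), cfg$support_threshold > 0,
    is.numeric(cfg$min_sample_size), cfg$min_sample_size >= 1,
    is.numeric(cfg$jump_threshold), cfg$jump_threshold > 0,
    is.logical(cfg$exclude_sustained_jumps),
    cfg$cohort_min_months <= cfg$cohort_max_months,
    cfg$survey_weighting %in% c("none", "sample_size"),
    length(cfg$dtp1_poly) == 3,
    cfg$calibration %in% c("multiplicative", "additive"),
    all(cfg$source_precedence %in% c("reported", "admin", "gov"))
  )
  # canonical storage types so configs compare equal after YAML round-trips
  cfg$window <- as.integer(cfg$window)
  cfg$support_threshold <- as.numeric(cfg$support_threshold)
  cfg$jump_threshold <- as.numeric(cfg$jump_threshold)
  cfg$min_sample_size <- as.integer(cfg$min_sample_size)
  cfg$cohort_min_months <- as.integer(cfg$cohort_min_months)
  cfg$cohort_max_months <- as.integer(cfg$cohort_max_months)
  cfg$dtp1_poly <- as.numeric(cfg$dtp1_poly)
  names(cfg$dtp1_poly) <- c("a", "b", "c")
  class(cfg) <- "wuenic_config"
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML file of settings and merges it over the defaults of
#' [wuenic_config()].  Unknown keys are an error so typos cannot silently
#' fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return a \code{"wuenic_config"} list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$dtp1_poly)) raw$dtp1_poly <- unlist(raw$dtp1_poly)
  if (!is.null(raw$window)) raw$window <- as.integer(unlist(raw$window))
  if (!is.null(raw$vaccines)) raw$vaccines <- as.character(unlist(raw$vaccines))
  if (!is.null(raw$source_precedence))
    raw$source_precedence <- as.character(unlist(raw$source_precedence))
  do.call(wuenic_config, raw)
}

#' Write the default configuration to a YAML file
#'
#' @param path destination file.
#' @param config configuration to write; defaults to [wuenic_config()].
#' @return \code{path}, invisibly.
#' @export
write_config <- function(path, config = wuenic_config()) {
  out <- unclass(config)
  out$dtp1_poly <- as.list(out$dtp1_poly)
  yaml::write_yaml(out, path)
  invisible(path)
}
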