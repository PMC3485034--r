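# Level 4: cross-vaccine reconciliation.  DTP1 (first dose) coverage is
# sometimes under-reported relative to DTP3; where DTP1 is missing or
# falls below DTP3 it is re-derived from DTP3 through a modelled
# second-degree polynomial.

#' Modelled DTP1 coverage from DTP3 coverage
#'
#' Evaluates the second-degree polynomial relating DTP3 coverage to the
#' DTP1--DTP3 difference and returns the implied DTP1 coverage:
#' \deqn{P_{dtp1} = P_{dtp3} + a P_{dtp3}^2 + b P_{dtp3} + c}
#' with default coefficients \eqn{a = -0.0066}, \eqn{b = 0.4799},
#' \eqn{c = 16.67}.  The raw polynomial value is clamped to [0, 100] but is
#' otherwise kept as is: near 100% coverage the modelled difference turns
#' slightly negative (the polynomial's positive root is at about 98.4), and
#' this is deliberately not forced back above DTP3.
#'
#' @param p_dtp3 DTP3 coverage in [0, 100].
#' @param coefficients named numeric \code{c(a=, b=, c=)}.
#' @return modelled DTP1 coverage, percentage points.
#' @export
#' @examples
#' dtp1_from_dtp3(0)    # 16.67
#' dtp1_from_dtp3(97)   # ~98.12
dtp1_from_dtp3 <- function(p_dtp3,
                           coefficients = wuenic_config()$dtp1_poly) {
  stopifnot(all(p_dtp3 >= 0), all(p_dtp3 <= 100), length(coefficients) == 3)
  a <- coefficients[["a"]]; b <- coefficients[["b"]]; cc <- coefficients[["c"]]
  clamp01(p_dtp3 + a * p_dtp3^2 + b * p_dtp3 + cc)
}

#' Reconcile DTP1 estimates against DTP3
#'
#' For each country and year with a DTP3 estimate: if the DTP1 estimate is
#' absent (but required) or lies below the DTP3 estimate, it is replaced by
#' [dtp1_from_dtp3()] of the DTP3 estimate, rule code \code{RMF}, with an
#' explanation naming the trigger.  Years where DTP1 is at least DTP3 are
#' untouched, as are DTP1 estimates fixed by a working-group decision
#' (assigned values are never overridden by any rule), and only DTP1 rows
#' are ever modified.  The operation is
#' idempotent: the replacement value depends only on DTP3, so applying it
#' twice changes nothing further.
#'
#' @param estimates estimates data frame for one country (all vaccines),
#'   with unrounded \code{coverage_raw}.
#' @param required the required-keys table (to know which absent DTP1
#'   years must be filled).
#' @param config a [wuenic_config()] list.
#' @return the updated estimates data frame.
#' @export
reconcile_dtp1 <- function(estimates, required,
                           config = wuenic_config()) {
  if (!nrow(estimates)) return(estimates)
  stopifnot(length(unique(estimates$country)) == 1)
  country <- estimates$country[1]
  dtp3 <- estimates[estimates$vaccine == "dtp3", , drop = FALSE]
  if (!nrow(dtp3)) return(estimates)
  req1 <- required[required$country == country & required$vaccine == "dtp1", ,
                   drop = FALSE]
  for (i in seq_len(nrow(dtp3))) {
    y <- dtp3$year[i]; p3 <- clamp01(dtp3$coverage_raw[i])
    j <- which(estimates$vaccine == "dtp1" & estimates$year == y)
    if (length(j)) {
      # a working-group assignment is never overridden, by any rule, and an
      # already-reconciled value is final (keeps the operation idempotent)
      if (estimates$rule_code[j[1]] %in% c("AP:W", "W", "RMF")) next
      if (estimates$coverage_raw[j[1]] >= p3) next
      trigger <- sprintf("DTP1 estimate below DTP3 estimate (%.4g)", p3)
      estimates$coverage_raw[j[1]] <- dtp1_from_dtp3(p3, config$dtp1_poly)
      estimates$rule_code[j[1]] <- "RMF"
      estimates$explanation[j[1]] <- explain_rule("RMF", trigger = trigger)
    } else if (y %in% req1$year) {
      new <- est_row(country, "dtp1", y, dtp1_from_dtp3(p3, config$dtp1_poly),
                     "RMF",
                     explain_rule("RMF",
                                  trigger = "no DTP1 estimate available"))
      estimates <- rbind(estimates, new)
    }
  }
  sort_df(estimates, c("country", "vaccine", "year"))
}
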