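# Small shared numeric helpers.

# Round half away from zero (base round() rounds half to even, which would
# turn 96.5 into 96; published estimates use commercial rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp01 <- function(x) pmin(100, pmax(0, x))

#' Linear interpolation between two series points
#'
#' Straight-line interpolation of a coverage value at \code{year} from the
#' points \code{(year_before, p_before)} and \code{(year_after, p_after)}:
#' \deqn{P = P_{before} + (Y - Y_{before})
#'          \frac{P_{after} - P_{before}}{Y_{after} - Y_{before}}}
#'
#' @param year_before,p_before earlier year and its coverage (percentage
#'   points).
#' @param year_after,p_after later year and its coverage.
#' @param year the year to interpolate at; must satisfy
#'   \code{year_before < year < year_after}.
#' @return interpolated coverage in percentage points (full precision; no
#'   rounding).
#' @export
#' @examples
#' interpolate_coverage(2004, 97, 2006, 85, 2005)  # 91
interpolate_coverage <- function(year_before, p_before,
                                 year_after, p_after, year) {
  stopifnot(year_before < year, year < year_after)
  p_before + (year - year_before) *
    ((p_after - p_before) / (year_after - year_before))
}

# kb tables are sorted into canonical order so that results never depend on
# input row order.
sort_df <- function(df, cols) {
  if (!nrow(df)) return(df)
  df <- df[do.call(order, df[cols]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
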