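# Naive reference evaluator: a second, independent transcription of the
# four-level estimation rules as flat year-by-year loops over the raw
# knowledge-base tables.  It shares no code with the engine (only the kb
# data structure and config list), and exists solely as an oracle.

ref_round <- function(x) sign(x) * floor(abs(x) + 0.5)
ref_clamp <- function(x) pmin(100, pmax(0, x))

ref_dose <- function(v) {
  d <- regmatches(v, regexpr("[0-9]+$", v))
  if (length(d) && nzchar(d)) as.integer(d) else 1L
}

# accepted reported value per year for one country/vaccine, as a named
# numeric vector (names are years)
ref_accepted_reported <- function(kb, co, v) {
  cfg <- kb$config
  rep <- kb$reported[kb$reported$country == co & kb$reported$vaccine == v, ]
  dec <- kb$decisions[kb$decisions$country == co & kb$decisions$vaccine == v, ]
  rv <- c()
  for (y in sort(unique(rep$year))) {
    rows <- rep[rep$year == y, ]
    for (s in cfg$source_precedence)
      if (s %in% rows$source) {
        rv[as.character(y)] <- rows$coverage[rows$source == s][1]
        break
      }
  }
  acc <- rv[rv < 100]
  # one-year spikes, judged simultaneously on the post-ge100 series
  drop <- c()
  thr <- cfg$jump_threshold
  for (ys in names(acc)) {
    y <- as.integer(ys)
    b <- as.character(y - 1); a <- as.character(y + 1)
    if (!(b %in% names(acc)) || !(a %in% names(acc))) next
    d1 <- acc[[ys]] - acc[[b]]; d2 <- acc[[a]] - acc[[ys]]
    if (abs(d1) > thr && abs(d2) > thr && sign(d1) != sign(d2))
      drop <- c(drop, ys)
  }
  acc <- acc[setdiff(names(acc), drop)]
  for (i in seq_len(nrow(dec))) {
    ys <- as.character(dec$year[i])
    if (dec$action[i] == "ignoreReported") acc <- acc[setdiff(names(acc), ys)]
    if (dec$action[i] == "acceptReported" && ys %in% names(rv))
      acc[ys] <- rv[[ys]]
  }
  acc[order(as.integer(names(acc)))]
}

# mean accepted/adjusted survey value per year, named numeric vector
ref_survey_values <- function(kb, co, v) {
  cfg <- kb$config
  sur <- kb$surveys[kb$surveys$country == co & kb$surveys$vaccine == v, ]
  all_sur <- kb$surveys[kb$surveys$country == co, ]
  des <- kb$survey_descriptions
  dec <- kb$decisions[kb$decisions$country == co & kb$decisions$vaccine == v, ]
  if (!nrow(sur)) return(c())
  vals <- list()
  for (i in seq_len(nrow(sur))) {
    d <- des[des$survey_id == sur$survey_id[i], ]
    y <- sur$cohort_year[i]
    excl <- FALSE
    if (d$sample_size < cfg$min_sample_size) excl <- TRUE
    if (d$cohort_min_months < cfg$cohort_min_months ||
        d$cohort_max_months > cfg$cohort_max_months) excl <- TRUE
    if (any(dec$action == "acceptSurvey" & dec$year == y)) excl <- FALSE
    if (any(dec$action == "ignoreSurvey" & dec$year == y)) excl <- TRUE
    # evidence redundancy within one survey
    twin <- sur[sur$survey_id == sur$survey_id[i] & sur$cohort_year == y, ]
    if (nrow(twin) == 2) {
      if (ref_dose(v) > 1 && sur$evidence[i] == "either") excl <- TRUE
      if (ref_dose(v) == 1 && sur$evidence[i] == "card") excl <- TRUE
    }
    if (excl) next
    cov <- sur$coverage[i]
    # recall-bias adjustment for later doses measured card-only
    if (ref_dose(v) > 1 && sur$evidence[i] == "card") {
      d1code <- paste0(sub("[0-9]+$", "", v), 1)
      d1 <- all_sur[all_sur$survey_id == sur$survey_id[i] &
                      all_sur$cohort_year == y & all_sur$vaccine == d1code, ]
      e1 <- d1$coverage[d1$evidence == "either"]
      c1 <- d1$coverage[d1$evidence == "card"]
      if (length(e1) && length(c1) && c1[1] > 0)
        cov <- min(100, cov * e1[1] / c1[1])
    }
    vals[[as.character(y)]] <- c(vals[[as.character(y)]], cov)
  }
  out <- vapply(vals, mean, numeric(1))
  out[order(as.integer(names(out)))]
}

# completed reported series over the given years (linear interpolation,
# nearest-neighbour extrapolation); NULL when nothing is accepted
ref_series <- function(acc, years) {
  if (!length(acc)) return(NULL)
  ay <- as.integer(names(acc))
  years <- sort(unique(c(years, ay)))
  out <- numeric(length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    if (y %in% ay) out[k] <- acc[[as.character(y)]]
    else if (y < min(ay)) out[k] <- acc[[as.character(min(ay))]]
    else if (y > max(ay)) out[k] <- acc[[as.character(max(ay))]]
    else {
      y1 <- max(ay[ay < y]); y2 <- min(ay[ay > y])
      p1 <- acc[[as.character(y1)]]; p2 <- acc[[as.character(y2)]]
      out[k] <- p1 + (y - y1) * (p2 - p1) / (y2 - y1)
    }
  }
  names(out) <- years
  out
}

# levels 1-3 for one country/vaccine; data.frame(year, coverage, rule_code)
ref_one <- function(kb, co, v, req_years) {
  cfg <- kb$config
  dec <- kb$decisions[kb$decisions$country == co & kb$decisions$vaccine == v, ]
  acc <- ref_accepted_reported(kb, co, v)
  svals <- ref_survey_values(kb, co, v)
  assign_dec <- dec[dec$action == "assignWUENIC", ]
  anchor_years <- sort(unique(c(
    intersect(as.integer(names(acc)), as.integer(names(svals))),
    assign_dec$year)))
  series <- ref_series(acc, c(req_years, anchor_years))

  ans <- data.frame(year = integer(), coverage = numeric(),
                    rule_code = character(), stringsAsFactors = FALSE)
  emit <- function(y, p, code)
    rbind(ans, data.frame(year = y, coverage = p, rule_code = code,
                          stringsAsFactors = FALSE))

  # resolve anchors
  a_cov <- numeric(0); a_res <- character(0)
  for (y in anchor_years) {
    if (y %in% assign_dec$year) {
      a_cov <- c(a_cov, assign_dec$coverage[assign_dec$year == y][1])
      a_res <- c(a_res, "AP:W")
    } else {
      pr <- acc[[as.character(y)]]; ps <- svals[[as.character(y)]]
      if (abs(ps - pr) < cfg$support_threshold) {
        a_cov <- c(a_cov, pr); a_res <- c(a_res, "AP:R")
      } else {
        a_cov <- c(a_cov, ps); a_res <- c(a_res, "AP:S")
      }
    }
  }

  orig_code <- function(y) {
    ay <- as.integer(names(acc))
    if (y %in% ay) "R" else if (y > min(ay) && y < max(ay)) "I" else "E"
  }

  if (!length(anchor_years)) {
    if (is.null(series)) return(ans)
    for (y in req_years)   # no assign decisions here: those years are anchors
      ans <- emit(y, series[[as.character(y)]], orig_code(y))
    return(ans)
  }

  if (is.null(series)) {
    for (y in req_years) {
      if (y %in% anchor_years)
        ans <- emit(y, a_cov[anchor_years == y], a_res[anchor_years == y])
      else {
        n <- anchor_years[which.min(abs(anchor_years - y))]
        ans <- emit(y, a_cov[anchor_years == n], "E")
      }
    }
    return(ans)
  }

  ratio_at <- function(k) {
    d <- series[[as.character(anchor_years[k])]]
    if (d == 0) NA_real_ else a_cov[k] / d
  }
  for (y in req_years) {
    if (y %in% anchor_years) {
      ans <- emit(y, a_cov[anchor_years == y], a_res[anchor_years == y])
    } else if (y < anchor_years[1]) {
      if (a_res[1] == "AP:R") ans <- emit(y, series[[as.character(y)]],
                                          orig_code(y))
      else {
        p <- ref_clamp(series[[as.character(y)]] * ratio_at(1))
        ans <- emit(y, p, if (orig_code(y) == "E") "E" else "C")
      }
    } else if (y > anchor_years[length(anchor_years)]) {
      k <- length(anchor_years)
      if (a_res[k] == "AP:R") ans <- emit(y, series[[as.character(y)]],
                                          orig_code(y))
      else {
        p <- ref_clamp(series[[as.character(y)]] * ratio_at(k))
        ans <- emit(y, p, if (orig_code(y) == "E") "E" else "C")
      }
    } else {
      k <- max(which(anchor_years < y))
      y1 <- anchor_years[k]; y2 <- anchor_years[k + 1]
      idec <- dec[dec$action == "interpolate" & dec$year >= y1 &
                    dec$year <= y2, ]
      if (nrow(idec)) {
        p <- a_cov[k] + (y - y1) * (a_cov[k + 1] - a_cov[k]) / (y2 - y1)
        ans <- emit(y, p, "W:I")
      } else if (a_res[k] == "AP:R" && a_res[k + 1] == "AP:R") {
        ans <- emit(y, series[[as.character(y)]], orig_code(y))
      } else {
        lam <- (y - y1) / (y2 - y1)
        r <- (1 - lam) * ratio_at(k) + lam * ratio_at(k + 1)
        ans <- emit(y, ref_clamp(series[[as.character(y)]] * r), "C")
      }
    }
  }
  ans
}

# full pipeline: levels 1-3 per country/vaccine, then DTP1/DTP3
# reconciliation, clamping and rounding
ref_pipeline <- function(kb) {
  req <- kb$required
  out <- list()
  for (co in sort(unique(req$country))) {
    co_rows <- list()
    for (v in sort(unique(req$vaccine[req$country == co]))) {
      yrs <- sort(req$year[req$country == co & req$vaccine == v])
      r <- ref_one(kb, co, v, yrs)
      if (nrow(r))
        co_rows[[v]] <- cbind(data.frame(country = co, vaccine = v,
                                         stringsAsFactors = FALSE), r)
    }
    est <- do.call(rbind, unname(co_rows))
    if (is.null(est)) next
    # level 4
    p <- kb$config$dtp1_poly
    d3 <- est[est$vaccine == "dtp3", ]
    for (i in seq_len(nrow(d3))) {
      y <- d3$year[i]; p3 <- ref_clamp(d3$coverage[i])
      model <- ref_clamp(p3 + p[["a"]] * p3^2 + p[["b"]] * p3 + p[["c"]])
      j <- which(est$vaccine == "dtp1" & est$year == y)
      if (length(j)) {
        if (est$rule_code[j] %in% c("AP:W", "W")) next
        if (est$coverage[j] < p3) {
          est$coverage[j] <- model; est$rule_code[j] <- "RMF"
        }
      } else if (any(req$country == co & req$vaccine == "dtp1" &
                       req$year == y)) {
        est <- rbind(est, data.frame(country = co, vaccine = "dtp1",
                                     year = y, coverage = model,
                                     rule_code = "RMF",
                                     stringsAsFactors = FALSE))
      }
    }
    out[[co]] <- est
  }
  est <- do.call(rbind, unname(out))
  if (is.null(est))
    return(data.frame(country = character(), vaccine = character(),
                      year = integer(), coverage = numeric(),
                      rule_code = character(), stringsAsFactors = FALSE))
  est$coverage <- ref_round(ref_clamp(est$coverage))
  est <- est[order(est$country, est$vaccine, est$year), ]
  rownames(est) <- NULL
  est
}

# convenience: engine output reduced to the columns the oracle produces
engine_pipeline <- function(kb, ...) {
  res <- suppressWarnings(wuenic_run(kb, ...))
  est <- res$estimates[c("country", "vaccine", "year", "coverage",
                         "rule_code")]
  est <- est[order(est$country, est$vaccine, est$year), ]
  rownames(est) <- NULL
  est
}
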