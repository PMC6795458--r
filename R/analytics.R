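## Monthly rates, composition tables, trend fits, sensitivity sweep.

#' Monthly antibiotic prescribing rate per 100 NB-ARTI consultations
#'
#' For each calendar month the denominator is the number of NB-ARTI
#' consultations and the numerator the number of those with a same-date J01
#' prescription; the rate is 100 x numerator/denominator. With
#' `stratify_by = "antibiotic_class"` the numerator counts a consultation
#' once per distinct class present (a two-drug consultation appears in two
#' class numerators but only once in the overall numerator) while the
#' denominator stays the overall monthly denominator. For partitioning
#' stratifiers (`age_group`, `diagnosis_category`, `specialty`, ...) both
#' numerator and denominator are computed within stratum. Months with a zero
#' denominator are flagged `defined = FALSE` and carry `NA` rates.
#'
#' @param cohort an `nbarti_cohort`
#' @param stratify_by `NULL` (overall), the name of a cohort covariate
#'   column, or `"antibiotic_class"`
#' @return data.table: `month_index`, `month_label`, `stratum`, `numerator`,
#'   `denominator`, `rate`, `defined`
#' @export
monthly_rate <- function(cohort, stratify_by = NULL) {
  co <- as.data.table(cohort)
  if (nrow(co) == 0) {
    nbarti_error("empty cohort: no months to rate", "nbarti_domain_error")
  }
  start <- attr(cohort, "study_start")
  months <- seq(min(co$month_index), max(co$month_index))
  base <- data.table(month_index = months,
                     month_label = month_label_of(months, start))

  overall_den <- co[, .(denominator = .N), by = month_index]

  if (is.null(stratify_by)) {
    num <- co[prescribed == TRUE, .(numerator = .N), by = month_index]
    out <- merge(merge(base, overall_den, by = "month_index", all.x = TRUE),
                 num, by = "month_index", all.x = TRUE)
    out[, stratum := "overall"]
  } else if (identical(stratify_by, "antibiotic_class")) {
    long <- co[prescribed == TRUE,
               .(abx_class = unlist(antibiotic_classes)),
               by = .(cons_id, month_index)]
    long <- unique(long)
    num <- long[, .(numerator = .N), by = .(month_index, stratum = abx_class)]
    grid <- CJ(month_index = months, stratum = ABX_CLASS_LEVELS)
    out <- merge(grid, num, by = c("month_index", "stratum"), all.x = TRUE)
    out <- merge(out, overall_den, by = "month_index", all.x = TRUE)
    out <- merge(out, base, by = "month_index")
  } else {
    if (!stratify_by %in% names(co)) {
      nbarti_error(sprintf("unknown stratifier: %s", stratify_by),
                   "nbarti_domain_error")
    }
    lev <- levels(co[[stratify_by]]) %||% sort(unique(co[[stratify_by]]))
    den <- co[, .(denominator = .N),
              by = .(month_index, stratum = as.character(get(stratify_by)))]
    num <- co[prescribed == TRUE, .(numerator = .N),
              by = .(month_index, stratum = as.character(get(stratify_by)))]
    grid <- CJ(month_index = months, stratum = lev)
    out <- merge(grid, den, by = c("month_index", "stratum"), all.x = TRUE)
    out <- merge(out, num, by = c("month_index", "stratum"), all.x = TRUE)
    out <- merge(out, base, by = "month_index")
  }
  out[is.na(numerator), numerator := 0L]
  out[is.na(denominator), denominator := 0L]
  out[, defined := denominator > 0L]
  out[, rate := fifelse(defined, 100 * numerator / denominator, NA_real_)]
  setcolorder(out, c("month_index", "month_label", "stratum", "numerator",
                     "denominator", "rate", "defined"))
  setorder(out, stratum, month_index)
  out[]
}

#' Rounded percentage of counts within a block
#'
#' `100 * count / total`, rounded to one decimal half away from zero — the
#' presentation convention for composition tables.
#'
#' @param counts integer vector
#' @param total denominator (default `sum(counts)`)
#' @return numeric vector of percentages
#' @export
composition_percent <- function(counts, total = sum(counts)) {
  round_half_away(100 * counts / total, 1)
}

#' Cohort composition table
#'
#' Counts and percentages of NB-ARTI consultations by sex, age group,
#' insured status, facility specialty, facility operation type, diagnosis
#' category and fiscal year. Percentages use the whole cohort as denominator
#' within every block, so each block's percents sum to 100 up to rounding.
#'
#' @param cohort an `nbarti_cohort`
#' @return data.table: `block`, `level`, `count`, `percent`
#' @export
composition_table <- function(cohort) {
  co <- as.data.table(cohort)
  total <- nrow(co)
  blocks <- c("sex", "age_group", "insured_status", "specialty",
              "facility_category", "diagnosis_category", "fiscal_year")
  out <- rbindlist(lapply(blocks, function(b) {
    tab <- co[, .(count = .N), by = .(level = as.character(get(b)))]
    lev <- levels(co[[b]])
    if (!is.null(lev)) {
      tab <- tab[match(intersect(lev, tab$level), level)]
    } else {
      setorder(tab, level)
    }
    tab[, block := b]
    tab
  }))
  out[, percent := composition_percent(count, total)]
  out[, .(block, level, count, percent)]
}

#' Fit a linear time trend to a monthly rate series by ordinary least squares
#'
#' Regresses the rate on the month index; the slope is in rate units
#' (prescriptions per 100 consultations) per month, with the conventional
#' two-sided t-test p-value for a zero slope and the coefficient of
#' determination. Undefined months (zero denominator) are dropped, not
#' imputed. A zero-variance response gives slope 0 and R-squared 0 with a
#' warning rather than an undefined fit.
#'
#' @param series one stratum's rows from [monthly_rate()] (or any data.frame
#'   with `month_index` and `rate`)
#' @return object of class `trend_fit`: list with `slope`, `intercept`,
#'   `p_value`, `r_squared`, `n`
#' @export
fit_trend <- function(series) {
  s <- as.data.table(series)
  if ("defined" %in% names(s)) s <- s[defined == TRUE]
  s <- s[!is.na(rate)]
  if (length(unique(s$stratum)) > 1) {
    nbarti_error("fit_trend expects a single stratum; filter first",
                 "nbarti_domain_error")
  }
  if (nrow(s) < 3) {
    nbarti_error("need at least 3 defined monthly rates",
                 "nbarti_domain_error")
  }
  if (var(s$month_index) == 0) {
    nbarti_error("zero variance in month index", "nbarti_domain_error")
  }
  if (var(s$rate) == 0) {
    warning("constant rate series: slope 0, R-squared reported as 0",
            call. = FALSE)
    return(structure(list(slope = 0, intercept = s$rate[1], p_value = 1,
                          r_squared = 0, n = nrow(s)),
                     class = "trend_fit"))
  }
  fit <- lm(rate ~ month_index, data = s)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = unname(sm$coefficients["month_index", "Pr(>|t|)"]),
                 r_squared = sm$r.squared,
                 n = nrow(s)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: slope %.5f, intercept %.3f, p %.4g, R2 %.4f (n=%d)\n",
              x$slope, x$intercept, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Regress the prescribing rate on the NB-ARTI diagnosis rate
#'
#' Tests whether a trend in prescribing merely reflects a trend in how often
#' ARTI consultations are coded as non-bacterial: ordinary least squares of
#' the monthly prescribing rate per 100 NB-ARTI consultations on the monthly
#' NB-ARTI diagnosis rate per 100 ARTI consultations, over their common
#' months.
#'
#' @param cohort an `nbarti_cohort` (carries monthly ARTI counts as an
#'   attribute)
#' @return a `trend_fit` (slope = regression coefficient on the diagnosis
#'   rate, intercept = fixed coefficient)
#' @export
rate_vs_diagnosisrate_regression <- function(cohort) {
  arti <- attr(cohort, "arti_monthly")
  pres <- monthly_rate(cohort)[defined == TRUE]
  nb <- as.data.table(cohort)[, .(n_nbarti = .N), by = month_index]
  m <- merge(merge(pres[, .(month_index, rate)], nb, by = "month_index"),
             arti, by = "month_index")
  if (nrow(m) < 3) {
    nbarti_error("need at least 3 common months", "nbarti_domain_error")
  }
  m[, dx_rate := 100 * n_nbarti / n_arti]
  if (var(m$dx_rate) == 0) {
    nbarti_error("diagnosis rate has zero variance", "nbarti_domain_error")
  }
  fit <- lm(rate ~ dx_rate, data = m)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = unname(sm$coefficients["dx_rate", "Pr(>|t|)"]),
                 r_squared = sm$r.squared,
                 n = nrow(m)),
            class = "trend_fit")
}

#' Relative change in rate between two months
#'
#' `100 * (rate_to - rate_from) / rate_from`, reported to one decimal (half
#' away from zero). Negative values are declines.
#'
#' @param series rows from [monthly_rate()] for one stratum
#' @param from_month,to_month month indices present and defined in `series`
#' @return percent change, one decimal
#' @export
relative_change <- function(series, from_month, to_month) {
  s <- as.data.table(series)
  pick <- function(idx) {
    r <- s[month_index == idx & defined == TRUE, rate]
    if (length(r) != 1) {
      nbarti_error(sprintf("month %d absent or undefined in series", idx),
                   "nbarti_domain_error")
    }
    r
  }
  from <- pick(from_month)
  to <- pick(to_month)
  if (from == 0) {
    nbarti_error("baseline rate is zero; relative change undefined",
                 "nbarti_domain_error")
  }
  round_half_away(100 * (to - from) / from, 1)
}

#' Linkage-window sensitivity sweep
#'
#' Rebuilds the cohort for each candidate lookback window and reports the
#' ARTI and NB-ARTI counts, bacterial exclusions, and the overall prescribing
#' rate both as the mean of monthly rates and pooled across all months.
#' Larger windows can only add active diagnoses, so ARTI counts and
#' bacterial exclusions are nondecreasing in the window.
#'
#' @param bundle a [claims_bundle()]
#' @param table an [appropriateness_table()]
#' @param windows vector of non-negative day counts
#' @param config passed to [build_cohort()]
#' @return data.table: `window`, `n_arti`, `n_excluded_bacterial`,
#'   `n_nbarti`, `mean_of_monthly_rate`, `pooled_rate`
#' @export
window_sensitivity <- function(bundle, table, windows = c(0, 7, 30, 60),
                               config = list()) {
  if (length(windows) < 1) {
    nbarti_error("need at least one window", "nbarti_domain_error")
  }
  if (any(windows < 0)) {
    nbarti_error("negative linkage window", "nbarti_domain_error")
  }
  rows <- lapply(windows, function(w) {
    ch <- build_cohort(bundle, table, window = w, config = config)
    att <- attrition(ch)
    if (nrow(ch)) {
      mr <- monthly_rate(ch)[defined == TRUE]
      mean_monthly <- mean(mr$rate)
      pooled <- 100 * sum(mr$numerator) / sum(mr$denominator)
    } else {
      mean_monthly <- NA_real_
      pooled <- NA_real_
    }
    data.table(window = w, n_arti = att$n_arti,
               n_excluded_bacterial = att$n_excluded_bacterial,
               n_nbarti = att$n_nbarti,
               mean_of_monthly_rate = mean_monthly, pooled_rate = pooled)
  })
  rbindlist(rows)
}
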