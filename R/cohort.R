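## Cohort construction: diagnosis linkage, ARTI selection, bacterial
## exclusion, category labelling, prescription linkage.

#' Link diagnoses active at each consultation
#'
#' A diagnosis is active for a consultation when it belongs to the same
#' patient and its issue date falls within the lookback window:
#' `consultation_date - window <= diagnosis_date <= consultation_date`
#' (inclusive at both ends, so same-day diagnoses count). Claims diagnoses
#' can linger in the record long after the episode, so the window caps how
#' stale a diagnosis may be; 30 days is the default adopted from a
#' sensitivity analysis over candidate windows.
#'
#' @param consultations data.table with `cons_id`, `patient_id`,
#'   `facility_id`, `date`
#' @param diagnoses data.table with `patient_id`, `facility_id`, `code`,
#'   `diagnosis_date`
#' @param window non-negative integer, days of lookback (default 30)
#' @param same_facility if `TRUE`, only diagnoses issued at the consulting
#'   facility are linked; default links diagnoses from any facility
#' @return data.table of active pairs: `cons_id`, `code` (distinct)
#' @export
link_active_diagnoses <- function(consultations, diagnoses, window = 30L,
                                  same_facility = FALSE) {
  if (window < 0) {
    nbarti_error("linkage window must be non-negative", "nbarti_domain_error")
  }
  co <- as.data.table(consultations)
  di <- as.data.table(diagnoses)
  if (nrow(co) == 0 || nrow(di) == 0) {
    return(data.table(cons_id = integer(), code = character()))
  }
  co <- co[, .(cons_id, patient_id, facility_id, date,
               lo = date - as.integer(window), hi = date)]
  by_cols <- if (same_facility) {
    c("patient_id", "facility_id")
  } else {
    "patient_id"
  }
  hits <- di[co,
             on = c(by_cols, "diagnosis_date>=lo", "diagnosis_date<=hi"),
             .(cons_id = i.cons_id, code = x.code), nomatch = NULL]
  unique(hits)
}

#' Select consultations with an active ARTI diagnosis
#'
#' Keeps consultations whose active code set contains at least one code whose
#' 3-character ICD-10 class is in J00--J06 or J20--J22 (acute upper
#' respiratory infections and acute bronchitis/bronchiolitis).
#'
#' @param consultations data.table with a `cons_id` column
#' @param active active pairs from [link_active_diagnoses()]
#' @return the subset of `consultations` with an ARTI code active
#' @export
select_arti_consultations <- function(consultations, active) {
  arti_ids <- unique(active[substr(code, 1, 3) %chin% ARTI_CLASSES, cons_id])
  as.data.table(consultations)[cons_id %in% arti_ids]
}

#' Exclude consultations with a concurrent antibiotic-requiring diagnosis
#'
#' Drops an ARTI consultation when ANY code in its active set is judged to
#' require antibiotic treatment — such visits may be appropriate prescribing
#' and must not enter the non-bacterial denominator.
#'
#' @param arti_consultations data.table of ARTI consultations (`cons_id`)
#' @param active active pairs from [link_active_diagnoses()]
#' @param table an [appropriateness_table()]
#' @return list with `kept` (the NB-ARTI subset), `n_before`, `n_after`,
#'   `n_excluded`
#' @export
exclude_bacterial <- function(arti_consultations, active, table) {
  co <- as.data.table(arti_consultations)
  act <- active[cons_id %in% co$cons_id]
  if (nrow(act)) {
    codes <- unique(act$code)
    verdict <- requires_antibiotics(table, codes)
    bad_ids <- unique(act[code %chin% codes[verdict], cons_id])
  } else {
    bad_ids <- integer()
  }
  kept <- co[!cons_id %in% bad_ids]
  list(kept = kept, n_before = nrow(co), n_after = nrow(kept),
       n_excluded = nrow(co) - nrow(kept))
}

#' Label the diagnosis category of an NB-ARTI consultation
#'
#' Active ARTI codes are reduced to distinct 3-character classes. Singleton
#' sets J20, J06, J02, J00, J03 and the five common pairs (J06 & J20,
#' J02 & J20, J02 & J06, J00 & J20, J00 & J06) keep their own label; every
#' other combination (other singletons such as J21, unlisted pairs, triples
#' and larger) is labelled `"others"`. The labels partition the cohort.
#'
#' @param active active pairs restricted to the cohort's consultations
#' @return data.table `cons_id`, `diagnosis_category` (factor)
#' @export
label_diagnosis_category <- function(active) {
  act <- active[substr(code, 1, 3) %chin% ARTI_CLASSES]
  if (nrow(act) == 0) {
    nbarti_error("no ARTI codes to label", "nbarti_domain_error")
  }
  act <- unique(act[, .(cons_id, class3 = substr(code, 1, 3))])
  lab <- act[order(class3),
             .(key = paste(class3, collapse = " & ")), by = cons_id]
  lab[, diagnosis_category :=
        factor(fifelse(key %chin% DX_CATEGORY_LEVELS, key, "others"),
               levels = DX_CATEGORY_LEVELS)]
  lab[, .(cons_id, diagnosis_category)]
}

#' Link same-date antibiotic prescriptions as the outcome
#'
#' The outcome is prescription of an oral systemic antibiotic (ATC J01) on
#' the same date as the consultation; diagnosis dates in claims are too vague
#' to link on. A consultation counts once in the overall numerator however
#' many drugs were dispensed; `antibiotic_classes` is the union of the
#' classes of all same-date J01 prescriptions. Non-J01 prescriptions are
#' ignored.
#'
#' @param cohort data.table of NB-ARTI consultations (`cons_id`,
#'   `patient_id`, `facility_id`, `date`)
#' @param prescriptions prescriptions table
#' @param match_facility if `TRUE`, also require the prescribing facility to
#'   equal the consulting facility (default `FALSE`: pharmacy claims often
#'   carry a different facility id)
#' @return `cohort` with `prescribed` (logical) and `antibiotic_classes`
#'   (list column of class labels) added
#' @export
link_prescriptions <- function(cohort, prescriptions,
                               match_facility = FALSE) {
  co <- copy(as.data.table(cohort))
  rx <- as.data.table(prescriptions)
  rx <- rx[startsWith(atc_code, "J01")]
  if (nrow(rx)) {
    cls <- classify_antibiotic(rx$atc_code)
    rx[, abx_class := as.character(cls$abx_class)]
    by_cols <- c("patient_id", "date", if (match_facility) "facility_id")
    hits <- rx[co[, c("cons_id", by_cols), with = FALSE], on = by_cols,
               .(cons_id = i.cons_id, abx_class), nomatch = NULL]
    agg <- hits[, .(classes = list(sort(unique(abx_class)))), by = cons_id]
    co[, antibiotic_classes := agg[match(co$cons_id, agg$cons_id), classes]]
  } else {
    co[, antibiotic_classes := vector("list", nrow(co))]
  }
  empty <- vapply(co$antibiotic_classes, is.null, logical(1))
  co[empty, antibiotic_classes := list(list(character()))]
  co[, prescribed := lengths(antibiotic_classes) > 0]
  co[]
}

#' Build the NB-ARTI analysis cohort from a claims bundle
#'
#' Runs the five construction steps in order — diagnosis linkage, ARTI
#' selection, bacterial exclusion, category labelling, prescription linkage —
#' then attaches covariates (sex, age group, insured status, specialty,
#' facility category, visit hours, fiscal year, calendar month, month index).
#' The returned cohort carries an attrition report and the monthly ARTI
#' consultation counts (needed for the diagnosis-rate regression) as
#' attributes.
#'
#' @param bundle a [claims_bundle()]
#' @param table an [appropriateness_table()]
#' @param window lookback days for diagnosis linkage (default 30)
#' @param config list: `match_facility`, `same_facility_exclusion`
#'   (both default `FALSE`), `study_start` (`"YYYY-MM"`; default the
#'   calendar month of the earliest consultation)
#' @return data.table of class `nbarti_cohort`, one row per NB-ARTI
#'   consultation; attributes `attrition` (list of stage counts),
#'   `arti_monthly` (data.table `month_index`, `n_arti`) and `study_start`
#' @export
build_cohort <- function(bundle, table, window = 30L, config = list()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  co <- copy(bundle$consultations)
  empty_cohort <- function(start) {
    out <- data.table(
      cons_id = integer(), patient_id = character(),
      facility_id = character(), date = as.Date(character()),
      diagnosis_category = factor(character(), levels = DX_CATEGORY_LEVELS),
      sex = factor(character(), levels = SEX_LEVELS),
      age_group = factor(character(), levels = AGE_LABELS),
      insured_status = factor(character(), levels = INSURED_LEVELS),
      specialty = factor(character(), levels = SPECIALTY_LEVELS),
      facility_category = factor(character(), levels = FACILITY_LEVELS),
      visit_hours = factor(character(), levels = HOURS_LEVELS),
      fiscal_year = integer(), month = factor(character(), MONTH_LEVELS),
      month_index = integer(), prescribed = logical(),
      antibiotic_classes = list())
    setattr(out, "attrition",
            list(n_consultations = nrow(co), n_arti = 0L, n_nbarti = 0L,
                 n_excluded_bacterial = 0L, n_prescribed = 0L))
    setattr(out, "arti_monthly",
            data.table(month_index = integer(), n_arti = integer()))
    setattr(out, "study_start", start)
    setattr(out, "class", c("nbarti_cohort", class(out)))
    out
  }
  if (nrow(co) == 0) return(empty_cohort(config$study_start %||% NA_character_))

  start <- config$study_start %||% format(min(co$date), "%Y-%m")
  co[, cons_id := seq_len(.N)]

  active <- link_active_diagnoses(co, bundle$diagnoses, window = window,
                                  same_facility = isTRUE(config$same_facility_exclusion))
  arti <- select_arti_consultations(co, active)
  arti_monthly <- arti[, .(n_arti = .N),
                       by = .(month_index = month_index_of(date, start))]
  setorder(arti_monthly, month_index)

  excl <- exclude_bacterial(arti, active, table)
  nb <- excl$kept
  if (nrow(nb) == 0) {
    out <- empty_cohort(start)
    attr(out, "attrition")$n_arti <- nrow(arti)
    attr(out, "attrition")$n_excluded_bacterial <- excl$n_excluded
    setattr(out, "arti_monthly", arti_monthly)
    return(out)
  }

  cat_lab <- label_diagnosis_category(active[cons_id %in% nb$cons_id])
  nb <- merge(nb, cat_lab, by = "cons_id", sort = TRUE)

  nb <- link_prescriptions(nb, bundle$prescriptions,
                           match_facility = isTRUE(config$match_facility))

  ## covariates
  p <- bundle$patients
  f <- bundle$facilities
  nb <- merge(nb, p[, .(patient_id, sex, birth_year_month, insured_status)],
              by = "patient_id", sort = FALSE)
  nb <- merge(nb, f[, .(facility_id, bed_count, university, public,
                        specialty)],
              by = "facility_id", sort = FALSE)
  nb[, age_group := derive_age_group(birth_year_month, date)]
  nb[, facility_category := facility_category(bed_count, university, public)]
  nb[, visit_hours := classify_visit_hours(date, visit_slot,
                                           holidays = bundle$holidays)]
  nb[, fiscal_year := fiscal_year(date)]
  nb[, month := factor(MONTH_LEVELS[as.integer(format(date, "%m"))],
                       levels = MONTH_LEVELS)]
  nb[, month_index := month_index_of(date, start)]
  nb[, sex := factor(sex, levels = SEX_LEVELS)]
  nb[, insured_status := factor(insured_status, levels = INSURED_LEVELS)]
  nb[, specialty := factor(specialty, levels = SPECIALTY_LEVELS)]
  nb[, c("birth_year_month", "bed_count", "university", "public",
         "visit_slot") := NULL]
  setcolorder(nb, c("cons_id", "patient_id", "facility_id", "date",
                    "diagnosis_category", "sex", "age_group",
                    "insured_status", "specialty", "facility_category",
                    "visit_hours", "fiscal_year", "month", "month_index",
                    "prescribed", "antibiotic_classes"))
  setorder(nb, cons_id)

  setattr(nb, "attrition",
          list(n_consultations = nrow(co),
               n_arti = nrow(arti),
               n_nbarti = nrow(nb),
               n_excluded_bacterial = excl$n_excluded,
               n_prescribed = sum(nb$prescribed)))
  setattr(nb, "arti_monthly", arti_monthly)
  setattr(nb, "study_start", start)
  setattr(nb, "class", c("nbarti_cohort", class(nb)))
  nb
}

#' Attrition report of a built cohort
#'
#' @param cohort an `nbarti_cohort`
#' @return list: consultations in, ARTI-selected, excluded as bacterial,
#'   NB-ARTI retained, with a prescription
#' @export
attrition <- function(cohort) attr(cohort, "attrition")

#' Write a cohort to CSV (classes semicolon-joined) plus attrition JSON
#'
#' @param cohort an `nbarti_cohort`
#' @param path output CSV path; attrition goes to `<path dir>/attrition.json`
#' @return invisibly, the two paths
#' @export
write_cohort <- function(cohort, path) {
  out <- copy(as.data.table(cohort))
  out[, antibiotic_classes :=
        vapply(antibiotic_classes, paste, character(1), collapse = ";")]
  out[, date := format(date, "%Y-%m-%d")]
  fwrite(out, path)
  att_path <- file.path(dirname(path), "attrition.json")
  jsonlite::write_json(attrition(cohort), att_path, auto_unbox = TRUE)
  invisible(c(cohort = path, attrition = att_path))
}
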