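#' Derive the nine-bin age group at consultation
#'
#' Age is computed in completed years on year-month granularity: the day of
#' month is ignored and birth is treated as the 1st of its month, because the
#' source data carry only year and month of birth. Bins are
#' 0-3, 4-6, 7-12, 13-18, 19-29, 30-39, 40-49, 50-59 and 60- (60 up to the
#' database ceiling of 75), chosen so that the youngest bins align with
#' municipal child-healthcare subsidy brackets.
#'
#' @param birth_year_month character vector, `"YYYY-MM"`
#' @param consultation_date `Date` vector (recycled against births)
#' @return factor with levels `"0-3"` ... `"60-"`
#' @export
#' @examples
#' derive_age_group("2010-05", as.Date("2013-04-15"))  # "0-3"
derive_age_group <- function(birth_year_month, consultation_date) {
  b <- parse_year_month(birth_year_month)
  cy <- as.integer(format(consultation_date, "%Y"))
  cm <- as.integer(format(consultation_date, "%m"))
  age <- (cy - b$year) - as.integer(cm < b$month)
  if (any(age < 0)) {
    nbarti_error("birth after consultation (negative age)",
                 "nbarti_domain_error")
  }
  if (any(age > 75)) {
    nbarti_error("age above 75: outside the population the data model covers",
                 "nbarti_domain_error")
  }
  idx <- findInterval(age, AGE_LOWER)
  factor(AGE_LABELS[idx], levels = AGE_LABELS)
}

#' Japanese fiscal year of a date
#'
#' April 1 through March 31, labelled by the calendar year containing April:
#' 2013-03-31 belongs to fiscal year 2012, 2013-04-01 to 2013.
#'
#' @param date `Date` vector
#' @return integer vector of fiscal years
#' @seealso [fy_label()]
#' @export
fiscal_year <- function(date) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  y - as.integer(m < 4L)
}

#' @rdname fiscal_year
#' @export
fy_label <- function(date) sprintf("FY%d", fiscal_year(date))

#' Classify a consultation as in-hours or out-of-hours
#'
#' In-hours is 08:00 (inclusive) to 18:00 (exclusive) on a weekday that is not
#' a holiday; everything else — evenings, nights, weekends, and any date in
#' the supplied holiday calendar — is out-of-hours. `visit_slot` may carry
#' either a clock time (`"HH:MM"`) or a pre-coded `"in_hours"`/`"out_of_hours"`
#' flag, mirroring claims feeds that ship a coded "time zone of visit".
#' Pre-coded flags are passed through unchanged.
#'
#' @param date `Date` vector
#' @param visit_slot character vector of clock times or flags
#' @param holidays `Date` vector of holidays (default none: weekends only)
#' @return factor with levels `in_hours`, `out_of_hours`
#' @export
classify_visit_hours <- function(date, visit_slot,
                                 holidays = as.Date(character())) {
  slot <- trimws(as.character(visit_slot))
  precoded <- slot %in% HOURS_LEVELS
  timed <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", slot)
  if (any(!precoded & !timed)) {
    nbarti_error(
      sprintf("unknown visit_slot encoding: %s",
              paste(head(unique(slot[!precoded & !timed]), 5),
                    collapse = ", ")),
      "nbarti_parse_error")
  }
  out <- character(length(slot))
  out[precoded] <- slot[precoded]
  if (any(timed)) {
    hm <- strsplit(slot[timed], ":", fixed = TRUE)
    hour <- vapply(hm, function(x) as.numeric(x[1]) + as.numeric(x[2]) / 60,
                   numeric(1))
    wd <- as.integer(format(date[timed], "%u"))      # 1 = Monday
    weekend <- wd >= 6L
    holiday <- date[timed] %in% holidays
    in_hours <- !weekend & !holiday & hour >= 8 & hour < 18
    out[timed] <- ifelse(in_hours, "in_hours", "out_of_hours")
  }
  factor(out, levels = HOURS_LEVELS)
}

#' Categorise a facility by operation type and bed count
#'
#' Operation flags dominate: a university facility is `university_hospital`
#' and a national/municipal one `public_hospital` regardless of beds. For
#' unflagged facilities, 0 beds is a clinic without beds, 1-19 a clinic with
#' beds, and 20 or more a general ("other") hospital.
#'
#' @param bed_count non-negative integer vector
#' @param university,public logical flags (recycled)
#' @return factor with the five facility-category levels
#' @export
facility_category <- function(bed_count, university = FALSE, public = FALSE) {
  n <- length(bed_count)
  university <- rep_len(university, n)
  public <- rep_len(public, n)
  if (any(university & public)) {
    nbarti_error("facility flagged both university and public",
                 "nbarti_domain_error")
  }
  if (any(bed_count < 0)) {
    nbarti_error("negative bed_count", "nbarti_domain_error")
  }
  out <- ifelse(university, "university_hospital",
         ifelse(public, "public_hospital",
         ifelse(bed_count == 0, "clinic_without_beds",
         ifelse(bed_count <= 19, "clinic_with_beds", "other_hospital"))))
  factor(out, levels = FACILITY_LEVELS)
}

## ---- claims bundle ---------------------------------------------------------

CLAIMS_SCHEMA <- list(
  patients      = c("patient_id", "sex", "birth_year_month", "insured_status"),
  facilities    = c("facility_id", "bed_count", "university", "public",
                    "specialty"),
  consultations = c("patient_id", "facility_id", "date", "visit_slot"),
  diagnoses     = c("patient_id", "facility_id", "code", "diagnosis_date"),
  prescriptions = c("patient_id", "facility_id", "date", "atc_code")
)

#' Construct a validated claims bundle from in-memory tables
#'
#' The bundle is the unit every downstream stage consumes: five cross-keyed
#' tables plus the holiday calendar. Validation enforces the documented
#' schema, parses dates, checks referential integrity, and collapses
#' duplicate (patient, facility, date) consultation lines to one row with a
#' warning — claims extracts commonly repeat lines per billed item.
#'
#' @param patients,facilities,consultations,diagnoses,prescriptions
#'   data.frames matching the documented column schema
#' @param holidays `Date` vector used by [classify_visit_hours()]
#' @return an object of class `claims_bundle`
#' @export
claims_bundle <- function(patients, facilities, consultations, diagnoses,
                          prescriptions, holidays = as.Date(character())) {
  tabs <- list(patients = as.data.table(patients),
               facilities = as.data.table(facilities),
               consultations = as.data.table(consultations),
               diagnoses = as.data.table(diagnoses),
               prescriptions = as.data.table(prescriptions))

  for (nm in names(CLAIMS_SCHEMA)) {
    missing <- setdiff(CLAIMS_SCHEMA[[nm]], names(tabs[[nm]]))
    if (length(missing)) {
      nbarti_error(
        sprintf("table '%s' is missing column(s): %s",
                nm, paste(missing, collapse = ", ")),
        "nbarti_schema_error")
    }
    tabs[[nm]] <- tabs[[nm]][, CLAIMS_SCHEMA[[nm]], with = FALSE]
  }

  p <- tabs$patients
  if (anyDuplicated(p$patient_id)) {
    nbarti_error("duplicate patient_id in patients table",
                 "nbarti_integrity_error")
  }
  bad_sex <- setdiff(unique(p$sex), SEX_LEVELS)
  if (length(bad_sex)) {
    nbarti_error(sprintf("unknown sex value(s): %s",
                         paste(bad_sex, collapse = ", ")),
                 "nbarti_parse_error")
  }
  bad_ins <- setdiff(unique(p$insured_status), INSURED_LEVELS)
  if (length(bad_ins)) {
    nbarti_error(sprintf("unknown insured_status value(s): %s",
                         paste(bad_ins, collapse = ", ")),
                 "nbarti_parse_error")
  }
  if (nrow(p)) parse_year_month(p$birth_year_month)  # validates format

  f <- tabs$facilities
  if (anyDuplicated(f$facility_id)) {
    nbarti_error("duplicate facility_id in facilities table",
                 "nbarti_integrity_error")
  }
  f[, bed_count := as.integer(bed_count)]
  f[, university := parse_logical_col(university, "university flag")]
  f[, public := parse_logical_col(public, "public flag")]
  bad_spec <- setdiff(unique(f$specialty), SPECIALTY_LEVELS)
  if (length(bad_spec)) {
    nbarti_error(sprintf("unknown specialty value(s): %s",
                         paste(bad_spec, collapse = ", ")),
                 "nbarti_parse_error")
  }

  co <- tabs$consultations
  if (!inherits(co$date, "Date")) co[, date := parse_iso_date(date, "consultation date")]
  di <- tabs$diagnoses
  if (!inherits(di$diagnosis_date, "Date")) {
    di[, diagnosis_date := parse_iso_date(diagnosis_date, "diagnosis date")]
  }
  if (nrow(di) && any(!nzchar(di$code))) {
    nbarti_error("empty diagnosis code", "nbarti_parse_error")
  }
  rx <- tabs$prescriptions
  if (!inherits(rx$date, "Date")) rx[, date := parse_iso_date(date, "prescription date")]
  if (nrow(rx)) {
    bad <- !grepl("^[A-Z]", rx$atc_code)
    if (any(bad)) {
      nbarti_error(sprintf("malformed ATC code(s): %s",
                           paste(head(unique(rx$atc_code[bad]), 5),
                                 collapse = ", ")),
                   "nbarti_parse_error")
    }
  }

  check_fk <- function(ids, universe, what, table) {
    bad <- setdiff(unique(ids), universe)
    if (length(bad)) {
      nbarti_error(
        sprintf("table '%s' references unknown %s: %s",
                table, what, paste(head(bad, 10), collapse = ", ")),
        "nbarti_integrity_error")
    }
  }
  check_fk(co$patient_id, p$patient_id, "patient_id", "consultations")
  check_fk(co$facility_id, f$facility_id, "facility_id", "consultations")
  check_fk(di$patient_id, p$patient_id, "patient_id", "diagnoses")
  check_fk(rx$patient_id, p$patient_id, "patient_id", "prescriptions")

  n_before <- nrow(co)
  co <- unique(co, by = c("patient_id", "facility_id", "date"))
  n_dups <- n_before - nrow(co)
  if (n_dups > 0) {
    warning(sprintf("collapsed %d duplicate consultation line(s)", n_dups),
            call. = FALSE)
  }

  ## birth never after a linked consultation
  if (nrow(co)) {
    chk <- merge(co[, .(patient_id, date)],
                 p[, .(patient_id, birth_year_month)], by = "patient_id")
    b <- parse_year_month(chk$birth_year_month)
    cons_ym <- as.integer(format(chk$date, "%Y")) * 12L +
      as.integer(format(chk$date, "%m"))
    if (any(b$year * 12L + b$month > cons_ym)) {
      nbarti_error("patient birth after a linked consultation",
                   "nbarti_integrity_error")
    }
  }

  structure(list(patients = p, facilities = f, consultations = co,
                 diagnoses = di, prescriptions = rx, holidays = holidays),
            n_duplicates_collapsed = n_dups,
            class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("claims_bundle:",
      nrow(x$patients), "patients,",
      nrow(x$facilities), "facilities,",
      nrow(x$consultations), "consultations,",
      nrow(x$diagnoses), "diagnoses,",
      nrow(x$prescriptions), "prescriptions\n")
  invisible(x)
}

#' Read a claims bundle from delimited text files
#'
#' Five UTF-8 tables with header rows; dates ISO-8601 (`YYYY-MM-DD`), births
#' `YYYY-MM`. Validation and de-duplication are as in [claims_bundle()].
#'
#' @param paths named list/vector with elements `patients`, `facilities`,
#'   `consultations`, `diagnoses`, `prescriptions`
#' @param config list of parsing options: `delimiter` (default `","`),
#'   `holiday_path` (optional text file, one `YYYY-MM-DD` per line)
#' @return a `claims_bundle`
#' @export
read_claims <- function(paths, config = list()) {
  delim <- config$delimiter %||% ","
  need <- names(CLAIMS_SCHEMA)
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    nbarti_error(sprintf("missing path(s) for table(s): %s",
                         paste(missing, collapse = ", ")),
                 "nbarti_schema_error")
  }
  for (nm in need) {
    if (!file.exists(paths[[nm]])) {
      nbarti_error(sprintf("file not found: %s", paths[[nm]]),
                   "nbarti_io_error")
    }
  }
  tabs <- lapply(need, function(nm) {
    fread(paths[[nm]], sep = delim, colClasses = "character",
          na.strings = NULL)
  })
  names(tabs) <- need
  holidays <- as.Date(character())
  if (!is.null(config$holiday_path)) {
    holidays <- parse_iso_date(readLines(config$holiday_path), "holiday")
  }
  claims_bundle(tabs$patients, tabs$facilities, tabs$consultations,
                tabs$diagnoses, tabs$prescriptions, holidays = holidays)
}

#' Write a claims bundle as delimited text files
#'
#' Inverse of [read_claims()]: re-reading the written directory yields an
#' identical bundle.
#'
#' @param bundle a `claims_bundle`
#' @param dir output directory (created if absent)
#' @param delimiter field separator (default comma)
#' @return named vector of the five file paths, invisibly
#' @export
write_claims <- function(bundle, dir, delimiter = ",") {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(names(CLAIMS_SCHEMA), ".csv"))
  names(paths) <- names(CLAIMS_SCHEMA)
  for (nm in names(CLAIMS_SCHEMA)) {
    out <- copy(bundle[[nm]])
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) {
        set(out, j = col, value = format(out[[col]], "%Y-%m-%d"))
      }
    }
    fwrite(out, paths[[nm]], sep = delimiter)
  }
  invisible(paths)
}
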