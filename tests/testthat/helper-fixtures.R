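`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-traced toy claims world used across the cohort tests.
#
# 5 patients, 3 facilities, 8 consultation lines (one exact duplicate -> 7
# unique). Expected pipeline counts, traced by hand from the linkage /
# exclusion / same-date rules:
#
#   window 30: ARTI 6 (C8 has only a non-ARTI code), bacterial exclusions 1
#     (C3 via J159 -> prefix J15), NB-ARTI 5, prescribed 2 (C1: J01DD04 +
#     J01CA04 union {ceph, penicillin}; C4: J01FA09; C6's J01MA02 is dated
#     one day late; C5's N02BE01 is non-J01)
#   window 60: the J18 dated 45 days before C6 becomes active -> exclusions
#     2, NB-ARTI 4
#   window  0: only same-day diagnoses -> ARTI 3 (C1, C5, C6), NB-ARTI 3,
#     prescribed 1
#
# Categories at window 30: C1 "J06", C4 "J02", C5 "J00 & J20", C6 "J06",
# C7 "others" (J21).

toy_tables <- function() {
  list(
    patients = data.frame(
      patient_id = c("P1", "P2", "P3", "P4", "P5"),
      sex = c("male", "female", "male", "female", "male"),
      birth_year_month = c("2008-03", "1980-06", "1950-01", "2013-10",
                           "1995-12"),
      insured_status = c("family_member", "member", "family_member",
                         "family_member", "member")),
    facilities = data.frame(
      facility_id = c("F1", "F2", "F3"),
      bed_count = c(0L, 150L, 10L),
      university = c(FALSE, TRUE, FALSE),
      public = c(FALSE, FALSE, FALSE),
      specialty = c("internal_medicine", "paediatrics", "ENT")),
    consultations = data.frame(
      patient_id = c("P1", "P1", "P2", "P3", "P4", "P5", "P2", "P3"),
      facility_id = c("F1", "F1", "F1", "F3", "F2", "F1", "F3", "F1"),
      date = c("2012-04-10", "2012-04-10", "2012-05-15", "2012-05-20",
               "2014-01-07", "2012-06-18", "2012-07-10", "2012-08-01"),
      visit_slot = c("10:00", "10:00", "19:00", "09:30", "11:00", "08:00",
                     "17:59", "12:00")),
    diagnoses = data.frame(
      patient_id = c("P1", "P2", "P2", "P3", "P4", "P4", "P5", "P5", "P2",
                     "P3"),
      facility_id = c("F1", "F1", "F1", "F3", "F2", "F2", "F1", "F1", "F3",
                      "F1"),
      code = c("J06", "J20", "J159", "J02", "J00", "J20", "J18", "J06",
               "J21", "I10"),
      diagnosis_date = c("2012-04-10", "2012-05-01", "2012-05-10",
                         "2012-04-20", "2014-01-07", "2014-01-05",
                         "2012-05-04", "2012-06-18", "2012-07-09",
                         "2012-07-25")),
    prescriptions = data.frame(
      patient_id = c("P1", "P1", "P3", "P5", "P4", "P2"),
      facility_id = c("F1", "F1", "F3", "F1", "F2", "F1"),
      date = c("2012-04-10", "2012-04-10", "2012-05-20", "2012-06-19",
               "2014-01-07", "2012-05-15"),
      atc_code = c("J01DD04", "J01CA04", "J01FA09", "J01MA02", "N02BE01",
                   "J01DD04")))
}

toy_bundle <- function() {
  tabs <- toy_tables()
  suppressWarnings(  # the duplicate consultation line is intentional
    claims_bundle(tabs$patients, tabs$facilities, tabs$consultations,
                  tabs$diagnoses, tabs$prescriptions))
}

toy_appropriateness <- function(mode = "strict") {
  appropriateness_table(
    codes = c("J00", "J02", "J06", "J20", "J21", "I10", "J15", "J18"),
    requires_antibiotics = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                             TRUE, TRUE),
    mode = mode)
}

# Small simulated worlds for property tests: a config whose bundles stay
# around a few dozen consultations.
tiny_sim_config <- function(...) {
  sim_config(n_patients = 25, n_facilities = 20, study_months = 6,
             consultation_rate = 3, ...)
}

# Write a bundle's five tables to a temp dir and return the path list
write_toy_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tabs <- toy_tables()
  paths <- list()
  for (nm in names(tabs)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(tabs[[nm]], paths[[nm]])
  }
  paths
}
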