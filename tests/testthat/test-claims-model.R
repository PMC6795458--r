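test_that("age groups follow year-month arithmetic and the nine-bin scheme", {
  expect_equal(as.character(derive_age_group("2010-05", as.Date("2013-04-15"))),
               "0-3")
  expect_equal(as.character(derive_age_group("1999-07", as.Date("2012-04-01"))),
               "7-12")
  expect_equal(as.character(derive_age_group("1950-01", as.Date("2015-06-30"))),
               "60-")
  # day of month is ignored: birth treated as the 1st
  expect_equal(as.character(derive_age_group("2000-06", as.Date("2010-06-01"))),
               "7-12")  # completed age 10 regardless of day
  expect_error(derive_age_group("2015-01", as.Date("2014-06-01")),
               class = "nbarti_domain_error")
  expect_error(derive_age_group("1930-01", as.Date("2012-04-01")),
               class = "nbarti_domain_error")  # age 82 > 75
})

test_that("age bins partition every age 0-75 exactly once", {
  cons <- as.Date("2015-06-15")
  for (age in 0:75) {
    births <- sprintf("%04d-06", 2015 - age)
    g <- derive_age_group(births, cons)
    expect_false(is.na(g))
    lo <- c(0, 4, 7, 13, 19, 30, 40, 50, 60)
    hi <- c(3, 6, 12, 18, 29, 39, 49, 59, 75)
    i <- match(as.character(g), levels(g))
    expect_true(age >= lo[i] && age <= hi[i])
  }
})

test_that("fiscal year runs April to March, labelled by the April year", {
  expect_equal(fiscal_year(as.Date("2013-03-31")), 2012L)
  expect_equal(fiscal_year(as.Date("2013-04-01")), 2013L)
  expect_equal(fiscal_year(as.Date("2017-06-30")), 2017L)
  expect_equal(fy_label(as.Date("2013-03-31")), "FY2012")
  # adding one calendar year always advances the fiscal year by exactly one
  dates <- seq(as.Date("2012-01-01"), by = "day", length.out = 400)
  shifted <- as.Date(vapply(dates, function(x) {
    format(seq(x, by = "1 year", length.out = 2)[2])
  }, character(1)))
  expect_true(all(fiscal_year(shifted) - fiscal_year(dates) == 1L))
})

test_that("visit-hours classification is total and matches the boundary rules", {
  wed <- as.Date("2012-04-11")   # Wednesday
  sun <- as.Date("2012-04-15")
  expect_equal(as.character(classify_visit_hours(wed, "10:00")), "in_hours")
  expect_equal(as.character(classify_visit_hours(wed, "18:30")),
               "out_of_hours")
  expect_equal(as.character(classify_visit_hours(sun, "09:00")),
               "out_of_hours")
  # half-open [08:00, 18:00)
  expect_equal(as.character(classify_visit_hours(wed, "08:00")), "in_hours")
  expect_equal(as.character(classify_visit_hours(wed, "17:59")), "in_hours")
  expect_equal(as.character(classify_visit_hours(wed, "18:00")),
               "out_of_hours")
  expect_equal(as.character(classify_visit_hours(wed, "07:59")),
               "out_of_hours")
  # configured holiday turns a weekday fully out-of-hours
  expect_equal(as.character(classify_visit_hours(wed, "10:00",
                                                 holidays = wed)),
               "out_of_hours")
  # pre-coded flags pass through
  expect_equal(as.character(classify_visit_hours(wed, "out_of_hours")),
               "out_of_hours")
  expect_error(classify_visit_hours(wed, "morning"),
               class = "nbarti_parse_error")

  # total and deterministic over a full week x hour grid
  week <- seq(as.Date("2024-01-01"), by = "day", length.out = 7)  # Mon..Sun
  grid <- expand.grid(d = week, h = 0:23)
  slot <- sprintf("%02d:00", grid$h)
  r1 <- classify_visit_hours(grid$d, slot)
  r2 <- classify_visit_hours(grid$d, slot)
  expect_identical(r1, r2)
  expect_false(anyNA(r1))
  wd <- as.integer(format(grid$d, "%u"))
  expect_identical(r1 == "in_hours",
                   wd <= 5 & grid$h >= 8 & grid$h < 18)
})

test_that("facility categories follow flags-then-beds precedence", {
  expect_equal(as.character(facility_category(0)), "clinic_without_beds")
  expect_equal(as.character(facility_category(19)), "clinic_with_beds")
  expect_equal(as.character(facility_category(20)), "other_hospital")
  expect_equal(as.character(facility_category(400, university = TRUE)),
               "university_hospital")
  expect_equal(as.character(facility_category(400, public = TRUE)),
               "public_hospital")
  expect_error(facility_category(10, university = TRUE, public = TRUE),
               class = "nbarti_domain_error")
})

test_that("read_claims validates schema, integrity, and de-duplicates", {
  paths <- write_toy_csvs()
  expect_warning(b <- read_claims(paths), "duplicate")
  expect_equal(nrow(b$consultations), 7L)
  expect_equal(attr(b, "n_duplicates_collapsed"), 1L)

  # empty-but-headered files: empty bundle, no warnings
  dir2 <- withr::local_tempdir()
  tabs <- toy_tables()
  paths2 <- list()
  for (nm in names(tabs)) {
    paths2[[nm]] <- file.path(dir2, paste0(nm, ".csv"))
    data.table::fwrite(tabs[[nm]][0, , drop = FALSE], paths2[[nm]])
  }
  expect_no_warning(b0 <- read_claims(paths2))
  expect_equal(nrow(b0$consultations), 0L)

  # unresolvable foreign key
  tabs3 <- toy_tables()
  tabs3$consultations$patient_id[3] <- "P99"
  expect_error(
    suppressWarnings(claims_bundle(tabs3$patients, tabs3$facilities,
                                   tabs3$consultations, tabs3$diagnoses,
                                   tabs3$prescriptions)),
    "P99", class = "nbarti_integrity_error")

  # missing column named in the error
  tabs4 <- toy_tables()
  tabs4$patients$sex <- NULL
  expect_error(
    claims_bundle(tabs4$patients, tabs4$facilities, tabs4$consultations,
                  tabs4$diagnoses, tabs4$prescriptions),
    "sex", class = "nbarti_schema_error")

  # unparseable date carries a row number
  tabs5 <- toy_tables()
  tabs5$diagnoses$diagnosis_date[4] <- "20120420"
  expect_error(
    suppressWarnings(claims_bundle(tabs5$patients, tabs5$facilities,
                                   tabs5$consultations, tabs5$diagnoses,
                                   tabs5$prescriptions)),
    "row", class = "nbarti_parse_error")
})

test_that("write_claims / read_claims round-trips a bundle", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  paths <- write_claims(b, dir)
  b2 <- read_claims(as.list(paths))
  for (nm in c("patients", "facilities", "consultations", "diagnoses",
               "prescriptions")) {
    expect_equal(as.data.frame(b[[nm]]), as.data.frame(b2[[nm]]),
                 ignore_attr = TRUE)
  }
})
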