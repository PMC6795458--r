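# build a minimal cohort-shaped object for rate arithmetic tests
fake_cohort <- function(month_index, prescribed, classes = NULL,
                        arti_monthly = NULL, start = "2012-04") {
  n <- length(month_index)
  dt <- data.table::data.table(
    cons_id = seq_len(n), month_index = month_index,
    prescribed = prescribed)
  if (is.null(classes)) {
    classes <- lapply(prescribed, function(p) {
      if (p) "third_gen_cephalosporin" else character()
    })
  }
  dt[, antibiotic_classes := classes]
  data.table::setattr(dt, "study_start", start)
  if (!is.null(arti_monthly)) {
    data.table::setattr(dt, "arti_monthly", arti_monthly)
  }
  data.table::setattr(dt, "class", c("nbarti_cohort", class(dt)))
  dt
}

test_that("monthly rates are 100 x numerator/denominator with undefined months flagged", {
  ch <- fake_cohort(month_index = c(rep(0L, 8), rep(2L, 4)),
                    prescribed = c(rep(TRUE, 2), rep(FALSE, 6),
                                   TRUE, TRUE, TRUE, FALSE))
  mr <- monthly_rate(ch)
  expect_equal(mr[month_index == 0, rate], 25.0)
  expect_equal(mr[month_index == 2, rate], 75.0)
  # month 1 has no consultations: flagged, NA rate
  expect_false(mr[month_index == 1, defined])
  expect_true(is.na(mr[month_index == 1, rate]))
  expect_equal(mr[month_index == 0, month_label], "2012-04")
  # undefined months are dropped from trend fits
  ch2 <- fake_cohort(month_index = c(0L, 0L, 2L, 2L, 3L, 3L, 5L, 5L),
                     prescribed = rep(c(TRUE, FALSE), 4))
  expect_equal(suppressWarnings(fit_trend(monthly_rate(ch2)))$n, 4L)
})

test_that("class-stratified numerators count a consultation once per class", {
  ch <- fake_cohort(
    month_index = rep(0L, 3),
    prescribed = c(TRUE, TRUE, FALSE),
    classes = list(c("macrolide", "penicillin"), "macrolide", character()))
  overall <- monthly_rate(ch)
  expect_equal(overall$numerator, 2L)   # not 3: multi-drug counts once
  expect_equal(overall$denominator, 3L)
  by_class <- monthly_rate(ch, "antibiotic_class")
  expect_equal(by_class[stratum == "macrolide", numerator], 2L)
  expect_equal(by_class[stratum == "penicillin", numerator], 1L)
  expect_equal(by_class[stratum == "fluoroquinolone", numerator], 0L)
  # class denominators are the overall denominator (classes don't partition
  # consultations)
  expect_true(all(by_class$denominator == 3L))
  expect_error(monthly_rate(ch, "no_such_column"),
               class = "nbarti_domain_error")
})

test_that("partitioning stratifier denominators sum to the overall denominator", {
  tab <- builtin_appropriateness("strict")
  b <- generate_bundle(sim_config(n_patients = 200, study_months = 8),
                       seed = 3)
  ch <- build_cohort(b, tab)
  overall <- monthly_rate(ch)
  for (strat in c("age_group", "diagnosis_category", "specialty")) {
    s <- monthly_rate(ch, strat)
    sums <- s[, .(denominator = sum(denominator)), by = month_index]
    m <- merge(overall[, .(month_index, denominator)], sums,
               by = "month_index")
    expect_equal(m$denominator.x, m$denominator.y)
  }
  # numerator never exceeds denominator
  expect_true(all(overall$numerator <= overall$denominator))
})

test_that("fit_trend matches exact lines, degenerate input, and closed-form OLS", {
  s <- data.table::data.table(month_index = 0:3, rate = c(30, 29, 28, 27),
                              defined = TRUE, stratum = "overall")
  f <- suppressWarnings(fit_trend(s))  # stats warns on an exact fit
  expect_equal(f$slope, -1.0)
  expect_equal(f$intercept, 30.0)
  expect_equal(f$r_squared, 1.0)

  const <- data.table::data.table(month_index = 0:5, rate = 10,
                                  defined = TRUE, stratum = "overall")
  expect_warning(fc <- fit_trend(const), "constant")
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  expect_error(fit_trend(s[1:2]), class = "nbarti_domain_error")

  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    x <- 0:(n - 1)
    y <- runif(1, -1, 1) * x + rnorm(n, sd = runif(1, 0.1, 5)) + 30
    f <- fit_trend(data.table::data.table(month_index = x, rate = y,
                                          defined = TRUE, stratum = "o"))
    o <- ols_closed_form(x, y)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("slope recovery: 63-month series from a known linear model", {
  # known slope -0.1, noise sd 1; estimate within 3 SEs nearly always
  set.seed(17)
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    x <- 0:62
    y <- 34 - 0.1 * x + rnorm(63, sd = 1)
    f <- fit_trend(data.table::data.table(month_index = x, rate = y,
                                          defined = TRUE, stratum = "o"))
    se <- sqrt(sum((y - f$intercept - f$slope * x)^2) / 61 /
                 sum((x - mean(x))^2))
    hits <- hits + as.integer(abs(f$slope - (-0.1)) <= 3 * se)
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("diagnosis-rate regression matches closed-form OLS on a hand-set world", {
  nb <- c(10L, 10L, 10L, 10L)
  yes <- c(2L, 4L, 6L, 8L)
  arti <- data.table::data.table(month_index = 0:3,
                                 n_arti = c(20L, 40L, 50L, 100L))
  ch <- fake_cohort(
    month_index = rep(0:3, nb),
    prescribed = unlist(lapply(1:4, function(i) {
      rep(c(TRUE, FALSE), c(yes[i], nb[i] - yes[i]))
    })),
    arti_monthly = arti)
  f <- rate_vs_diagnosisrate_regression(ch)
  x <- 100 * nb / arti$n_arti
  y <- 100 * yes / nb
  o <- ols_closed_form(x, y)
  expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
})

test_that("relative change reproduces endpoint arithmetic to one decimal", {
  s <- data.table::data.table(month_index = c(0L, 62L),
                              rate = c(34.36, 27.77), defined = TRUE)
  expect_equal(relative_change(s, 0, 62), -19.2)
  s2 <- data.table::data.table(month_index = 0:1, rate = c(50, 50),
                               defined = TRUE)
  expect_equal(relative_change(s2, 0, 1), 0.0)
  s3 <- data.table::data.table(month_index = 0:1, rate = c(50, 25),
                               defined = TRUE)
  expect_equal(relative_change(s3, 0, 1), -50.0)
  s4 <- data.table::data.table(month_index = 0:1, rate = c(0, 25),
                               defined = TRUE)
  expect_error(relative_change(s4, 0, 1), class = "nbarti_domain_error")
  expect_error(relative_change(s3, 0, 5), class = "nbarti_domain_error")
})

test_that("window sensitivity is consistent, deterministic and monotone", {
  b <- toy_bundle()
  tab <- toy_appropriateness()
  one <- window_sensitivity(b, tab, windows = 30)
  ch <- build_cohort(b, tab, window = 30)
  expect_equal(one$n_nbarti, attrition(ch)$n_nbarti)
  mr <- monthly_rate(ch)[defined == TRUE]
  expect_equal(one$mean_of_monthly_rate, mean(mr$rate))
  expect_equal(one$pooled_rate, 100 * sum(mr$numerator) / sum(mr$denominator))

  two <- window_sensitivity(b, tab, windows = c(30, 30))
  expect_equal(two[1], two[2], ignore_attr = TRUE)

  sweep <- window_sensitivity(b, tab, windows = c(0, 7, 30, 60))
  expect_true(all(diff(sweep$n_arti) >= 0))
  expect_true(all(diff(sweep$n_excluded_bacterial) >= 0))
  expect_error(window_sensitivity(b, tab, windows = -5),
               class = "nbarti_domain_error")
  expect_error(window_sensitivity(b, tab, windows = numeric()),
               class = "nbarti_domain_error")
})

test_that("composition table percentages follow the rounding convention", {
  # the printed-count arithmetic the reporting convention implies
  expect_equal(composition_percent(15194276, 17208787), 88.3)
  expect_equal(round_half_away(88.25), 88.3)
  expect_equal(round_half_away(-0.05), -0.1)

  ch <- build_cohort(toy_bundle(), toy_appropriateness())
  comp <- composition_table(ch)
  # every block's percents sum to ~100
  sums <- comp[, .(s = sum(percent)), by = block]
  expect_true(all(abs(sums$s - 100) <= 0.2))
  # counts per block sum to cohort size
  counts <- comp[, .(n = sum(count)), by = block]
  expect_true(all(counts$n == nrow(ch)))
  # five distinct age groups of one consultation each -> 20% apiece
  age <- comp[block == "age_group"]
  expect_true(all(age$percent == 20.0))

  single <- ch[1]
  data.table::setattr(single, "class", class(ch))
  comp1 <- composition_table(single)
  expect_true(all(comp1$percent == 100.0))
})
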