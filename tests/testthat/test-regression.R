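test_that("crude OR equals the 2x2 cross-product ratio", {
  ch <- cohort_from_2x2(30, 70, 20, 80)
  r <- fit_crude(ch, "grp", ref = "ref")
  expect_equal(r[level == "exp", or], cross_product_or(30, 70, 20, 80),
               tolerance = 1e-6)
  expect_equal(r[level == "ref", or], 1)
  expect_true(r[level == "ref", is_reference])
  expect_true(is.na(r[level == "ref", ci_low]))
  # CI brackets the estimate
  expect_true(r[level == "exp", ci_low < or & or < ci_high])

  # perfectly balanced outcome -> OR 1
  bal <- cohort_from_2x2(50, 50, 50, 50)
  expect_equal(fit_crude(bal, "grp", ref = "ref")[level == "exp", or], 1,
               tolerance = 1e-8)

  # oracle equivalence on 50 random tables, 6 significant figures
  set.seed(31)
  for (i in 1:50) {
    k <- sample(5:200, 4, replace = TRUE)
    ch <- cohort_from_2x2(k[1], k[2], k[3], k[4])
    got <- fit_crude(ch, "grp", ref = "ref")[level == "exp", or]
    want <- cross_product_or(k[1], k[2], k[3], k[4])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("exchanging the reference level inverts the OR", {
  set.seed(5)
  ch <- cohort_from_2x2(35, 61, 22, 80)
  a <- fit_crude(ch, "grp", ref = "ref")[level == "exp", or]
  b <- fit_crude(ch, "grp", ref = "exp")[level == "ref", or]
  expect_equal(a * b, 1, tolerance = 1e-8)
})

test_that("perfect separation and missing reference are clean errors", {
  sep <- cohort_from_2x2(40, 0, 20, 80)
  expect_error(fit_crude(sep, "grp", ref = "ref"), "exp",
               class = "nbarti_separation_error")
  ch <- cohort_from_2x2(30, 70, 20, 80)
  expect_error(fit_crude(ch, "grp", ref = "absent"),
               class = "nbarti_domain_error")
})

test_that("adjusted ORs equal crude ORs for a single-covariate model", {
  ch <- cohort_from_2x2(33, 67, 25, 75, levels = c("male", "female"))
  data.table::setnames(ch, "grp", "sex")
  spec <- model_spec(factors = c(sex = "male"))
  adj <- fit_adjusted(ch, spec)
  crude <- fit_crude(ch, "sex", ref = "male")
  expect_equal(adj[level == "female", or], crude[level == "female", or],
               tolerance = 1e-10)
  expect_equal(adj[level == "female", ci_low],
               crude[level == "female", ci_low], tolerance = 1e-10)
})

test_that("fit_adjusted recovers generator coefficients on a mid-size world", {
  mixes <- list(
    sex = c(male = 0.5, female = 0.5),
    age_group = c("60-" = 0.25, "0-3" = 0.25, "19-29" = 0.25,
                  "40-49" = 0.25),
    facility_category = c(other_hospital = 0.4, clinic_without_beds = 0.6))
  coefs <- list(
    sex = c(female = log(0.957)),
    age_group = c("0-3" = log(0.644), "19-29" = log(1.585),
                  "40-49" = log(1.385)),
    facility_category = c(clinic_without_beds = log(2.123)))
  dat <- make_regression_world(40000, coefs, intercept = -1.0,
                               mixes = mixes, seed = 8)
  spec <- model_spec(factors = c(sex = "male", age_group = "60-",
                                 facility_category = "other_hospital"))
  fit <- fit_adjusted(dat, spec)
  for (nm in names(coefs)) {
    for (lev in names(coefs[[nm]])) {
      row <- fit[term == nm & level == lev]
      truth <- exp(coefs[[nm]][[lev]])
      expect_true(row$ci_low < truth * 1.25 && row$ci_high > truth * 0.8,
                  label = sprintf("%s=%s CI near truth", nm, lev))
      expect_equal(row$or, truth, tolerance = 0.15)
    }
  }
})

test_that("null world: aORs near 1 and CIs usually cover 1", {
  mixes <- list(sex = c(male = 0.5, female = 0.5),
                visit_hours = c(in_hours = 0.8, out_of_hours = 0.2))
  covered <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    dat <- make_regression_world(4000, coefs = list(), intercept = 0,
                                 mixes = mixes, seed = 100 + i)
    fit <- fit_adjusted(dat, model_spec(factors = c(
      sex = "male", visit_hours = "in_hours")))
    row <- fit[term == "sex" & level == "female"]
    covered <- covered + as.integer(row$ci_low <= 1 & 1 <= row$ci_high)
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("confounding toggle makes crude and adjusted specialty ORs diverge", {
  tab <- builtin_appropriateness("strict")
  cfg <- sim_config(n_patients = 6000, study_months = 12,
                    confound_age_specialty = TRUE)
  ch <- build_cohort(generate_bundle(cfg, seed = 12), tab)
  crude <- fit_crude(ch, "specialty", ref = "others")
  spec <- model_spec(factors = c(specialty = "others", age_group = "60-"))
  adj <- fit_adjusted(ch, spec)
  c_or <- crude[level == "paediatrics", or]
  a_or <- adj[level == "paediatrics", or]
  # paediatrics sees children (low-prescribing ages): crude OR well below
  # the age-adjusted one
  expect_lt(c_or, a_or * 0.9)
})

test_that("or_table merges crude and adjusted columns consistently", {
  tab <- builtin_appropriateness("strict")
  ch <- build_cohort(generate_bundle(sim_config(n_patients = 1200,
                                                study_months = 12),
                                     seed = 4), tab)
  spec <- model_spec(factors = c(sex = "male", age_group = "60-",
                                 visit_hours = "in_hours"))
  out <- or_table(ch, spec)
  expect_setequal(out$term, c("sex", "age_group", "visit_hours"))
  expect_true(all(out[is_reference == TRUE, crude_or] == 1))
  expect_true(all(out[is_reference == TRUE, adjusted_or] == 1))
  expect_true(all(out[is_reference == FALSE,
                      crude_ci_low <= crude_or & crude_or <= crude_ci_high]))
})

test_that("stratified yearly aORs: single-specialty cohort matches overall", {
  tab <- builtin_appropriateness("strict")
  cfg <- sim_config(n_patients = 2500, study_months = 36,
                    specialty_mix = c(internal_medicine = 1,
                                      paediatrics = 0, ENT = 0, others = 0))
  ch <- build_cohort(generate_bundle(cfg, seed = 23), tab)
  sa <- suppressWarnings(stratified_yearly_aor(ch))
  ov <- sa[specialty == "overall"]
  im <- sa[specialty == "internal_medicine"]
  expect_equal(ov$aor, im$aor, tolerance = 1e-10)
  # reference year pinned at 1
  expect_equal(ov[fiscal_year == min(fiscal_year), aor], 1)
  # empty specialties reported as NA, not dropped
  expect_true(all(is.na(sa[specialty == "ENT", aor])))
})
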