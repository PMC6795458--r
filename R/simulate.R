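## Synthetic claims generator with known ground truth.
##
## The stated world: employee-insurance outpatients, nine age strata, five
## facility operation types x four specialties, winter-peaked ARTI visit
## intensity, ICD-10 diagnosis codes issued on or shortly before the visit,
## and same-date J01 prescriptions drawn from a logistic model whose
## covariate effects echo published adjusted odds ratios (as stylised
## parameter sources, never as data) plus a secular per-month log-odds trend.
##
## One structural guarantee matters for testability: consultations of the
## same patient are at least 77 days apart, so no diagnosis issued for one
## consultation can fall inside another consultation's 30-day linkage window
## (nor inside the 60-day sensitivity window once the 45-day decoy offset is
## added). The diagnosis-category covariate the pipeline derives therefore
## equals the generated one, and the prescribing model is exactly true for
## the analysis dataset.

REFRACTORY_DAYS <- 76L
DECOY_OFFSET_DAYS <- 45L

ABX_ATC_CODES <- list(
  third_gen_cephalosporin = c("J01DD04", "J01DD08", "J01DD13"),
  macrolide = c("J01FA09", "J01FA10", "J01FA01"),
  fluoroquinolone = c("J01MA02", "J01MA12", "J01MA14"),
  penicillin = c("J01CA04", "J01CR02"),
  other_J01 = c("J01AA02", "J01EE01", "J01XX01"))

NON_ABX_ATC <- c("R05DA09", "N02BE01", "R06AE07")

BACTERIAL_CODES <- c("J13", "J15", "J18")
OTHERS_POOL <- c("J04", "J05", "J21", "J22")

#' Simulation configuration for the synthetic claims generator
#'
#' Defaults describe one fixed stylised world echoing the marginal structure
#' of Japanese employee-insurance outpatient claims, 63 study months from
#' April 2012: age mix, facility mix and covariate effects near published
#' adjusted odds ratios, a mean prescribing rate near 31.65 per 100
#' consultations, and a secular decline of about 19% across the period.
#' See the methods vignette for the provenance of every default.
#'
#' @param n_patients,n_facilities population sizes
#' @param study_start first study month, `"YYYY-MM"`
#' @param study_months number of months (63 = April 2012 to June 2017)
#' @param age_distribution weights over the nine age bins (normalised)
#' @param p_male,p_member patient-level probabilities
#' @param facility_mix weights over the five operation-type categories
#' @param specialty_mix weights over the four specialties
#' @param consultation_rate mean ARTI visits per patient-year (before the
#'   same-patient refractory thinning; see vignette)
#' @param seasonality length-12 multipliers on monthly visit intensity
#'   (January first; normalised to mean 1)
#' @param p_bacterial_codiagnosis probability a visit carries an
#'   antibiotic-requiring co-diagnosis (and is later excluded)
#' @param p_decoy_out_of_window probability of a requiring diagnosis dated 45
#'   days before the visit (outside the default window; inside a 60-day one)
#' @param p_out_of_hours probability of an out-of-hours visit
#' @param diagnosis_category_weights weights over the 11 category labels
#' @param prescribing_model list: `intercept` (log-odds at the reference
#'   profile in month 0), `coef` (named list of named log-odds vectors per
#'   non-reference covariate level), `trend_per_month` (secular log-odds
#'   slope), `month_coef` (length-12 seasonal log-odds, January first)
#' @param class_mix multinomial weights over the five antibiotic classes
#' @param p_second_drug probability a prescribed visit receives a second drug
#' @param p_nonabx_rx probability of a same-date non-J01 decoy prescription
#' @param p_bacterial_prescribed prescribing probability at excluded
#'   (bacterial) visits
#' @param confound_age_specialty if `TRUE`, specialty is drawn conditionally
#'   on age (children mostly paediatrics), making crude and adjusted ORs
#'   diverge
#' @param seed default RNG seed used by [generate_bundle()]
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(
    n_patients = 4000,
    n_facilities = 120,
    study_start = "2012-04",
    study_months = 63,
    age_distribution = c("0-3" = 0.289, "4-6" = 0.132, "7-12" = 0.115,
                         "13-18" = 0.056, "19-29" = 0.076, "30-39" = 0.111,
                         "40-49" = 0.105, "50-59" = 0.075, "60-" = 0.042),
    p_male = 0.522,
    p_member = 0.269,
    facility_mix = c(clinic_without_beds = 0.883, clinic_with_beds = 0.021,
                     other_hospital = 0.073, university_hospital = 0.004,
                     public_hospital = 0.018),
    specialty_mix = c(internal_medicine = 0.532, paediatrics = 0.302,
                      ENT = 0.096, others = 0.071),
    consultation_rate = 2.0,
    seasonality = c(1.30, 1.25, 1.15, 1.00, 0.90, 0.85,
                    0.80, 0.70, 0.85, 0.95, 1.10, 1.25),
    p_bacterial_codiagnosis = 0.35,
    p_decoy_out_of_window = 0.05,
    p_out_of_hours = 0.15,
    diagnosis_category_weights = c(
      "J20" = 0.300, "J06" = 0.290, "J02" = 0.141, "J00" = 0.060,
      "J06 & J20" = 0.049, "J02 & J20" = 0.034, "J03" = 0.028,
      "J02 & J06" = 0.018, "J00 & J20" = 0.013, "J00 & J06" = 0.012,
      "others" = 0.058),
    prescribing_model = list(
      ## calibrated once so the default world's mean monthly rate over the
      ## 63 study months is 31.65 per 100 consultations (see vignette)
      intercept = -1.300311,
      coef = list(
        sex = c(female = log(0.957)),
        age_group = c("0-3" = log(0.644), "4-6" = log(0.959),
                      "7-12" = log(1.174), "13-18" = log(1.493),
                      "19-29" = log(1.585), "30-39" = log(1.507),
                      "40-49" = log(1.385), "50-59" = log(1.195)),
        insured_status = c(member = log(1.108)),
        specialty = c(internal_medicine = log(1.167),
                      paediatrics = log(0.878), ENT = log(1.424)),
        facility_category = c(clinic_without_beds = log(2.123),
                              clinic_with_beds = log(1.752),
                              university_hospital = log(0.739),
                              public_hospital = log(0.793)),
        visit_hours = c(out_of_hours = log(0.963)),
        diagnosis_category = c(
          "J06" = log(0.565), "J02" = log(0.989), "J00" = log(0.272),
          "J06 & J20" = log(1.152), "J02 & J20" = log(1.305),
          "J03" = log(1.460), "J02 & J06" = log(1.049),
          "J00 & J20" = log(1.019), "J00 & J06" = log(0.854),
          "others" = log(1.128))),
      trend_per_month = log(0.678) / 60,
      month_coef = rep(0, 12)),
    class_mix = c(third_gen_cephalosporin = 0.401, macrolide = 0.341,
                  fluoroquinolone = 0.144, penicillin = 0.060,
                  other_J01 = 0.054),
    p_second_drug = 0.05,
    p_nonabx_rx = 0.30,
    p_bacterial_prescribed = 0.80,
    confound_age_specialty = FALSE,
    seed = 20120401) {

  ## normalise JSON-style inputs: named lists become vectors; unnamed
  ## vectors of the right length take the canonical level order
  norm_w <- function(w, levels) {
    w <- unlist(w)
    if (is.null(names(w)) && length(w) == length(levels)) names(w) <- levels
    w
  }
  age_distribution <- norm_w(age_distribution, AGE_LABELS)
  facility_mix <- norm_w(facility_mix, FACILITY_LEVELS)
  specialty_mix <- norm_w(specialty_mix, SPECIALTY_LEVELS)
  diagnosis_category_weights <- norm_w(diagnosis_category_weights,
                                       DX_CATEGORY_LEVELS)
  class_mix <- norm_w(class_mix, ABX_CLASS_LEVELS)
  seasonality <- as.numeric(unlist(seasonality))
  if (!is.null(prescribing_model$coef)) {
    prescribing_model$coef <- lapply(prescribing_model$coef, unlist)
  }
  ## partial prescribing_model specs inherit the remaining defaults
  pm_default <- eval(formals(sim_config)$prescribing_model)
  for (nm in setdiff(names(pm_default), names(prescribing_model))) {
    prescribing_model[[nm]] <- pm_default[[nm]]
  }
  prescribing_model$month_coef <-
    as.numeric(unlist(prescribing_model$month_coef))

  cfg <- list(n_patients = n_patients, n_facilities = n_facilities,
              study_start = study_start, study_months = as.integer(study_months),
              age_distribution = age_distribution, p_male = p_male,
              p_member = p_member, facility_mix = facility_mix,
              specialty_mix = specialty_mix,
              consultation_rate = consultation_rate,
              seasonality = seasonality,
              p_bacterial_codiagnosis = p_bacterial_codiagnosis,
              p_decoy_out_of_window = p_decoy_out_of_window,
              p_out_of_hours = p_out_of_hours,
              diagnosis_category_weights = diagnosis_category_weights,
              prescribing_model = prescribing_model,
              class_mix = class_mix, p_second_drug = p_second_drug,
              p_nonabx_rx = p_nonabx_rx,
              p_bacterial_prescribed = p_bacterial_prescribed,
              confound_age_specialty = confound_age_specialty,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_weights <- function(w, nm, expected_names) {
    if (any(w < 0) || sum(w) <= 0 || anyNA(w)) {
      nbarti_error(sprintf("invalid weights in %s", nm), "nbarti_config_error")
    }
    if (!is.null(expected_names) && !setequal(names(w), expected_names)) {
      nbarti_error(sprintf("%s must be named over: %s", nm,
                           paste(expected_names, collapse = ", ")),
                   "nbarti_config_error")
    }
  }
  chk_weights(cfg$age_distribution, "age_distribution", AGE_LABELS)
  chk_weights(cfg$facility_mix, "facility_mix", FACILITY_LEVELS)
  chk_weights(cfg$specialty_mix, "specialty_mix", SPECIALTY_LEVELS)
  chk_weights(cfg$diagnosis_category_weights, "diagnosis_category_weights",
              DX_CATEGORY_LEVELS)
  chk_weights(cfg$class_mix, "class_mix", ABX_CLASS_LEVELS)
  if (length(cfg$seasonality) != 12 || any(cfg$seasonality < 0)) {
    nbarti_error("seasonality must be 12 non-negative multipliers",
                 "nbarti_config_error")
  }
  for (p in c("p_male", "p_member", "p_bacterial_codiagnosis",
              "p_decoy_out_of_window", "p_out_of_hours", "p_second_drug",
              "p_nonabx_rx", "p_bacterial_prescribed")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      nbarti_error(sprintf("%s must be in [0,1]", p), "nbarti_config_error")
    }
  }
  if (cfg$n_patients < 1 || cfg$n_facilities < 20 || cfg$study_months < 1) {
    nbarti_error("need n_patients >= 1, n_facilities >= 20, study_months >= 1",
                 "nbarti_config_error")
  }
  if (length(cfg$prescribing_model$month_coef) != 12) {
    nbarti_error("prescribing_model$month_coef must have length 12",
                 "nbarti_config_error")
  }
  invisible(cfg)
}

## specialty distribution conditional on age bin (9 x 4 matrix, rows sum 1)
specialty_given_age <- function(cfg) {
  base <- cfg$specialty_mix / sum(cfg$specialty_mix)
  m <- matrix(base, nrow = 9, ncol = 4, byrow = TRUE,
              dimnames = list(AGE_LABELS, SPECIALTY_LEVELS))
  if (isTRUE(cfg$confound_age_specialty)) {
    child <- c(internal_medicine = 0.15, paediatrics = 0.70,
               ENT = 0.08, others = 0.07)
    adult <- c(internal_medicine = 0.65, paediatrics = 0.02,
               ENT = 0.15, others = 0.18)
    m[1:3, ] <- matrix(child, 3, 4, byrow = TRUE)
    m[4:9, ] <- matrix(adult, 6, 4, byrow = TRUE)
  }
  m
}

## age-in-months-at-start support per bin (uniform), capped so age stays <= 75
age_month_range <- function(bin_idx, study_months) {
  lo <- AGE_LOWER[bin_idx] * 12L
  hi <- min((AGE_UPPER[bin_idx] + 1L) * 12L - 1L, 900L - study_months)
  c(lo, hi)
}

## P(age bin | month t) matrix: study_months x 9, exact under the uniform
## within-bin age-at-start draw
age_bin_by_month <- function(cfg) {
  a0 <- 0:(900L - cfg$study_months)
  w <- numeric(length(a0))
  for (b in seq_along(AGE_LABELS)) {
    r <- age_month_range(b, cfg$study_months)
    idx <- which(a0 >= r[1] & a0 <= r[2])
    w[idx] <- w[idx] + cfg$age_distribution[b] /
      sum(cfg$age_distribution) / length(idx)
  }
  out <- matrix(0, nrow = cfg$study_months, ncol = 9,
                dimnames = list(NULL, AGE_LABELS))
  for (t in seq_len(cfg$study_months) - 1L) {
    yrs <- (a0 + t) %/% 12L
    bin <- findInterval(pmin(yrs, 75L), AGE_LOWER)
    out[t + 1L, ] <- vapply(1:9, function(b) sum(w[bin == b]), numeric(1))
  }
  out
}

## log-odds contribution of a covariate level (0 for reference levels)
coef_of <- function(coefs, factor, levels_chr) {
  v <- coefs[[factor]]
  if (is.null(v)) return(numeric(length(levels_chr)))
  out <- v[levels_chr]
  out[is.na(out)] <- 0
  unname(out)
}

## category label -> list of 3-character code vectors ("others" draws one
## unlisted ARTI class at random)
dx_category_codes <- function(categories) {
  sets <- strsplit(categories, " & ", fixed = TRUE)
  others <- which(categories == "others")
  if (length(others)) {
    sets[others] <- as.list(sample(OTHERS_POOL, length(others),
                                   replace = TRUE))
  }
  sets
}

#' Generate a synthetic claims bundle
#'
#' Reproducible given the seed: the same `(config, seed)` always yields an
#' identical bundle. Every generated consultation carries at least one ARTI
#' diagnosis dated within the default linkage window, plus optional
#' antibiotic-requiring co-diagnoses (same episode), out-of-window decoy
#' requiring diagnoses, and non-J01 decoy prescriptions that the pipeline
#' must ignore.
#'
#' @param config a [sim_config()]
#' @param seed RNG seed (default `config$seed`)
#' @return a [claims_bundle()]; attribute `sim_truth_cols` names the hidden
#'   generation columns
#' @export
generate_bundle <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  cfg <- config
  n_mo <- cfg$study_months
  start <- cfg$study_start

  ## ---- patients -----------------------------------------------------------
  np <- cfg$n_patients
  age_w <- cfg$age_distribution / sum(cfg$age_distribution)
  bin0 <- sample.int(9L, np, replace = TRUE, prob = age_w)
  a0 <- vapply(bin0, function(b) {
    r <- age_month_range(b, n_mo)
    sample(r[1]:r[2], 1L)
  }, integer(1))
  o <- parse_year_month(start)
  birth_tot <- (o$year * 12L + o$month - 1L) - a0
  patients <- data.table(
    patient_id = sprintf("P%06d", seq_len(np)),
    sex = ifelse(runif(np) < cfg$p_male, "male", "female"),
    birth_year_month = sprintf("%04d-%02d", birth_tot %/% 12L,
                               birth_tot %% 12L + 1L),
    insured_status = ifelse(runif(np) < cfg$p_member, "member",
                            "family_member"))

  ## ---- facilities: >= 1 per (category, specialty) cell --------------------
  nf <- cfg$n_facilities
  cells <- CJ(category = FACILITY_LEVELS, specialty = SPECIALTY_LEVELS,
              sorted = FALSE)
  cat_w <- cfg$facility_mix / sum(cfg$facility_mix)
  spec_w <- cfg$specialty_mix / sum(cfg$specialty_mix)
  extra <- nf - nrow(cells)
  joint_w <- cat_w[cells$category] * spec_w[cells$specialty]
  extra_cells <- sample.int(nrow(cells), extra, replace = TRUE,
                            prob = joint_w)
  fac_cell <- c(seq_len(nrow(cells)), extra_cells)
  fac_cat <- cells$category[fac_cell]
  beds <- integer(nf)
  beds[fac_cat == "clinic_with_beds"] <-
    sample(1:19, sum(fac_cat == "clinic_with_beds"), replace = TRUE)
  beds[fac_cat == "other_hospital"] <-
    sample(20:500, sum(fac_cat == "other_hospital"), replace = TRUE)
  beds[fac_cat == "university_hospital"] <-
    sample(300:1200, sum(fac_cat == "university_hospital"), replace = TRUE)
  beds[fac_cat == "public_hospital"] <-
    sample(20:600, sum(fac_cat == "public_hospital"), replace = TRUE)
  facilities <- data.table(
    facility_id = sprintf("F%05d", seq_len(nf)),
    bed_count = beds,
    university = fac_cat == "university_hospital",
    public = fac_cat == "public_hospital",
    specialty = cells$specialty[fac_cell])
  fac_by_cell <- split(facilities$facility_id, fac_cell)

  ## ---- consultations ------------------------------------------------------
  season <- cfg$seasonality / mean(cfg$seasonality)
  cal_month <- vapply(seq_len(n_mo) - 1L, function(t) {
    as.integer(substr(month_label_of(t, start), 6, 7))
  }, integer(1))
  lam <- cfg$consultation_rate / 12 * season[cal_month]
  counts <- matrix(rpois(np * n_mo, rep(lam, each = np)), nrow = np)
  idx <- which(counts > 0, arr.ind = TRUE)
  cons <- data.table(pat = idx[, 1], t = idx[, 2] - 1L,
                     k = counts[idx])
  cons <- cons[rep(seq_len(.N), k)][, k := NULL]

  ## calendar scaffolding per month: weekday/weekend days of month
  first_days <- month_start_date(seq_len(n_mo) - 1L, start)
  ndays <- days_in_month(seq_len(n_mo) - 1L, start)
  weekday_days <- lapply(seq_len(n_mo), function(i) {
    d <- first_days[i] + 0:(ndays[i] - 1L)
    d[as.integer(format(d, "%u")) <= 5L]
  })
  weekend_days <- lapply(seq_len(n_mo), function(i) {
    d <- first_days[i] + 0:(ndays[i] - 1L)
    d[as.integer(format(d, "%u")) >= 6L]
  })

  cons[, ooh := runif(.N) < cfg$p_out_of_hours]
  ## out-of-hours visits: weekend day (any time) or weekday evening
  cons[, wk_evening := ooh & runif(.N) < 0.4]
  cons[, date := as.Date(NA)]
  for (i in seq_len(n_mo)) {
    t0 <- i - 1L
    sel_in <- cons$t == t0 & (!cons$ooh | cons$wk_evening)
    if (any(sel_in)) {
      cons[sel_in, date := sample(weekday_days[[i]], sum(sel_in),
                                  replace = TRUE)]
    }
    sel_we <- cons$t == t0 & cons$ooh & !cons$wk_evening
    if (any(sel_we)) {
      cons[sel_we, date := sample(weekend_days[[i]], sum(sel_we),
                                  replace = TRUE)]
    }
  }
  cons[, visit_slot := fifelse(
    ooh & wk_evening, "19:30",
    fifelse(ooh, "10:15",
            sprintf("%02d:%02d", sample(8:17, .N, replace = TRUE),
                    sample(0:59, .N, replace = TRUE))))]

  ## refractory thinning: same-patient visits > REFRACTORY_DAYS apart
  setorder(cons, pat, date)
  cons[, gap := as.integer(date - shift(date)), by = pat]
  cons <- cons[is.na(gap) | gap > REFRACTORY_DAYS][, gap := NULL]

  n <- nrow(cons)
  cons[, patient_id := patients$patient_id[pat]]
  cons[, sex := patients$sex[pat]]
  cons[, insured_status := patients$insured_status[pat]]
  cons[, age_bin := pmin((a0[pat] + t) %/% 12L, 75L)]
  cons[, age_group := AGE_LABELS[findInterval(age_bin, AGE_LOWER)]]

  ## facility cell: category by facility_mix, specialty | age
  spec_m <- specialty_given_age(cfg)
  cons[, cat_i := sample.int(5L, .N, replace = TRUE, prob = cat_w)]
  cons[, spec_i := 0L]
  for (b in 1:9) {
    sel <- cons$age_group == AGE_LABELS[b]
    if (any(sel)) {
      cons[sel, spec_i := sample.int(4L, sum(sel), replace = TRUE,
                                     prob = spec_m[b, ])]
    }
  }
  cons[, cell := (cat_i - 1L) * 4L + spec_i]  # CJ(category, specialty) order
  cons[, facility_id := NA_character_]
  for (cl in unique(cons$cell)) {
    pool <- fac_by_cell[[as.character(cl)]]
    sel <- cons$cell == cl
    cons[sel, facility_id := pool[sample.int(length(pool), sum(sel),
                                             replace = TRUE)]]
  }
  cons[, facility_category := FACILITY_LEVELS[cat_i]]
  cons[, specialty := SPECIALTY_LEVELS[spec_i]]

  ## diagnosis category and episode flags
  dxw <- cfg$diagnosis_category_weights /
    sum(cfg$diagnosis_category_weights)
  cons[, dx_cat := sample(DX_CATEGORY_LEVELS, .N, replace = TRUE,
                          prob = dxw)]
  cons[, bacterial := runif(.N) < cfg$p_bacterial_codiagnosis]
  cons[, decoy := runif(.N) < cfg$p_decoy_out_of_window]

  ## ---- diagnoses ----------------------------------------------------------
  code_sets <- dx_category_codes(cons$dx_cat)
  n_codes_per <- lengths(code_sets)
  dx <- data.table(
    row = rep(seq_len(n), n_codes_per),
    code = unlist(code_sets))
  dx[, offset := fifelse(runif(.N) < 0.8, 0L,
                         sample(1:7, .N, replace = TRUE))]
  ## finer national-code suffix on some codes exercises prefix matching
  dx[, code := fifelse(runif(.N) < 0.3, paste0(code, "0"), code)]
  if (any(cons$bacterial)) {
    nb <- sum(cons$bacterial)
    dx <- rbind(dx, data.table(
      row = which(cons$bacterial),
      code = sample(BACTERIAL_CODES, nb, replace = TRUE),
      offset = sample(0:7, nb, replace = TRUE)))
  }
  if (any(cons$decoy)) {
    dx <- rbind(dx, data.table(
      row = which(cons$decoy),
      code = sample(BACTERIAL_CODES, sum(cons$decoy), replace = TRUE),
      offset = DECOY_OFFSET_DAYS))
  }
  diagnoses <- dx[, .(patient_id = cons$patient_id[row],
                      facility_id = cons$facility_id[row],
                      code,
                      diagnosis_date = cons$date[row] - offset)]

  ## ---- prescriptions ------------------------------------------------------
  pm <- cfg$prescribing_model
  eta <- pm$intercept +
    coef_of(pm$coef, "sex", cons$sex) +
    coef_of(pm$coef, "age_group", cons$age_group) +
    coef_of(pm$coef, "insured_status", cons$insured_status) +
    coef_of(pm$coef, "specialty", cons$specialty) +
    coef_of(pm$coef, "facility_category", cons$facility_category) +
    coef_of(pm$coef, "visit_hours",
            ifelse(cons$ooh, "out_of_hours", "in_hours")) +
    coef_of(pm$coef, "diagnosis_category", cons$dx_cat) +
    pm$trend_per_month * cons$t +
    pm$month_coef[as.integer(format(cons$date, "%m"))]
  p <- plogis(eta)
  cons[, rx := fifelse(bacterial, runif(.N) < cfg$p_bacterial_prescribed,
                       runif(.N) < p)]

  rx_rows <- which(cons$rx)
  classw <- cfg$class_mix / sum(cfg$class_mix)
  draw_atc <- function(k) {
    cls <- sample(ABX_CLASS_LEVELS, k, replace = TRUE, prob = classw)
    out <- character(k)
    for (cl in unique(cls)) {
      codes <- ABX_ATC_CODES[[cl]]
      sel <- cls == cl
      out[sel] <- codes[sample.int(length(codes), sum(sel), replace = TRUE)]
    }
    out
  }
  rx1 <- data.table(row = rx_rows, atc_code = draw_atc(length(rx_rows)))
  second <- rx_rows[runif(length(rx_rows)) < cfg$p_second_drug]
  rx2 <- data.table(row = second, atc_code = draw_atc(length(second)))
  decoy_rx_rows <- which(runif(n) < cfg$p_nonabx_rx)
  rx3 <- data.table(row = decoy_rx_rows,
                    atc_code = sample(NON_ABX_ATC, length(decoy_rx_rows),
                                      replace = TRUE))
  rx <- rbind(rx1, rx2, rx3)
  prescriptions <- rx[, .(patient_id = cons$patient_id[row],
                          facility_id = cons$facility_id[row],
                          date = cons$date[row], atc_code)]
  setorder(prescriptions, patient_id, date, atc_code)

  consultations <- cons[, .(patient_id, facility_id, date, visit_slot)]
  setorder(consultations, patient_id, date)
  setorder(diagnoses, patient_id, diagnosis_date, code)

  bundle <- claims_bundle(patients, facilities, consultations, diagnoses,
                          prescriptions)
  attr(bundle, "sim_seed") <- seed
  bundle
}

#' Closed-form ground truth of a simulation configuration
#'
#' True odds ratios are the exponentiated generator coefficients. Because
#' the month index decomposes exactly as
#' `t = 12 * (fiscal_year - first_year) + ((calendar_month - 4) mod 12)`,
#' the secular trend is exactly representable by fiscal-year and month
#' factors, so true ORs are also available for the fiscal-year and month
#' terms the adjusted model fits. The expected monthly prescribing rate is
#' computed by exact enumeration over the finite covariate grid (no
#' simulation).
#'
#' @param config a [sim_config()]
#' @return list of class `ground_truth`: `true_or` (named list per factor),
#'   `monthly_rate` (data.table `month_index`, `rate` per 100),
#'   `mean_rate` (mean of the monthly curve), `expected_cohort_size`
#'   (approximate; thinning makes it an upper bound)
#' @export
ground_truth <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  pm <- cfg$prescribing_model
  n_mo <- cfg$study_months
  start <- cfg$study_start
  o <- parse_year_month(start)

  true_or <- lapply(pm$coef, exp)
  ## fiscal-year and month true ORs implied by trend + month_coef
  first_fy <- o$year - as.integer(o$month < 4L)
  last_date <- month_start_date(n_mo - 1L, start)
  fys <- seq(first_fy, fiscal_year(last_date))
  true_or$fiscal_year <- setNames(
    exp(12 * pm$trend_per_month * (fys - first_fy)), as.character(fys))[-1]
  moff <- ((1:12 - o$month) %% 12)   # months since study-start month
  jan <- moff[1]
  month_lor <- pm$trend_per_month * (moff - jan) +
    (pm$month_coef - pm$month_coef[1])
  true_or$month <- setNames(exp(month_lor), MONTH_LEVELS)[-1]
  true_or$trend_per_month <- exp(pm$trend_per_month)

  ## exact enumeration of the expected conditional rate per month
  sexes <- data.table(lev = SEX_LEVELS,
                      w = c(cfg$p_male, 1 - cfg$p_male),
                      b = coef_of(pm$coef, "sex", SEX_LEVELS))
  ins <- data.table(lev = INSURED_LEVELS,
                    w = c(cfg$p_member, 1 - cfg$p_member),
                    b = coef_of(pm$coef, "insured_status", INSURED_LEVELS))
  hrs <- data.table(lev = HOURS_LEVELS,
                    w = c(1 - cfg$p_out_of_hours, cfg$p_out_of_hours),
                    b = coef_of(pm$coef, "visit_hours", HOURS_LEVELS))
  fac <- data.table(lev = FACILITY_LEVELS,
                    w = as.numeric(cfg$facility_mix / sum(cfg$facility_mix)),
                    b = coef_of(pm$coef, "facility_category", FACILITY_LEVELS))
  dx <- data.table(lev = DX_CATEGORY_LEVELS,
                   w = as.numeric(cfg$diagnosis_category_weights /
                                    sum(cfg$diagnosis_category_weights)),
                   b = coef_of(pm$coef, "diagnosis_category",
                               DX_CATEGORY_LEVELS))
  static <- CJ(s = seq_len(nrow(sexes)), i = seq_len(nrow(ins)),
               h = seq_len(nrow(hrs)), f = seq_len(nrow(fac)),
               d = seq_len(nrow(dx)))
  static_w <- sexes$w[static$s] * ins$w[static$i] * hrs$w[static$h] *
    fac$w[static$f] * dx$w[static$d]
  static_b <- sexes$b[static$s] + ins$b[static$i] + hrs$b[static$h] +
    fac$b[static$f] + dx$b[static$d]

  spec_m <- specialty_given_age(cfg)
  age_b <- coef_of(pm$coef, "age_group", AGE_LABELS)
  spec_b <- coef_of(pm$coef, "specialty", SPECIALTY_LEVELS)
  p_age <- age_bin_by_month(cfg)

  rates <- vapply(seq_len(n_mo) - 1L, function(t) {
    cal <- as.integer(substr(month_label_of(t, start), 6, 7))
    base <- pm$intercept + pm$trend_per_month * t + pm$month_coef[cal]
    ## joint (age, specialty) weights and log-odds
    w_as <- as.vector(p_age[t + 1L, ] * spec_m)       # 9 x 4 recycled by column
    b_as <- as.vector(outer(age_b, spec_b, "+"))
    eta <- outer(static_b + base, b_as, "+")
    100 * sum((static_w %o% w_as) * plogis(eta))
  }, numeric(1))

  monthly <- data.table(month_index = seq_len(n_mo) - 1L, rate = rates)
  expected_size <- cfg$n_patients * cfg$consultation_rate * (n_mo / 12) *
    (1 - cfg$p_bacterial_codiagnosis)
  structure(list(true_or = true_or, monthly_rate = monthly,
                 mean_rate = mean(rates),
                 expected_cohort_size = expected_size),
            class = "ground_truth")
}
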