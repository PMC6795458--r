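# Independent brute-force oracles. These deliberately use nothing from the
# package's pipeline path beyond the appropriateness lookup table contents:
# plain loops over every (consultation, diagnosis, prescription) triple.

# One row per NB-ARTI consultation with category, prescribed flag, and the
# sorted class set, comparable against build_cohort() output.
brute_force_cohort <- function(bundle, table, window) {
  co <- as.data.frame(bundle$consultations)
  di <- as.data.frame(bundle$diagnoses)
  rx <- as.data.frame(bundle$prescriptions)
  verdicts <- table$entries
  lookup_requires <- function(code) {
    hit <- verdicts$requires[match(code, verdicts$code)]
    if (is.na(hit)) hit <- verdicts$requires[match(substr(code, 1, 3),
                                                   verdicts$code)]
    isTRUE(hit)
  }
  classify1 <- function(atc) {
    if (startsWith(atc, "J01DD")) return("third_gen_cephalosporin")
    if (startsWith(atc, "J01FA")) return("macrolide")
    if (startsWith(atc, "J01MA")) return("fluoroquinolone")
    if (startsWith(atc, "J01C")) return("penicillin")
    "other_J01"
  }
  arti <- c("J00", "J01", "J02", "J03", "J04", "J05", "J06",
            "J20", "J21", "J22")
  out <- list()
  n_arti <- 0L
  n_excluded <- 0L
  for (i in seq_len(nrow(co))) {
    active <- character()
    for (j in seq_len(nrow(di))) {
      if (di$patient_id[j] == co$patient_id[i] &&
          di$diagnosis_date[j] <= co$date[i] &&
          di$diagnosis_date[j] >= co$date[i] - window) {
        active <- c(active, di$code[j])
      }
    }
    active <- unique(active)
    classes3 <- unique(substr(active, 1, 3))
    arti_classes <- sort(intersect(classes3, arti))
    if (length(arti_classes) == 0) next
    n_arti <- n_arti + 1L
    if (any(vapply(active, lookup_requires, logical(1)))) {
      n_excluded <- n_excluded + 1L
      next
    }
    key <- paste(arti_classes, collapse = " & ")
    singles <- c("J20", "J06", "J02", "J00", "J03")
    pairs <- c("J06 & J20", "J02 & J20", "J02 & J06", "J00 & J20",
               "J00 & J06")
    category <- if (key %in% c(singles, pairs)) key else "others"
    drugs <- character()
    for (j in seq_len(nrow(rx))) {
      if (rx$patient_id[j] == co$patient_id[i] &&
          rx$date[j] == co$date[i] &&
          startsWith(rx$atc_code[j], "J01")) {
        drugs <- c(drugs, classify1(rx$atc_code[j]))
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = co$patient_id[i], facility_id = co$facility_id[i],
      date = co$date[i], diagnosis_category = category,
      prescribed = length(drugs) > 0,
      classes = paste(sort(unique(drugs)), collapse = ";"))
  }
  list(cohort = if (length(out)) do.call(rbind, out) else NULL,
       n_arti = n_arti, n_excluded = n_excluded)
}

# comparable flat view of a built cohort
flatten_cohort <- function(cohort) {
  df <- as.data.frame(cohort)[, c("patient_id", "facility_id", "date",
                                  "diagnosis_category", "prescribed")]
  df$diagnosis_category <- as.character(df$diagnosis_category)
  df$classes <- vapply(cohort$antibiotic_classes, function(x) {
    paste(sort(x), collapse = ";")
  }, character(1))
  df[order(df$patient_id, df$facility_id, df$date), ]
}

# closed-form OLS slope/intercept oracle
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# cross-product odds ratio of a 2x2 (exposed yes/no vs ref yes/no)
cross_product_or <- function(a_yes, a_no, b_yes, b_no) {
  (a_yes * b_no) / (a_no * b_yes)
}

# cohort-shaped table from explicit 2x2 counts
cohort_from_2x2 <- function(a_yes, a_no, b_yes, b_no,
                            levels = c("ref", "exp")) {
  data.table::data.table(
    grp = factor(rep(levels, c(b_yes + b_no, a_yes + a_no)),
                 levels = levels),
    prescribed = c(rep(c(TRUE, FALSE), c(b_yes, b_no)),
                   rep(c(TRUE, FALSE), c(a_yes, a_no))))
}

# cohort-like table drawn directly from a logistic model over the config's
# covariate mixture: the regression-test oracle world (no claims plumbing)
make_regression_world <- function(n, coefs, intercept, mixes, seed) {
  set.seed(seed)
  dat <- data.table::data.table(.n = seq_len(n))
  eta <- rep(intercept, n)
  for (nm in names(mixes)) {
    levs <- names(mixes[[nm]])
    x <- sample(levs, n, replace = TRUE, prob = mixes[[nm]])
    dat[[nm]] <- factor(x, levels = levs)
    b <- coefs[[nm]]
    if (!is.null(b)) {
      add <- b[x]
      add[is.na(add)] <- 0
      eta <- eta + unname(add)
    }
  }
  dat$.n <- NULL
  dat$prescribed <- stats::runif(n) < stats::plogis(eta)
  dat
}
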