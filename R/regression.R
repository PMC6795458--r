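## Crude and adjusted odds-ratio models for the prescribed-antibiotic flag.

#' Model specification for the adjusted logistic regression
#'
#' Ordered list of categorical covariates with their reference levels, as
#' used for the full adjusted model: sex (ref male), age group (ref 60-),
#' insured status (ref family member), facility specialty (ref others),
#' facility operation type (ref other hospitals), visit hours (ref
#' in-hours), diagnosis category (ref acute bronchitis J20), fiscal year
#' (ref the first study year) and calendar month (ref January).
#'
#' @param factors named character vector mapping factor column to reference
#'   level; defaults to the full covariate set
#' @return object of class `model_spec`
#' @export
model_spec <- function(factors = c(
  sex = "male", age_group = "60-", insured_status = "family_member",
  specialty = "others", facility_category = "other_hospital",
  visit_hours = "in_hours", diagnosis_category = "J20",
  fiscal_year = "2012", month = "January")) {
  structure(list(factors = factors), class = "model_spec")
}

## prepare one factor column: reference first, empty levels dropped (warned)
prep_factor <- function(x, ref, name) {
  f <- factor(as.character(x))
  present <- levels(f)
  if (!ref %in% present) {
    nbarti_error(sprintf("reference level '%s' of '%s' absent from data",
                         ref, name), "nbarti_domain_error")
  }
  orig <- levels(x)
  if (!is.null(orig)) {
    dropped <- setdiff(orig, present)
    if (length(dropped)) {
      warning(sprintf("dropping empty level(s) of %s: %s", name,
                      paste(dropped, collapse = ", ")), call. = FALSE)
    }
  }
  stats::relevel(f, ref = ref)
}

## shared logistic fit -> OR rows; IRLS via stats::glm, Wald 95% CIs
fit_logistic_or <- function(dat, factors, type) {
  dat <- as.data.table(dat)
  keep <- complete.cases(dat[, c("prescribed", names(factors)), with = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(sprintf("complete-case analysis: dropped %d row(s)", n_dropped))
    dat <- dat[keep]
  }
  mf <- data.table(prescribed = as.integer(dat$prescribed))
  for (nm in names(factors)) {
    mf[, (nm) := prep_factor(dat[[nm]], factors[[nm]], nm)]
    ## perfect separation guard: a non-reference level with one-sided outcome
    tab <- table(mf[[nm]], mf$prescribed)
    if (ncol(tab) < 2) {
      nbarti_error(sprintf("outcome constant within '%s'", nm),
                   "nbarti_separation_error")
    }
    onesided <- rownames(tab)[rowSums(tab == 0) > 0]
    if (length(onesided)) {
      nbarti_error(
        sprintf("perfect separation: level(s) %s of '%s' have one-sided outcome",
                paste(onesided, collapse = ", "), nm),
        "nbarti_separation_error")
    }
  }
  form <- stats::as.formula(
    paste("prescribed ~", paste(names(factors), collapse = " + ")))
  fit <- glm(form, family = binomial(), data = mf,
             control = list(epsilon = 1e-10, maxit = 100),
             model = FALSE, x = FALSE, y = FALSE)
  if (!fit$converged) {
    nbarti_error(sprintf("logistic fit did not converge in %d iterations",
                         fit$iter), "nbarti_convergence_error")
  }
  beta <- coef(fit)
  if (anyNA(beta)) {
    nbarti_error(
      sprintf("rank-deficient design; aliased: %s",
              paste(names(beta)[is.na(beta)], collapse = ", ")),
      "nbarti_rank_error")
  }
  se <- sqrt(diag(vcov(fit)))

  rows <- rbindlist(lapply(names(factors), function(nm) {
    lev <- levels(mf[[nm]])
    coefnames <- paste0(nm, lev[-1])
    est <- beta[coefnames]
    s <- se[coefnames]
    rbind(
      data.table(term = nm, level = lev[1], is_reference = TRUE,
                 or = 1, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_),
      data.table(term = nm, level = lev[-1], is_reference = FALSE,
                 or = exp(est),
                 ci_low = exp(est - 1.96 * s),
                 ci_high = exp(est + 1.96 * s),
                 p_value = 2 * stats::pnorm(-abs(est / s))))
  }))
  setattr(rows, "model",
          list(type = type, n = nrow(mf), n_dropped = n_dropped,
               loglik = as.numeric(stats::logLik(fit)),
               coefficients = beta, se = se, converged = fit$converged))
  setattr(rows, "class", c("or_table", class(rows)))
  rows[]
}

#' Crude odds ratios for one factor
#'
#' Single-factor logistic regression of the prescribed flag; the exponent of
#' each non-reference coefficient is the crude OR and equals the 2x2
#' cross-product ratio against the reference level. 95% CIs are Wald
#' intervals on the log scale.
#'
#' @param cohort an `nbarti_cohort` (or any data.frame with `prescribed`)
#' @param factor name of the factor column
#' @param ref reference level (default: the declared reference in
#'   [model_spec()], if the factor is part of it)
#' @return an `or_table` (data.table with `term`, `level`, `is_reference`,
#'   `or`, `ci_low`, `ci_high`, `p_value`)
#' @export
fit_crude <- function(cohort, factor, ref = NULL) {
  spec <- model_spec()
  if (is.null(ref)) {
    ref <- spec$factors[[factor]] %||%
      as.character(sort(unique(as.character(cohort[[factor]])))[1])
  }
  factors <- setNames(ref, factor)
  fit_logistic_or(cohort, factors, type = "crude")
}

#' Adjusted odds ratios from the full multivariate logistic model
#'
#' One joint logistic regression containing every factor in the spec;
#' returns Wald 95% CIs per non-reference level. Fiscal year and calendar
#' month are both included (they are only partially confounded because the
#' study year starts in April); the design matrix is checked for rank.
#'
#' @param cohort an `nbarti_cohort`
#' @param spec a [model_spec()]
#' @return an `or_table` with a `model` attribute (n, log-likelihood,
#'   coefficients)
#' @export
fit_adjusted <- function(cohort, spec = model_spec()) {
  fit_logistic_or(cohort, spec$factors, type = "adjusted")
}

#' Combined crude + adjusted OR table
#'
#' Fits one crude model per factor and the joint adjusted model, and merges
#' them into the conventional two-column report layout.
#'
#' @param cohort an `nbarti_cohort`
#' @param spec a [model_spec()]
#' @return data.table: `term`, `level`, `is_reference`, `crude_or`,
#'   `crude_ci_low`, `crude_ci_high`, `adjusted_or`, `adjusted_ci_low`,
#'   `adjusted_ci_high`
#' @export
or_table <- function(cohort, spec = model_spec()) {
  adj <- fit_adjusted(cohort, spec)
  crude <- rbindlist(lapply(names(spec$factors), function(nm) {
    fit_crude(cohort, nm, ref = spec$factors[[nm]])
  }))
  out <- merge(
    crude[, .(term, level, is_reference, crude_or = or,
              crude_ci_low = ci_low, crude_ci_high = ci_high)],
    adj[, .(term, level, adjusted_or = or,
            adjusted_ci_low = ci_low, adjusted_ci_high = ci_high)],
    by = c("term", "level"), sort = FALSE)
  out[]
}

#' Specialty-stratified yearly adjusted odds ratios
#'
#' Within each facility-specialty stratum (and overall), fits a logistic
#' model with sex, age group, insured status, facility operation type, visit
#' hours and calendar month as covariates plus fiscal year, and reports the
#' adjusted OR of each fiscal year against the first study year. A fiscal
#' year absent from a stratum is reported as `NA`, not imputed.
#'
#' @param cohort an `nbarti_cohort`
#' @param ref_year reference fiscal year (default the cohort's earliest)
#' @return data.table: `specialty` (including `"overall"`), `fiscal_year`,
#'   `aor`, `ci_low`, `ci_high`
#' @export
stratified_yearly_aor <- function(cohort, ref_year = NULL) {
  co <- as.data.table(cohort)
  ref_year <- as.character(ref_year %||% min(co$fiscal_year))
  covariates <- c(sex = "male", age_group = "60-",
                  insured_status = "family_member",
                  facility_category = "other_hospital",
                  visit_hours = "in_hours", month = "January",
                  fiscal_year = ref_year)
  years <- sort(unique(co$fiscal_year))
  strata <- c("overall", levels(co$specialty))
  rows <- lapply(strata, function(s) {
    dat <- if (s == "overall") co else co[specialty == s]
    ## drop covariates collapsing to a single level in this stratum
    use <- covariates
    for (nm in names(use)) {
      if (length(unique(as.character(dat[[nm]]))) < 2) {
        use <- use[names(use) != nm]
      }
    }
    if (!"fiscal_year" %in% names(use)) {
      return(data.table(specialty = s, fiscal_year = years, aor = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    tab <- tryCatch(fit_logistic_or(dat, use, type = "adjusted"),
                    error = function(e) {
                      warning(sprintf("stratum '%s' not fitted: %s", s,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (is.null(tab)) {
      return(data.table(specialty = s, fiscal_year = years, aor = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    fy <- tab[term == "fiscal_year" & is_reference == FALSE]
    out <- data.table(specialty = s, fiscal_year = years)
    out <- merge(out, fy[, .(fiscal_year = as.integer(level), aor = or,
                             ci_low, ci_high)],
                 by = "fiscal_year", all.x = TRUE)
    out[fiscal_year == as.integer(ref_year),
        `:=`(aor = 1, ci_low = NA_real_, ci_high = NA_real_)]
    out[, .(specialty, fiscal_year, aor, ci_low, ci_high)]
  })
  rbindlist(rows)
}
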