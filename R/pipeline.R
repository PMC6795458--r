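## Run orchestration: config validation, staged execution, manifest.

#' Validate a run configuration
#'
#' Schema-checks a run configuration without executing anything and returns
#' every problem found, not just the first. A valid configuration names
#' exactly one input source — `input` (the five table paths) or `simulate`
#' (a [sim_config()]-style list) — plus an appropriateness table (`path` or
#' `"builtin"`), a non-negative linkage `window`, and an output directory.
#'
#' @param config a list, or a path to a JSON file holding one
#' @return character vector of problems (empty when valid)
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      nbarti_error(sprintf("config file not found: %s", config),
                   "nbarti_io_error")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  problems <- character()
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    problems <- c(problems,
                  "exactly one of 'input' and 'simulate' must be present")
  }
  if (has_input) {
    missing <- setdiff(names(CLAIMS_SCHEMA), names(config$input))
    if (length(missing)) {
      problems <- c(problems, sprintf("input: missing table path(s): %s",
                                      paste(missing, collapse = ", ")))
    }
    for (nm in intersect(names(CLAIMS_SCHEMA), names(config$input))) {
      if (!file.exists(config$input[[nm]])) {
        problems <- c(problems, sprintf("input$%s: file not found: %s",
                                        nm, config$input[[nm]]))
      }
    }
  }
  if (has_sim && !has_input) {
    ok <- tryCatch({
      do.call(sim_config, config$simulate)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) problems <- c(problems, paste("simulate:", ok))
  }
  ap <- config$appropriateness %||% "builtin"
  if (!identical(ap, "builtin") && !file.exists(ap)) {
    problems <- c(problems,
                  sprintf("appropriateness: file not found: %s", ap))
  }
  w <- config[["window"]] %||% 30
  if (any(w < 0)) problems <- c(problems, "window: must be non-negative")
  if (!is.null(config$windows) && any(config$windows < 0)) {
    problems <- c(problems, "windows: must be non-negative")
  }
  if (is.null(config$out_dir)) {
    problems <- c(problems, "out_dir: required")
  }
  problems
}

#' Run the full pipeline and write its artifact directory
#'
#' Stages: (optionally) simulate a bundle, build the NB-ARTI cohort, then
#' composition table, monthly rates (overall plus requested stratifiers),
#' trend fits, crude/adjusted odds-ratio tables, specialty-stratified yearly
#' adjusted ORs, and the linkage-window sensitivity sweep. A
#' `manifest.json` records inputs, seed, row counts and MD5 checksums of
#' every artifact, so a rerun with the same configuration and seed is
#' byte-identical where floating point allows (it does here: all stages are
#' deterministic given the seed).
#'
#' @param config list or JSON path; see [validate_run_config()]. Recognised
#'   stage toggles: `stages` (character subset of `c("cohort", "composition",
#'   "rates", "trend", "regression", "stratified", "sensitivity")`),
#'   `stratifiers` (default `c("age_group", "diagnosis_category",
#'   "antibiotic_class")`), `windows` for the sweep, `seed` override.
#' @return invisibly, named vector of artifact paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  problems <- validate_run_config(config)
  if (length(problems)) {
    nbarti_error(paste0("invalid run config:\n  ",
                        paste(problems, collapse = "\n  ")),
                 "nbarti_config_error")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("cohort", "composition", "rates", "trend",
                                 "regression", "sensitivity")
  stratifiers <- config$stratifiers %||%
    c("age_group", "diagnosis_category", "antibiotic_class")
  window <- config[["window"]] %||% 30
  artifacts <- character()

  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sim <- do.call(sim_config, config$simulate)
      seed <- config$seed %||% sim$seed
      bundle <- generate_bundle(sim, seed = seed)
      gt <- ground_truth(sim)
      gt_path <- file.path(out_dir, "groundtruth.json")
      jsonlite::write_json(
        list(true_or = gt$true_or, monthly_rate = gt$monthly_rate,
             mean_rate = gt$mean_rate,
             expected_cohort_size = gt$expected_cohort_size),
        gt_path, auto_unbox = TRUE, digits = NA)
      artifacts["groundtruth"] <- gt_path
    } else {
      seed <- config$seed %||% NA
      bundle <- read_claims(config$input, config$parsing %||% list())
    }

    ap <- config$appropriateness %||% "builtin"
    mode <- if (isTRUE(config$strict_appropriateness)) "strict" else "lenient"
    table <- if (identical(ap, "builtin")) {
      builtin_appropriateness(mode)
    } else {
      load_appropriateness_table(ap, mode = mode)
    }

    stage <- "cohort"
    cohort <- build_cohort(bundle, table, window = window,
                           config = config)
    paths <- write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    artifacts["cohort"] <- paths[["cohort"]]
    artifacts["attrition"] <- paths[["attrition"]]

    if ("composition" %in% stages && nrow(cohort)) {
      stage <- "composition"
      comp <- composition_table(cohort)
      fwrite(comp, file.path(out_dir, "composition.csv"))
      artifacts["composition"] <- file.path(out_dir, "composition.csv")
    }

    rates_all <- NULL
    if ("rates" %in% stages && nrow(cohort)) {
      stage <- "rates"
      rates_all <- rbindlist(c(
        list(monthly_rate(cohort)),
        lapply(stratifiers, function(s) monthly_rate(cohort, s))))
      fwrite(rates_all, file.path(out_dir, "rates.csv"))
      artifacts["rates"] <- file.path(out_dir, "rates.csv")
    }

    if ("trend" %in% stages && !is.null(rates_all)) {
      stage <- "trend"
      overall <- rates_all[stratum == "overall"]
      trends <- list(overall = unclass(fit_trend(overall)))
      if ("antibiotic_class" %in% stratifiers) {
        for (cl in ABX_CLASS_LEVELS) {
          s <- rates_all[stratum == cl]
          if (sum(s$defined) >= 3 && var(s[defined == TRUE, rate]) > 0) {
            trends[[cl]] <- unclass(fit_trend(s))
          }
        }
      }
      trends$diagnosis_rate_regression <-
        unclass(rate_vs_diagnosisrate_regression(cohort))
      jsonlite::write_json(trends, file.path(out_dir, "trend.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts["trend"] <- file.path(out_dir, "trend.json")
    }

    if ("regression" %in% stages && nrow(cohort)) {
      stage <- "regression"
      spec <- model_spec()
      ## restrict to factors with >= 2 observed levels
      keep <- vapply(names(spec$factors), function(nm) {
        length(unique(as.character(cohort[[nm]]))) >= 2
      }, logical(1))
      spec$factors <- spec$factors[keep]
      if ("fiscal_year" %in% names(spec$factors)) {
        spec$factors["fiscal_year"] <-
          as.character(min(cohort$fiscal_year))
      }
      tab <- or_table(cohort, spec)
      fwrite(tab, file.path(out_dir, "or_table.csv"))
      artifacts["or_table"] <- file.path(out_dir, "or_table.csv")
      if ("stratified" %in% stages || isTRUE(config$stratified_aor)) {
        sa <- stratified_yearly_aor(cohort)
        fwrite(sa, file.path(out_dir, "stratified_aor.csv"))
        artifacts["stratified_aor"] <- file.path(out_dir,
                                                 "stratified_aor.csv")
      }
    }

    if ("sensitivity" %in% stages && !is.null(config$windows)) {
      stage <- "sensitivity"
      sens <- window_sensitivity(bundle, table,
                                 windows = config$windows,
                                 config = config)
      fwrite(sens, file.path(out_dir, "sensitivity.csv"))
      artifacts["sensitivity"] <- file.path(out_dir, "sensitivity.csv")
    }

    list(cohort = cohort, seed = seed)
  }, error = function(e) {
    nbarti_error(sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e)),
                 "nbarti_pipeline_error")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("nbarti")),
    seed = res$seed,
    window = window,
    stages = stages,
    n_cohort_rows = nrow(res$cohort),
    attrition = attrition(res$cohort),
    checksums = as.list(tools::md5sum(unname(artifacts))))
  names(manifest$checksums) <- basename(unname(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts["manifest"] <- file.path(out_dir, "manifest.json")
  invisible(artifacts)
}
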