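#' Diagnosis-level antibiotic appropriateness table
#'
#' A lookup from diagnosis code (3-character ICD-10 class or a finer
#' national-code suffix) to a binary verdict: does the diagnosis require
#' antibiotic treatment? The package consumes such a table as data; the
#' expert adjudication that produces one is out of scope. A small synthetic
#' stand-in covering the ICD-10 J00--J22 classes ships at
#' `system.file("extdata", "appropriateness_synthetic.csv", package = "nbarti")`.
#'
#' @param codes character vector of diagnosis codes
#' @param requires_antibiotics logical vector of verdicts
#' @param mode `"strict"` (unknown-code lookups error) or `"lenient"`
#'   (unknown codes default to `FALSE` with a warning)
#' @param provenance free-text source note
#' @return object of class `appropriateness_table`
#' @export
appropriateness_table <- function(codes, requires_antibiotics,
                                  mode = c("strict", "lenient"),
                                  provenance = "user-supplied") {
  mode <- match.arg(mode)
  if (any(!nzchar(codes)) || any(!grepl("^[A-Z][0-9]", codes))) {
    nbarti_error("syntactically invalid diagnosis code in table",
                 "nbarti_parse_error")
  }
  dt <- data.table(code = codes, requires = as.logical(requires_antibiotics))
  dt <- unique(dt)
  conflicts <- dt[, .N, by = code][N > 1, code]
  if (length(conflicts)) {
    nbarti_error(
      sprintf("conflicting verdicts for code(s): %s",
              paste(conflicts, collapse = ", ")),
      "nbarti_conflict_error")
  }
  setkey(dt, code)
  structure(list(entries = dt, mode = mode, provenance = provenance),
            class = "appropriateness_table")
}

#' @export
print.appropriateness_table <- function(x, ...) {
  cat(sprintf("appropriateness_table: %d codes (%d requiring), mode=%s\n",
              nrow(x$entries), sum(x$entries$requires), x$mode))
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Load an appropriateness table from a two-column delimited file
#'
#' Columns `code` and `requires_antibiotics` (`true`/`false`, `1`/`0`).
#' Identical duplicate rows are collapsed with a message; the same code with
#' conflicting verdicts is an error.
#'
#' @param path file path
#' @param mode see [appropriateness_table()]
#' @param delimiter field separator
#' @return an `appropriateness_table`
#' @export
load_appropriateness_table <- function(path, mode = c("strict", "lenient"),
                                       delimiter = ",") {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    nbarti_error(sprintf("file not found: %s", path), "nbarti_io_error")
  }
  dt <- fread(path, sep = delimiter, colClasses = "character")
  need <- c("code", "requires_antibiotics")
  missing <- setdiff(need, names(dt))
  if (length(missing)) {
    nbarti_error(sprintf("appropriateness table missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 "nbarti_schema_error")
  }
  verdict <- parse_logical_col(dt$requires_antibiotics,
                               "requires_antibiotics verdict")
  n_before <- nrow(dt)
  keep <- !duplicated(paste(dt$code, verdict))
  if (sum(!keep)) {
    message(sprintf("collapsed %d identical duplicate row(s)", sum(!keep)))
  }
  appropriateness_table(dt$code[keep], verdict[keep], mode = mode,
                        provenance = path)
}

#' Look up whether diagnoses require antibiotic treatment
#'
#' Exact-code match wins; otherwise the 3-character ICD-10 class prefix is
#' tried (national codes are finer than ICD-10, so verdicts may exist at
#' either granularity). Codes unknown at both levels follow the table's mode:
#' an error in strict mode, `FALSE` with a warning in lenient mode.
#'
#' @param table an `appropriateness_table`
#' @param codes character vector of diagnosis codes
#' @return logical vector
#' @export
requires_antibiotics <- function(table, codes) {
  stopifnot(inherits(table, "appropriateness_table"))
  e <- table$entries
  out <- e[match(codes, e$code), requires]
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- e[match(substr(codes[miss], 1, 3), e$code), requires]
  }
  unknown <- is.na(out)
  if (any(unknown)) {
    if (table$mode == "strict") {
      nbarti_error(
        sprintf("unknown diagnosis code(s) in strict mode: %s",
                paste(head(unique(codes[unknown]), 10), collapse = ", ")),
        "nbarti_unknown_code_error")
    }
    warning(sprintf("defaulting %d unknown code(s) to requires_antibiotics=FALSE",
                    sum(unknown)), call. = FALSE)
    out[unknown] <- FALSE
  }
  out
}

#' Classify an ATC J01 antibiotic code
#'
#' Third-generation cephalosporins (J01DD), macrolides (J01FA) and
#' fluoroquinolones (J01MA) are the broad-spectrum classes; penicillins
#' (J01C) and all remaining J01 codes are not broad-spectrum. Codes outside
#' J01 (non-systemic-antibacterials) are out of scope and raise an error —
#' filter prescriptions to J01 first.
#'
#' @param atc_code character vector of ATC level-4/5 codes (e.g. `"J01DD04"`)
#' @return `data.table` with columns `atc_code`, `abx_class` (factor) and
#'   `broad_spectrum` (logical)
#' @export
#' @examples
#' classify_antibiotic(c("J01DD04", "J01CA04"))
classify_antibiotic <- function(atc_code) {
  if (any(!startsWith(atc_code, "J01"))) {
    nbarti_error(
      sprintf("non-J01 ATC code(s) out of scope: %s",
              paste(head(unique(atc_code[!startsWith(atc_code, "J01")]), 5),
                    collapse = ", ")),
      "nbarti_domain_error")
  }
  cls <- rep("other_J01", length(atc_code))
  cls[startsWith(atc_code, "J01DD")] <- "third_gen_cephalosporin"
  cls[startsWith(atc_code, "J01FA")] <- "macrolide"
  cls[startsWith(atc_code, "J01MA")] <- "fluoroquinolone"
  cls[startsWith(atc_code, "J01C")] <- "penicillin"
  data.table(atc_code = atc_code,
             abx_class = factor(cls, levels = ABX_CLASS_LEVELS),
             broad_spectrum = cls %in% BROAD_SPECTRUM_CLASSES)
}

#' Built-in synthetic appropriateness table
#'
#' Convenience loader for the shipped stand-in table (ARTI classes J00--J06,
#' J20--J22 marked not requiring antibiotics; bacterial pneumonia classes and
#' a few common bacterial diagnoses marked requiring). It is a synthetic
#' stand-in for an expert-adjudicated list, suitable for tests and
#' simulations only.
#'
#' @param mode see [appropriateness_table()]
#' @return an `appropriateness_table`
#' @export
builtin_appropriateness <- function(mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  path <- system.file("extdata", "appropriateness_synthetic.csv",
                      package = "nbarti")
  tab <- load_appropriateness_table(path, mode = mode)
  tab$provenance <- "synthetic stand-in shipped with nbarti (not expert-adjudicated)"
  tab
}
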