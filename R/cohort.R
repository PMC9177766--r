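#' Construct a cohort
#'
#' A cohort bundles one row per surgical case with the variable specs that
#' type its columns. Discrete variables are stored as character vectors of
#' category labels (binary as "0"/"1" character is *not* used: binary columns
#' are numeric 0/1), continuous variables as numeric. Missing values use
#' `NA`, serialized as the empty CSV cell.
#'
#' @param data A data.frame with columns `case_id`, `hospital_id` and one
#'   column per variable spec.
#' @param specs Named list of [variable_spec()] objects.
#' @param provenance Free-text provenance note.
#' @return An object of class `"cohort"` with elements `data`, `specs`,
#'   `provenance`.
#' @export
cohort <- function(data, specs = default_variable_specs(), provenance = "") {
  stopifnot(is.data.frame(data))
  for (col in c("case_id", "hospital_id")) {
    if (!col %in% names(data)) stop("cohort data lacks required column '", col, "'")
  }
  if (anyDuplicated(data$case_id))
    stop("integrity error: duplicate case_id values in cohort")
  if (anyNA(data$hospital_id))
    stop("integrity error: missing hospital_id values in cohort")
  structure(list(data = data, specs = specs, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$data), " cases, ",
      length(unique(x$data$hospital_id)), " hospitals, ",
      length(x$specs), " variables\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$data)

#' Subset a cohort by row
#' @param x A cohort.
#' @param i Row index (logical or integer).
#' @param ... Unused.
#' @return A cohort containing the selected cases.
#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$data[i, , drop = FALSE], x$specs, x$provenance)
}

coerce_column <- function(raw, spec) {
  n_bad <- 0L
  if (spec$kind == "continuous") {
    suppressWarnings(val <- as.numeric(raw))
    n_bad <- sum(!is.na(raw) & nzchar(trimws(raw)) & is.na(val))
  } else if (spec$kind == "binary") {
    suppressWarnings(val <- as.numeric(raw))
    ok <- is.na(val) | val %in% c(0, 1)
    n_bad <- sum((!is.na(raw) & nzchar(trimws(raw)) & is.na(val)) | !ok)
    val[!ok] <- NA_real_
  } else {
    val <- as.character(raw)
    val[!nzchar(trimws(val %||% ""))] <- NA_character_
    bad <- !is.na(val) & !val %in% spec$categories
    n_bad <- sum(bad)
    val[bad] <- NA_character_
  }
  list(value = val, n_bad = n_bad)
}

#' Read a cohort from CSV
#'
#' Reads an RFC-4180 CSV (header row, UTF-8, empty cell = missing) and types
#' each column against its variable spec. Cells that cannot be parsed under
#' the spec (non-numeric text in a continuous column, unknown category
#' labels) become missing and are counted in the parse report attached as
#' attribute `"parse_report"`.
#'
#' @param path CSV file path.
#' @param specs Named list of [variable_spec()] objects.
#' @return A [cohort()]; `attr(, "parse_report")` is a named integer vector
#'   of unparseable-cell counts per affected column.
#' @export
read_cohort <- function(path, specs = default_variable_specs()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "")
  for (col in c("case_id", "hospital_id", names(specs))) {
    if (!col %in% names(raw))
      stop("schema error: required column '", col, "' absent from ", path)
  }
  out <- data.frame(case_id = raw$case_id, hospital_id = raw$hospital_id,
                    stringsAsFactors = FALSE)
  report <- integer(0)
  for (nm in names(specs)) {
    cc <- coerce_column(raw[[nm]], specs[[nm]])
    out[[nm]] <- cc$value
    if (cc$n_bad > 0L) {
      report[nm] <- cc$n_bad
      warning(cc$n_bad, " unparseable cell(s) in column '", nm,
              "' set to missing", call. = FALSE)
    }
  }
  co <- cohort(out, specs, provenance = paste0("read from ", basename(path)))
  attr(co, "parse_report") <- report
  co
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, so
#' `read_cohort(write_cohort(x))` round-trips typed values and missingness.
#'
#' @param x A cohort.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the study eligibility rules
#'
#' Excludes cases below 18 or above 109 years of age; both boundary ages are
#' retained. Idempotent.
#'
#' @param x A cohort with non-missing `age` for every case.
#' @return A list with `cohort` (retained cases) and `report`, a named
#'   integer vector with counts `retained`, `under_18`, `over_109`.
#' @export
apply_exclusions <- function(x) {
  age <- x$data$age
  if (anyNA(age)) stop("apply_exclusions requires non-missing age for all cases")
  under <- age < 18
  over <- age > 109
  keep <- !under & !over
  list(cohort = x[keep],
       report = c(retained = sum(keep), under_18 = sum(under),
                  over_109 = sum(over)))
}

#' Resolve the in-hospital mortality outcome
#'
#' Maps a raw discharge status to the binary modelling outcome: death in
#' hospital before day 60 is the event; patients discharged alive, and
#' patients still in hospital on day 60, are both coded as survivors.
#'
#' @param raw_status Character vector with values in
#'   `c("died", "discharged_alive", "in_hospital_day60")`.
#' @return Numeric 0/1 vector.
#' @export
resolve_outcome <- function(raw_status) {
  allowed <- c("died", "discharged_alive", "in_hospital_day60")
  bad <- setdiff(unique(raw_status), allowed)
  if (length(bad) > 0L)
    stop("unknown outcome status token(s): ", paste(bad, collapse = ", "))
  as.numeric(raw_status == "died")
}
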