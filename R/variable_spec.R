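#' Define a covariate specification
#'
#' A variable spec records everything the pipeline needs to know about one
#' covariate: its measurement kind, unit, legal categories (for discrete
#' variables), the base category excluded from dummy encoding, whether the
#' lower Winsorization cut is active, and a physiologically plausible range
#' used to redact implausible values before modelling.
#'
#' @param name Variable name (must match the cohort column name).
#' @param kind One of `"continuous"`, `"binary"`, `"ordinal"`, `"nominal"`.
#' @param unit Free-text unit, e.g. `"mmol/L"`. Empty for unitless variables.
#' @param categories Ordered character vector of allowed categories
#'   (ordinal/nominal only; binary variables implicitly use `c("0", "1")`).
#' @param base Category excluded from dummy encoding. Defaults to the first
#'   allowed category.
#' @param winsor_lower Logical; is the lower Winsorization cut active?
#'   Age uses `FALSE` (upper cut only).
#' @param plausible_range Length-2 numeric `c(min, max)`; continuous values
#'   outside this range are redacted to missing. `NULL` disables redaction.
#' @return An object of class `"variable_spec"`.
#' @export
variable_spec <- function(name, kind, unit = "", categories = NULL,
                          base = NULL, winsor_lower = TRUE,
                          plausible_range = NULL) {
  kind <- match.arg(kind, c("continuous", "binary", "ordinal", "nominal"))
  if (kind %in% c("ordinal", "nominal")) {
    if (is.null(categories) || length(categories) < 2L)
      stop("'", name, "': ordinal/nominal specs need >= 2 categories")
    categories <- as.character(categories)
    if (is.null(base)) base <- categories[1L]
    if (!base %in% categories)
      stop("'", name, "': base category '", base, "' not in allowed categories")
  }
  if (kind == "binary") {
    categories <- c("0", "1")
    base <- "0"
  }
  if (!is.null(plausible_range)) {
    stopifnot(length(plausible_range) == 2L,
              plausible_range[1L] < plausible_range[2L])
  }
  structure(
    list(name = name, kind = kind, unit = unit, categories = categories,
         base = base, winsor_lower = isTRUE(winsor_lower),
         plausible_range = plausible_range),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat("<variable_spec> ", x$name, " [", x$kind, "]",
      if (nzchar(x$unit)) paste0(" (", x$unit, ")"), "\n", sep = "")
  if (!is.null(x$categories))
    cat("  categories:", paste(x$categories, collapse = ", "),
        "| base:", x$base, "\n")
  if (!is.null(x$plausible_range))
    cat("  plausible range: [", x$plausible_range[1L], ", ",
        x$plausible_range[2L], "]\n", sep = "")
  invisible(x)
}

#' The 13 most common surgical indications retained before consolidation
#'
#' Raw indications outside this list are mapped to `"other"` by
#' [consolidate_indication()].
#'
#' @return Character vector of length 13.
#' @export
top13_indications <- function() {
  c("small_bowel_obstruction", "large_bowel_obstruction", "perforation",
    "peritonitis", "ischaemia", "haemorrhage", "abdominal_abscess",
    "anastomotic_leak", "colitis", "incarcerated_hernia", "sepsis",
    "volvulus", "intestinal_fistula")
}

#' Default covariate specifications for the emergency laparotomy cohort
#'
#' One spec per modelled variable plus identifiers and the outcome. Units and
#' category encodings follow the registry conventions: creatinine and blood
#' urea nitrogen in mg/dL, lactate in mmol/L, albumin in g/L; cardiovascular
#' status 0 = no cardiac failure through 3 = raised JVP/cardiomegaly;
#' respiratory status 0 = no dyspnoea through 3 = severe dyspnoea.
#' Plausible ranges are physiological limits; values outside them are
#' treated as data-entry errors and redacted to missing.
#'
#' @return Named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function() {
  sp <- list(
    variable_spec("age", "continuous", "years", winsor_lower = FALSE,
                  plausible_range = c(0, 120)),
    variable_spec("asa", "ordinal", categories = as.character(1:5)),
    variable_spec("cardio_status", "ordinal", categories = as.character(0:3)),
    variable_spec("resp_status", "ordinal", categories = as.character(0:3)),
    variable_spec("heart_rate", "continuous", "beats/min",
                  plausible_range = c(20, 300)),
    variable_spec("arrhythmia", "binary"),
    variable_spec("systolic_bp", "continuous", "mmHg",
                  plausible_range = c(40, 300)),
    variable_spec("sodium", "continuous", "mmol/L",
                  plausible_range = c(100, 180)),
    variable_spec("potassium", "continuous", "mmol/L",
                  plausible_range = c(1.5, 10)),
    variable_spec("wcc", "continuous", "1e9/L",
                  plausible_range = c(0.1, 100)),
    variable_spec("creatinine", "continuous", "mg/dL",
                  plausible_range = c(0.1, 25)),
    variable_spec("bun", "continuous", "mg/dL",
                  plausible_range = c(1, 200)),
    variable_spec("lactate", "continuous", "mmol/L",
                  plausible_range = c(0.1, 30)),
    variable_spec("albumin", "continuous", "g/L",
                  plausible_range = c(5, 60)),
    variable_spec("gcs", "continuous", plausible_range = c(3, 15)),
    variable_spec("ct_performed", "binary"),
    variable_spec("soiling", "nominal",
                  categories = c("none", "serous", "purulent", "feculent")),
    variable_spec("malignancy", "nominal",
                  categories = c("none", "primary", "nodal", "distant")),
    variable_spec("indication", "nominal",
                  categories = c(top13_indications(), "other"),
                  base = "small_bowel_obstruction"),
    variable_spec("lactate_missing", "binary"),
    variable_spec("albumin_missing", "binary"),
    variable_spec("died", "binary")
  )
  names(sp) <- vapply(sp, `[[`, character(1L), "name")
  sp
}

#' Names of routinely measured covariates
#'
#' All modelled covariates except lactate and albumin (the two labs that are
#' frequently unmeasured at prediction time) and their missingness
#' indicators. These must be supplied for prospective prediction; at model
#' fitting time their missing values are handled by chained-equation and
#' categorical imputation.
#'
#' @param specs Variable specs as from [default_variable_specs()].
#' @return Character vector of variable names.
#' @export
routine_covariates <- function(specs = default_variable_specs()) {
  setdiff(names(specs),
          c("lactate", "albumin", "lactate_missing", "albumin_missing", "died"))
}

variable_kind <- function(specs, name) specs[[name]]$kind

#' Serialize variable specs to JSON
#' @param specs Named list of [variable_spec()] objects.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_variable_specs <- function(specs, path) {
  jsonlite::write_json(lapply(unname(specs), unclass), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read variable specs from JSON
#' @param path File written by [write_variable_specs()].
#' @return Named list of [variable_spec()] objects.
#' @export
read_variable_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sp <- lapply(raw, function(r) {
    variable_spec(r$name, r$kind, unit = r$unit %||% "",
                  categories = if (r$kind %in% c("ordinal", "nominal")) unlist(r$categories),
                  base = if (r$kind %in% c("ordinal", "nominal")) r$base,
                  winsor_lower = isTRUE(r$winsor_lower),
                  plausible_range = if (!is.null(r$plausible_range)) unlist(r$plausible_range))
  })
  names(sp) <- vapply(sp, `[[`, character(1L), "name")
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
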