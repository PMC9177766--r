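#' Redact implausible values
#'
#' Continuous values outside a variable's plausible physiological range are
#' treated as data-entry errors and set to missing. Ranges live on the
#' [variable_spec()]s.
#'
#' @param x A cohort.
#' @return A cohort with out-of-range continuous values set to missing.
#' @export
redact_implausible <- function(x) {
  d <- x$data
  for (nm in names(x$specs)) {
    sp <- x$specs[[nm]]
    if (sp$kind != "continuous" || is.null(sp$plausible_range)) next
    v <- d[[nm]]
    bad <- !is.na(v) & (v < sp$plausible_range[1L] | v > sp$plausible_range[2L])
    if (any(bad)) d[[nm]][bad] <- NA_real_
  }
  cohort(d, x$specs, x$provenance)
}

#' Fit Winsorization thresholds on training data
#'
#' Thresholds are the 0.1 and 99.9 empirical percentiles of the non-missing
#' training values of each continuous variable (linear interpolation between
#' order statistics). Age uses the upper cut only. Thresholds are refit per
#' cross-validation round and never touched by validation data.
#'
#' @param x Training cohort.
#' @param specs Variable specs (defaults to the cohort's).
#' @param probs Length-2 percentile pair, defaults `c(0.001, 0.999)`.
#' @return Object of class `"winsor_thresholds"`: per-variable list of
#'   `lower`, `upper`, and active-side flags.
#' @export
fit_winsor_thresholds <- function(x, specs = x$specs,
                                  probs = c(0.001, 0.999)) {
  out <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (sp$kind != "continuous") next
    v <- x$data[[nm]]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop("cannot fit Winsor thresholds for '", nm, "': no non-missing values")
    if (length(v) < 1000L)
      warning("fewer than 1000 non-missing values for '", nm,
              "'; Winsor thresholds may be unstable", call. = FALSE)
    q <- stats::quantile(v, probs, names = FALSE, type = 7)
    out[[nm]] <- list(lower = q[1L], upper = q[2L],
                      lower_active = sp$winsor_lower, upper_active = TRUE)
  }
  structure(out, class = "winsor_thresholds", probs = probs)
}

#' Clamp continuous values to fitted Winsor thresholds
#'
#' Non-missing values are clamped into the training thresholds; missing
#' markers are untouched; thresholds are never refit here, so validation
#' values beyond the training range are clamped to the training cut.
#' Idempotent.
#'
#' @param x A cohort.
#' @param thresholds A [fit_winsor_thresholds()] object.
#' @return The clamped cohort.
#' @export
apply_winsor <- function(x, thresholds) {
  d <- x$data
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    v <- d[[nm]]
    obs <- !is.na(v)
    if (th$lower_active) v[obs] <- pmax(v[obs], th$lower)
    if (th$upper_active) v[obs] <- pmin(v[obs], th$upper)
    d[[nm]] <- v
  }
  cohort(d, x$specs, x$provenance)
}

#' Clamp a single variable's values to its Winsor thresholds
#' @param values Numeric vector.
#' @param thresholds A `"winsor_thresholds"` object.
#' @param name Variable name within `thresholds`.
#' @return Clamped numeric vector (missing values untouched).
#' @export
winsor_clamp <- function(values, thresholds, name) {
  th <- thresholds[[name]]
  if (is.null(th)) return(values)
  obs <- !is.na(values)
  if (th$lower_active) values[obs] <- pmax(values[obs], th$lower)
  if (th$upper_active) values[obs] <- pmin(values[obs], th$upper)
  values
}

#' Serialize Winsor thresholds to JSON
#' @param thresholds A `"winsor_thresholds"` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_winsor_thresholds <- function(thresholds, path) {
  jsonlite::write_json(lapply(thresholds, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read Winsor thresholds from JSON
#' @param path File written by [write_winsor_thresholds()].
#' @return A `"winsor_thresholds"` object.
#' @export
read_winsor_thresholds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  structure(lapply(raw, function(th) {
    list(lower = th$lower, upper = th$upper,
         lower_active = isTRUE(th$lower_active),
         upper_active = isTRUE(th$upper_active))
  }), class = "winsor_thresholds")
}

#' Rationalise an ECG category to a binary arrhythmia flag
#'
#' Any arrhythmia category maps to 1; sinus rhythm / no abnormality to 0;
#' missing propagates.
#'
#' @param raw_ecg Character vector of raw ECG categories.
#' @param sinus_categories Categories coding absence of arrhythmia.
#' @param arrhythmia_categories Categories coding any arrhythmia.
#' @return Numeric 0/1 vector with `NA` propagated.
#' @export
binarize_ecg <- function(raw_ecg,
                         sinus_categories = c("sinus rhythm", "no abnormality"),
                         arrhythmia_categories = c("AF rate < 90", "AF rate > 90",
                                                   "other arrhythmia")) {
  out <- rep(NA_real_, length(raw_ecg))
  known <- is.na(raw_ecg) | raw_ecg %in% c(sinus_categories, arrhythmia_categories)
  if (!all(known))
    stop("unknown ECG category: ",
         paste(unique(raw_ecg[!known]), collapse = ", "))
  out[raw_ecg %in% sinus_categories] <- 0
  out[raw_ecg %in% arrhythmia_categories] <- 1
  out
}

#' Consolidate raw surgical indications to 13 categories plus "other"
#'
#' A single raw indication in the retained top-13 list maps to itself; a
#' single indication outside it maps to `"other"`; an empty selection, or a
#' selection of multiple simultaneous indications, maps to missing (to be
#' imputed downstream).
#'
#' @param raw_indications List of character vectors (one element per case;
#'   each a set of selected raw indications) or a character vector for the
#'   single-selection case.
#' @param top13 The 13 retained indication categories.
#' @return Character vector: a category in `c(top13, "other")` or `NA`.
#' @export
consolidate_indication <- function(raw_indications, top13 = top13_indications()) {
  if (length(top13) != 13L) stop("top13 must have exactly 13 entries")
  if (!is.list(raw_indications)) raw_indications <- as.list(raw_indications)
  vapply(raw_indications, function(s) {
    s <- s[!is.na(s)]
    if (length(s) != 1L) return(NA_character_)
    if (s %in% top13) s else "other"
  }, character(1L))
}

#' Derive lactate and albumin missingness indicators
#'
#' Sets `lactate_missing` / `albumin_missing` to 1 exactly where the lab is
#' absent, before any imputation. The indicators are modelled covariates in
#' their own right (testing the hypothesis that measurement itself carries
#' prognostic signal) and are never missing.
#'
#' @param x A cohort.
#' @return The cohort with refreshed indicator columns.
#' @export
add_missingness_indicators <- function(x) {
  d <- x$data
  d$lactate_missing <- as.numeric(is.na(d$lactate))
  d$albumin_missing <- as.numeric(is.na(d$albumin))
  cohort(d, x$specs, x$provenance)
}
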