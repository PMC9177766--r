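#' Default covariate specification for the lab imputation sub-models
#'
#' Gaussian GAM design for imputing lactate or albumin from the routinely
#' measured covariates: penalized splines of the continuous variables and
#' L2-penalized dummies of the discrete ones. Neither lab is a covariate of
#' the other (both may be unmeasured at prediction time). The outcome is
#' appended only when the config asks for it.
#'
#' @param include_outcome Append `died` as a (binary) covariate.
#' @return A `"gam_spec"`.
#' @export
lab_imputer_spec <- function(include_outcome = FALSE) {
  cont <- c("age", "heart_rate", "systolic_bp", "sodium", "potassium",
            "wcc", "creatinine", "bun", "gcs")
  cats <- c("asa", "cardio_status", "resp_status", "arrhythmia",
            "ct_performed", "soiling", "malignancy")
  terms <- c(lapply(cont, spline_term),
             lapply(cats, categorical_term))
  if (include_outcome) terms <- c(terms, list(categorical_term("died")))
  gam_spec(terms)
}

#' Fit a lactate or albumin imputation sub-model
#'
#' Fits a Gaussian GAM for the target lab on the cases where it is
#' observed, within one completed dataset from the first imputation stage.
#' Lactate is modelled on the log scale by default. The fitted coefficient
#' covariance supports posterior draws at imputation and prediction time.
#'
#' @param completed A completed dataset (routine covariates complete).
#' @param target `"lactate"` or `"albumin"`.
#' @param config An [imputation_config()].
#' @param spec Covariate spec; defaults to [lab_imputer_spec()] honouring
#'   `config$include_outcome_in_lab`.
#' @param min_observed Warn-free minimum number of observed targets.
#' @return A `"lab_imputer"`: target name, fitted Gaussian GAM
#'   (coefficients, covariance, residual scale), covariate list, log-scale
#'   and outcome flags.
#' @export
fit_lab_imputer <- function(completed, target = c("lactate", "albumin"),
                            config = imputation_config(), spec = NULL,
                            min_observed = 500L) {
  target <- match.arg(target)
  if (is.null(spec)) spec <- lab_imputer_spec(config$include_outcome_in_lab)
  d <- completed$data
  obs <- !is.na(d[[target]])
  if (!any(obs)) stop("fit error: '", target, "' never observed")
  if (sum(obs) < min_observed)
    warning("only ", sum(obs), " observed values of '", target,
            "' available to the imputation sub-model", call. = FALSE)
  log_scale <- target == "lactate" && config$lactate_log_scale
  dd <- d[obs, , drop = FALSE]
  if (log_scale) dd[[target]] <- log(dd[[target]])
  fit <- fit_gaussian_gam(dd, spec, target, specs = completed$specs)
  structure(list(target = target, fit = fit,
                 covariates = spec_variables(spec),
                 log_scale = log_scale,
                 include_outcome = config$include_outcome_in_lab,
                 mice_index = completed$mice_index %||% NA_integer_),
            class = "lab_imputer")
}

#' @export
print.lab_imputer <- function(x, ...) {
  cat("<lab_imputer> target: ", x$target,
      if (x$log_scale) " (log scale)", ", ", length(x$fit$coef),
      " coefficients, residual scale ", format(round(x$fit$sigma, 3)),
      "\n", sep = "")
  invisible(x)
}

# one posterior-predictive draw of the target for the given rows
lab_imputer_draw_values <- function(model, data, residual_noise = TRUE) {
  X <- build_design(data, model$fit$spec, model$fit$meta)$X
  beta <- drop(sample_coefficients(model$fit, 1L))
  mu <- drop(X %*% beta)
  if (residual_noise) mu <- mu + stats::rnorm(length(mu), 0, model$fit$sigma)
  if (model$log_scale) mu <- exp(mu)
  mu
}

#' Draw multiple lab imputations from a fitted sub-model
#'
#' For each of `k` draws: one coefficient vector is sampled from the
#' approximate posterior, then each missing target value is drawn from the
#' resulting predictive distribution (with residual noise unless disabled
#' in the config). Observed values are untouched; drawn values are clamped
#' to the variable's Winsor thresholds.
#'
#' @param model A `"lab_imputer"`.
#' @param completed A completed dataset whose target may be missing.
#' @param k Number of imputed copies.
#' @param seed Integer seed.
#' @param thresholds Optional `"winsor_thresholds"` used to clamp draws.
#' @param config An [imputation_config()] (controls residual noise).
#' @return List of `k` completed datasets with `lab_index` set.
#' @export
draw_lab_imputations <- function(model, completed, k, seed = 1L,
                                 thresholds = NULL,
                                 config = imputation_config()) {
  d <- completed$data
  mis <- is.na(d[[model$target]])
  set.seed(seed)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    dj <- d
    if (any(mis)) {
      val <- lab_imputer_draw_values(model, d[mis, , drop = FALSE],
                                     residual_noise = config$lab_residual_noise)
      if (!is.null(thresholds))
        val <- winsor_clamp(val, thresholds, model$target)
      dj[[model$target]][mis] <- val
    }
    cj <- cohort(dj, completed$specs, completed$provenance)
    cj$mice_index <- completed$mice_index
    cj$lab_index <- j
    out[[j]] <- cj
  }
  out
}

#' Serialize a lab imputer to JSON
#'
#' Writes coefficients, covariance, residual scale, design metadata (spline
#' ranges, category levels) and flags, so prospective prediction needs no
#' training data.
#'
#' @param model A `"lab_imputer"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lab_imputer <- function(model, path) {
  jsonlite::write_json(lab_imputer_to_list(model), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

lab_imputer_to_list <- function(model) {
  list(target = model$target,
       coef = as.list(model$fit$coef),
       cov = model$fit$cov,
       sigma = model$fit$sigma,
       log_scale = model$log_scale,
       include_outcome = model$include_outcome,
       mice_index = model$mice_index,
       spec = spec_to_list(model$fit$spec),
       meta = meta_to_list(model$fit$meta))
}

lab_imputer_from_list <- function(l) {
  coef <- unlist(l$coef)
  cov <- matrix(unlist(l$cov), length(coef), length(coef))
  dimnames(cov) <- list(names(coef), names(coef))
  fit <- structure(list(coef = coef, cov = cov, sigma = l$sigma,
                        spec = spec_from_list(l$spec),
                        meta = meta_from_list(l$meta), converged = TRUE),
                   class = c("fitted_gaussian_gam", "fitted_gam"))
  structure(list(target = l$target, fit = fit,
                 covariates = spec_variables(fit$spec),
                 log_scale = isTRUE(l$log_scale),
                 include_outcome = isTRUE(l$include_outcome),
                 mice_index = l$mice_index %||% NA_integer_),
            class = "lab_imputer")
}

#' Read a lab imputer from JSON
#' @param path File written by [write_lab_imputer()].
#' @return A `"lab_imputer"`.
#' @export
read_lab_imputer <- function(path) {
  lab_imputer_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                            simplifyDataFrame = FALSE))
}

spec_to_list <- function(spec) {
  lapply(spec$terms, function(t) {
    list(kind = t$kind, vars = as.list(t$vars),
         n_basis = t$n_basis %||% NULL, degree = t$degree %||% NULL,
         penalty = as.list(t$penalty))
  })
}

spec_from_list <- function(l) {
  gam_spec(lapply(l, function(t) {
    vars <- unlist(t$vars)
    pen <- unlist(t$penalty)
    switch(t$kind,
           spline = spline_term(vars, t$n_basis, t$degree, pen),
           categorical = categorical_term(vars, pen),
           tensor = tensor_term(vars[1L], vars[2L], t$n_basis %||% 10L,
                                t$degree %||% 2L, pen))
  }))
}

meta_to_list <- function(meta) {
  lapply(meta, function(m) {
    if (m$kind == "continuous")
      list(kind = "continuous", range = as.list(m$range), median = m$median)
    else
      list(kind = "discrete", levels = as.list(m$levels), base = m$base)
  })
}

meta_from_list <- function(l) {
  structure(lapply(l, function(m) {
    if (m$kind == "continuous")
      list(kind = "continuous", range = unlist(m$range), median = m$median)
    else
      list(kind = "discrete", levels = unlist(m$levels), base = m$base)
  }), class = "design_meta")
}
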