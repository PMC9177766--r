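#' Default run configuration
#'
#' Single source of truth for the study defaults: the imputation-count
#' rule with 3 lab draws per completed dataset, 5 coefficient draws per
#' completed case version, 120 hospital-grouped splits with an 80%
#' development fraction, and the sensitivity toggles (outcome excluded
#' from the lab sub-models so they can run prospectively; albumin
#' retained).
#'
#' @return Nested list of configuration values.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    cohort_csv = NULL,
    output_dir = "distrisk_output",
    generator = list(n_cases = 20000L, n_hospitals = 186L,
                     prevalence_target = 0.113,
                     missingness_mechanism = "MAR-severity"),
    imputation = list(m_mice = NULL, k_lab = 3L, n_cycles = 10L,
                      include_outcome_in_mice = TRUE,
                      include_outcome_in_lab = FALSE,
                      lab_residual_noise = TRUE,
                      lactate_log_scale = TRUE),
    model = list(spline_penalty = 1, categorical_penalty = 1,
                 include_missingness_indicators = TRUE),
    validation = list(n_splits = 120L, train_frac = 0.8,
                      n_coef_draws = 5L, include_mace = TRUE),
    prediction = list(n_coef_draws = 5L),
    sensitivity = list(exclude_outcome_from_lab_imputers = TRUE,
                       drop_albumin = FALSE)
  )
}

known_config_keys <- function() names(default_run_config())

#' Read and validate a YAML run configuration
#'
#' Unknown top-level keys fail fast before any computation; known keys
#' are merged over [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), known_config_keys())
  if (length(bad) > 0L)
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      badk <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(badk) > 0L)
        stop("config error: unknown key(s) under '", k, "': ",
             paste(badk, collapse = ", "))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

config_imputation <- function(cfg) {
  imputation_config(m_mice = cfg$imputation$m_mice,
                    k_lab = cfg$imputation$k_lab,
                    n_cycles = cfg$imputation$n_cycles,
                    include_outcome_in_mice = cfg$imputation$include_outcome_in_mice,
                    include_outcome_in_lab =
                      !isTRUE(cfg$sensitivity$exclude_outcome_from_lab_imputers),
                    lab_residual_noise = cfg$imputation$lab_residual_noise,
                    lactate_log_scale = cfg$imputation$lactate_log_scale,
                    seed = cfg$seed)
}

config_spec <- function(cfg) {
  default_gam_spec(
    include_albumin = !isTRUE(cfg$sensitivity$drop_albumin),
    include_missingness_indicators =
      isTRUE(cfg$model$include_missingness_indicators),
    spline_penalty = cfg$model$spline_penalty,
    categorical_penalty = cfg$model$categorical_penalty)
}

config_cohort <- function(cfg) {
  if (!is.null(cfg$cohort_csv)) {
    read_cohort(cfg$cohort_csv)
  } else {
    g <- generator_config(n_cases = cfg$generator$n_cases,
                          n_hospitals = cfg$generator$n_hospitals,
                          prevalence_target = cfg$generator$prevalence_target,
                          missingness_mechanism =
                            cfg$generator$missingness_mechanism,
                          seed = cfg$seed)
    inject_missingness(generate_cohort(g)$cohort, g)
  }
}

#' Fit a production model from a run configuration
#'
#' Reads (or simulates) the cohort, applies the eligibility rules, fits
#' the full model, and — if `output_dir` is set — serializes the
#' self-contained prediction bundle plus a run log recording seeds and
#' imputation counts.
#'
#' @param config A config list from [read_run_config()] (or a YAML path).
#' @return The fitted `"distrisk"` model, invisibly carrying the bundle
#'   path as attribute `"bundle"` when one was written.
#' @export
run_fit <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  co <- config_cohort(config)
  co <- apply_exclusions(co)$cohort
  model <- distrisk(co, spec = config_spec(config),
                    imputation = config_imputation(config))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    bundle <- file.path(config$output_dir, "model_bundle.json")
    write_model_bundle(model, bundle)
    log <- file.path(config$output_dir, "run_log.json")
    jsonlite::write_json(list(seed = config$seed, m_mice = model$m_mice,
                              k_lab = model$k_lab,
                              completed_datasets = model$n_completed_datasets,
                              n_cases = model$n,
                              prevalence = model$prevalence,
                              converged = model$converged),
                         log, auto_unbox = TRUE, digits = NA)
    attr(model, "bundle") <- bundle
  }
  invisible(model)
}

#' Run the cross-validation harness from a run configuration
#'
#' @param config A config list from [read_run_config()] (or a YAML path).
#' @return The `"score_report"`; artifacts are written under
#'   `output_dir/validation` when `output_dir` is set.
#' @export
run_validate <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  co <- config_cohort(config)
  co <- apply_exclusions(co)$cohort
  plan <- make_split_plan(co$data$hospital_id,
                          n_splits = config$validation$n_splits,
                          train_frac = config$validation$train_frac,
                          seed = config$seed)
  report <- run_validation(co, plan, spec = config_spec(config),
                           imputation = config_imputation(config),
                           n_coef_draws = config$validation$n_coef_draws,
                           seed = config$seed,
                           include_mace = config$validation$include_mace)
  if (!is.null(config$output_dir))
    write_score_report(report, file.path(config$output_dir, "validation"))
  report
}

#' Predict the case-study patient before and after lab measurement
#'
#' Predicts the risk distribution for the worked case-study fixture twice:
#' once with lactate and albumin unmeasured (prospectively imputed) and
#' once with the measured, relatively deranged values supplied (no lab
#' draws — the measured values are used directly). Returns both
#' distributions with their summaries and kernel density curves.
#'
#' @param model A fitted `"distrisk"` model.
#' @param n_coef_draws Coefficient draws per completed version.
#' @param seed Integer seed.
#' @return List with `pre` and `post` (each: `distribution`, `summary`,
#'   `density`).
#' @export
run_case_study <- function(model, n_coef_draws = 5L, seed = 1L) {
  fx <- case_study_fixture()
  pre <- predict_distribution(fx$pre, model, n_coef_draws, seed)
  post <- predict_distribution(fx$post, model, n_coef_draws, seed + 1L)
  list(pre = list(distribution = pre, summary = pre$summary,
                  density = density_curve(pre)),
       post = list(distribution = post, summary = post$summary,
                   density = density_curve(post)))
}

#' Serialize a fitted model to a self-contained JSON bundle
#'
#' The bundle holds everything prospective prediction needs without the
#' training data: the model spec (terms, knots ranges), pooled
#' coefficients and covariance, Winsor thresholds, the lab imputation
#' sub-models, and the imputation configuration.
#'
#' @param model A `"distrisk"` model.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_bundle <- function(model, path) {
  bundle <- list(
    format = "distrisk_bundle_v1",
    spec = spec_to_list(model$spec),
    meta = meta_to_list(model$meta),
    coef = as.list(model$pooled$coef),
    cov = model$pooled$cov,
    m = model$pooled$m,
    m_mice = model$m_mice,
    k_lab = model$k_lab,
    n = model$n,
    prevalence = model$prevalence,
    thresholds = lapply(model$thresholds, unclass),
    imputation = unclass(model$imputation),
    lab_imputers = lapply(model$lab_imputers, function(pair)
      lapply(pair, lab_imputer_to_list))
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model bundle written by [write_model_bundle()]
#' @param path Bundle JSON path.
#' @return A `"distrisk"` model usable for prediction (no training data).
#' @export
read_model_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  coef <- unlist(b$coef)
  cov <- matrix(unlist(b$cov), length(coef), length(coef))
  dimnames(cov) <- list(names(coef), names(coef))
  spec <- spec_from_list(b$spec)
  meta <- meta_from_list(b$meta)
  pooled <- structure(list(coef = coef, cov = cov, m = b$m, spec = spec,
                           meta = meta, within_cov = NULL,
                           between_cov = NULL, converged = TRUE),
                      class = "pooled_gam")
  thresholds <- structure(lapply(b$thresholds, function(th)
    list(lower = th$lower, upper = th$upper,
         lower_active = isTRUE(th$lower_active),
         upper_active = isTRUE(th$upper_active))),
    class = "winsor_thresholds")
  imp <- b$imputation
  imputation <- imputation_config(
    m_mice = b$m_mice, k_lab = b$k_lab, n_cycles = imp$n_cycles %||% 10L,
    include_outcome_in_mice = isTRUE(imp$include_outcome_in_mice),
    include_outcome_in_lab = isTRUE(imp$include_outcome_in_lab),
    lab_residual_noise = isTRUE(imp$lab_residual_noise),
    lactate_log_scale = isTRUE(imp$lactate_log_scale),
    seed = imp$seed %||% 1L)
  structure(list(pooled = pooled,
                 lab_imputers = lapply(b$lab_imputers, function(pair)
                   lapply(pair, lab_imputer_from_list)),
                 thresholds = thresholds, spec = spec,
                 specs = default_variable_specs(), imputation = imputation,
                 meta = meta, m_mice = b$m_mice, k_lab = b$k_lab,
                 n_completed_datasets = b$m_mice * b$k_lab, n = b$n,
                 prevalence = b$prevalence, converged = TRUE),
            class = "distrisk")
}
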