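# design meta from observed (non-missing) values of a winsorized cohort, so
# every per-imputation fit shares identical knots and column maps
fit_design_meta_observed <- function(x, spec, specs = x$specs) {
  meta <- list()
  for (v in spec_variables(spec)) {
    kind <- specs[[v]]$kind
    if (kind == "continuous") {
      vals <- x$data[[v]]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L)
        stop("no observed values of '", v, "' to anchor the spline basis")
      meta[[v]] <- list(kind = "continuous", range = range(vals),
                        median = stats::median(vals))
    } else {
      meta[[v]] <- list(kind = "discrete", levels = specs[[v]]$categories,
                        base = specs[[v]]$base)
    }
  }
  structure(meta, class = "design_meta")
}

# draw k completed copies of `completed` with both labs imputed jointly
complete_labs <- function(completed, lactate_model, albumin_model, k, seed,
                          thresholds, config) {
  lac <- draw_lab_imputations(lactate_model, completed, k, seed = seed,
                              thresholds = thresholds, config = config)
  alb <- draw_lab_imputations(albumin_model, completed, k,
                              seed = seed + 1L, thresholds = thresholds,
                              config = config)
  lapply(seq_len(k), function(l) {
    cj <- lac[[l]]
    cj$data$albumin <- alb[[l]]$data$albumin
    cj$lab_index <- l
    cj
  })
}

#' Fit the distributional mortality risk model
#'
#' End-to-end model fitting on a development cohort:
#' \enumerate{
#'   \item redact physiologically implausible values, derive the lactate and
#'     albumin missingness indicators, fit Winsor thresholds (0.1/99.9
#'     percentiles; upper-only for age) and clamp;
#'   \item multiply impute the routine covariates by chained equations
#'     (`m_mice` datasets, outcome included as predictor) and complete the
#'     nominal variables probabilistically;
#'   \item fit Gaussian GAM sub-models for lactate and albumin on each
#'     completed dataset, then draw `k_lab` posterior-predictive imputations
#'     from each, giving `m_mice * k_lab` fully completed datasets;
#'   \item fit the penalized binomial-logit GAM on each completed dataset
#'     and pool the fits with Rubin's rules.
#' }
#' The pooled coefficient covariance carries both estimation and
#' between-imputation uncertainty and is sampled at prediction time.
#'
#' @param x A [cohort()] with non-missing outcome.
#' @param spec Model structure; defaults to [default_gam_spec()].
#' @param imputation An [imputation_config()].
#' @param seed Master seed (defaults to the imputation config's).
#' @param redact Apply plausible-range redaction first (default `TRUE`).
#' @return An object of class `"distrisk"` with elements `pooled`
#'   (the Rubin-pooled GAM), `lab_imputers` (per first-stage imputation, a
#'   `lactate`/`albumin` model pair), `thresholds`, `spec`, `specs`,
#'   `imputation`, `m_mice`, `k_lab`, `n`, `prevalence`.
#' @seealso [predict.distrisk()], [partial_dependence()], [run_validation()]
#' @export
distrisk <- function(x, spec = default_gam_spec(),
                     imputation = imputation_config(), seed = NULL,
                     redact = TRUE) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(seed)) imputation$seed <- as.integer(seed)
  if (redact) x <- redact_implausible(x)
  x <- add_missingness_indicators(x)
  thresholds <- fit_winsor_thresholds(x)
  x <- apply_winsor(x, thresholds)

  meta <- fit_design_meta_observed(x, spec)
  mice_list <- run_mice(x, imputation)
  m <- attr(mice_list, "m_mice")
  mice_list <- lapply(mice_list, impute_categoricals, config = imputation)

  need_albumin <- "albumin" %in% spec_variables(spec)
  lab_imputers <- vector("list", m)
  completed <- list()
  fits <- vector("list", 0L)
  for (j in seq_len(m)) {
    lac <- fit_lab_imputer(mice_list[[j]], "lactate", imputation)
    alb <- fit_lab_imputer(mice_list[[j]], "albumin", imputation)
    lab_imputers[[j]] <- list(lactate = lac, albumin = alb)
    cs <- complete_labs(mice_list[[j]], lac, alb, imputation$k_lab,
                        seed = subseed(imputation$seed, 3000L + j),
                        thresholds = thresholds, config = imputation)
    for (cj in cs) {
      fit <- fit_binomial_gam(cj, spec, meta = meta, specs = x$specs)
      fits[[length(fits) + 1L]] <- fit
    }
    completed[[j]] <- cs
  }
  pooled <- pool_fits(fits)

  structure(list(pooled = pooled, lab_imputers = lab_imputers,
                 thresholds = thresholds, spec = spec, specs = x$specs,
                 imputation = imputation, meta = meta,
                 m_mice = m, k_lab = imputation$k_lab,
                 n_completed_datasets = length(fits),
                 n = nrow(x$data), prevalence = mean(x$data$died),
                 converged = pooled$converged),
            class = "distrisk")
}

#' @export
print.distrisk <- function(x, ...) {
  cat("<distrisk> distributional mortality risk model\n",
      "  n = ", x$n, " cases, prevalence ",
      sprintf("%.1f%%", 100 * x$prevalence), "\n",
      "  ", x$m_mice, " chained-equation imputations x ", x$k_lab,
      " lab draws = ", x$n_completed_datasets,
      " completed datasets pooled (Rubin's rules)\n",
      "  ", length(x$pooled$coef), " coefficients; converged: ",
      x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
summary.distrisk <- function(object, ...) {
  se <- sqrt(diag(object$pooled$cov))
  within <- sqrt(diag(object$pooled$within_cov))
  out <- list(model = object,
              coef_table = data.frame(estimate = object$pooled$coef,
                                      se = se, within_se = within),
              terms = names(object$pooled$col_map))
  class(out) <- "summary.distrisk"
  out
}

#' @export
print.summary.distrisk <- function(x, ...) {
  print(x$model)
  cat("  terms:\n")
  for (t in x$terms) cat("    ", t, "\n", sep = "")
  cat("  coefficient magnitude: max |beta| = ",
      format(round(max(abs(x$coef_table$estimate)), 3)), "\n", sep = "")
  invisible(x)
}

#' @export
coef.distrisk <- function(object, ...) object$pooled$coef

#' Plot partial dependence of one covariate
#'
#' Draws the nested confidence-band profile from [partial_dependence()]
#' with base graphics: darker bands are narrower (20%), lighter bands wider
#' (95%).
#'
#' @param x A `"distrisk"` model.
#' @param variable Covariate name to profile.
#' @param ... Passed to [partial_dependence()].
#' @return The partial-dependence data.frame, invisibly.
#' @export
plot.distrisk <- function(x, variable, ...) {
  pd <- partial_dependence(x$pooled, variable, ...)
  lev <- sort(as.numeric(sub("^lo", "", grep("^lo", names(pd), value = TRUE))),
              decreasing = TRUE)
  xs <- if (is.numeric(pd$value)) pd$value else seq_along(pd$value)
  ylim <- range(pd[grep("^(lo|hi)", names(pd))], pd$median)
  graphics::plot(xs, pd$median, type = "n", xlab = variable,
                 ylab = "predicted mortality risk", ylim = ylim,
                 xaxt = if (is.numeric(pd$value)) "s" else "n")
  if (!is.numeric(pd$value))
    graphics::axis(1L, at = xs, labels = pd$value)
  shade <- grDevices::grey(seq(0.85, 0.45, length.out = length(lev)))
  for (i in seq_along(lev)) {
    graphics::polygon(c(xs, rev(xs)),
                      c(pd[[paste0("lo", lev[i])]],
                        rev(pd[[paste0("hi", lev[i])]])),
                      col = shade[i], border = NA)
  }
  graphics::lines(xs, pd$median, lwd = 2)
  invisible(pd)
}
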