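# prepare new cases for prediction: winsorize, refresh indicators, check
# routine covariates are supplied
prepare_newdata <- function(model, newdata) {
  d <- as_case_data(newdata)
  routine <- routine_covariates(model$specs)
  modelled <- spec_variables(model$spec)
  lab_covs <- unique(unlist(lapply(model$lab_imputers[[1L]], `[[`,
                                   "covariates")))
  needed <- union(intersect(routine, modelled), setdiff(lab_covs, "died"))
  for (v in needed) {
    if (is.null(d[[v]]) || anyNA(d[[v]]))
      stop("prediction error: routine covariate '", v,
           "' is missing; prospective imputation covers only lactate and albumin")
  }
  d$lactate_missing <- as.numeric(is.na(d$lactate))
  d$albumin_missing <- as.numeric(is.na(d$albumin))
  for (nm in names(model$thresholds))
    if (!is.null(d[[nm]])) d[[nm]] <- winsor_clamp(d[[nm]], model$thresholds, nm)
  d
}

#' Predict per-case mortality risk samples
#'
#' For each of the model's `m_mice` lab-imputer pairs and each of `k_lab`
#' posterior-predictive lab draws, missing lactate/albumin values are
#' imputed and `n_coef_draws` risks are computed from coefficient vectors
#' sampled from the pooled approximate posterior — a total of
#' `m_mice * k_lab * n_coef_draws` risk samples per case (420 under the
#' headline configuration of 28 x 3 x 5). Fully observed cases pass the
#' same completed version through the whole grid, so their variation comes
#' from the coefficient draws alone.
#'
#' @param object A fitted `"distrisk"` model.
#' @param newdata Cohort or data.frame of cases; routine covariates must be
#'   observed (only lactate/albumin are imputed prospectively).
#' @param n_coef_draws Coefficient draws per completed version (default 5).
#' @param seed Integer seed.
#' @param type `"summary"` (default) returns a data.frame of per-case
#'   median, 2.5th/97.5th percentiles and risk distribution range with the
#'   sample matrix attached as attribute `"samples"`; `"samples"` returns
#'   the cases-by-samples matrix; `"distribution"` returns a list of
#'   [risk_distribution()] objects.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.distrisk <- function(object, newdata, n_coef_draws = 5L, seed = 1L,
                             type = c("summary", "samples", "distribution"),
                             ...) {
  type <- match.arg(type)
  d <- prepare_newdata(object, newdata)
  n <- nrow(d)
  m <- object$m_mice
  k <- object$k_lab
  s <- as.integer(n_coef_draws)
  total <- m * k * s
  samples <- matrix(NA_real_, n, total)
  prov <- data.frame(mice = integer(total), lab = integer(total),
                     coef = integer(total))
  dd <- cohort_like_frame(d, object$specs)
  idx <- 0L
  for (j in seq_len(m)) {
    pair <- object$lab_imputers[[j]]
    for (l in seq_len(k)) {
      set.seed(subseed(seed, j * 1000L + l))
      comp <- dd
      for (target in c("lactate", "albumin")) {
        mdl <- pair[[target]]
        if (is.null(mdl)) next
        mis <- is.na(comp[[target]])
        if (any(mis)) {
          val <- lab_imputer_draw_values(
            mdl, comp[mis, , drop = FALSE],
            residual_noise = object$imputation$lab_residual_noise)
          val <- winsor_clamp(val, object$thresholds, target)
          comp[[target]][mis] <- val
        }
      }
      B <- sample_coefficients(object$pooled, s,
                               seed = subseed(seed, 7L + j * 977L + l))
      risks <- stats::plogis(gam_linpred(object$pooled, comp, B))
      cols <- idx + seq_len(s)
      samples[, cols] <- risks
      prov$mice[cols] <- j
      prov$lab[cols] <- l
      prov$coef[cols] <- seq_len(s)
      idx <- idx + s
    }
  }
  rownames(samples) <- d$case_id
  if (type == "samples") {
    attr(samples, "provenance") <- prov
    return(samples)
  }
  if (type == "distribution") {
    return(lapply(seq_len(n), function(i) {
      risk_distribution(d$case_id[i], samples[i, ], prov)
    }))
  }
  summ <- t(apply(samples, 1L, function(r)
    unlist(risk_summary_samples(r))))
  out <- data.frame(case_id = d$case_id, summ, row.names = NULL)
  attr(out, "samples") <- samples
  attr(out, "provenance") <- prov
  out
}

cohort_like_frame <- function(d, specs) d

#' Predict the full risk distribution for one case
#'
#' Convenience wrapper around [predict.distrisk()] returning a single
#' [risk_distribution()] object for a one-row case record.
#'
#' @param case One-row data.frame (or single-case cohort).
#' @param model A fitted `"distrisk"` model.
#' @param n_coef_draws Coefficient draws per completed version (default 5).
#' @param seed Integer seed.
#' @return A `"risk_distribution"`.
#' @export
predict_distribution <- function(case, model, n_coef_draws = 5L, seed = 1L) {
  stats::predict(model, case, n_coef_draws = n_coef_draws, seed = seed,
                 type = "distribution")[[1L]]
}

#' Construct a per-case risk distribution
#'
#' @param case_id Case identifier.
#' @param samples Numeric vector of risk samples in (0, 1).
#' @param provenance Optional data.frame of `(mice, lab, coef)` indices per
#'   sample.
#' @return An object of class `"risk_distribution"` with the samples,
#'   provenance and cached summary (median, p2.5, p97.5, rdr).
#' @export
risk_distribution <- function(case_id, samples, provenance = NULL) {
  stopifnot(all(samples > 0 & samples < 1))
  structure(list(case_id = case_id, samples = as.numeric(samples),
                 provenance = provenance,
                 summary = risk_summary_samples(samples)),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  s <- x$summary
  cat("<risk_distribution> case ", x$case_id, ": ", length(x$samples),
      " samples\n  median ", sprintf("%.1f%%", 100 * s$median),
      ", 95% range ", sprintf("%.1f%%", 100 * s$p2.5), " - ",
      sprintf("%.1f%%", 100 * s$p97.5),
      " (rdr ", sprintf("%.1f", 100 * s$rdr), " points)\n", sep = "")
  invisible(x)
}

risk_summary_samples <- function(samples) {
  q <- stats::quantile(samples, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  list(median = q[2L], p2.5 = q[1L], p97.5 = q[3L], rdr = q[3L] - q[1L])
}

#' Summarize a risk distribution
#'
#' Returns the median predicted risk (the point estimate), the 2.5th and
#' 97.5th percentiles, and the risk distribution range (rdr), defined as
#' the width between those two percentiles. The rdr approximates a 95%
#' credible interval when all covariates are observed, and widens towards a
#' prediction interval where labs were imputed.
#'
#' @param dist A `"risk_distribution"` or a numeric vector of samples.
#' @return List with `median`, `p2.5`, `p97.5`, `rdr`.
#' @export
risk_summary <- function(dist) {
  samples <- if (inherits(dist, "risk_distribution")) dist$samples else dist
  if (length(samples) < 2L) stop("need at least 2 risk samples to summarize")
  risk_summary_samples(samples)
}

#' Kernel density curve of a risk distribution
#'
#' Gaussian-kernel density of the risk samples with boundary reflection at
#' 0 and 1, so no probability mass leaks outside the unit interval; the
#' returned curve integrates to 1 on the grid. Bandwidth defaults to
#' Silverman's plug-in rule.
#'
#' @param dist A `"risk_distribution"` or numeric vector of samples (>= 10).
#' @param bandwidth Optional kernel bandwidth.
#' @param n_grid Grid resolution on `[0, 1]`.
#' @return Data.frame with `risk` (grid) and `density`.
#' @export
density_curve <- function(dist, bandwidth = NULL, n_grid = 512L) {
  samples <- if (inherits(dist, "risk_distribution")) dist$samples else dist
  if (length(samples) < 10L) stop("need at least 10 samples for a density curve")
  if (stats::sd(samples) < 1e-12) {
    warning("degenerate risk distribution: all samples identical",
            call. = FALSE)
    grid <- seq(0, 1, length.out = n_grid)
    dens <- numeric(n_grid)
    at <- which.min(abs(grid - samples[1L]))
    dens[at] <- 1 / (grid[2L] - grid[1L])
    return(data.frame(risk = grid, density = dens))
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(samples)
  augmented <- c(samples, -samples, 2 - samples)
  kd <- stats::density(augmented, bw = bandwidth, from = 0, to = 1,
                       n = n_grid)
  data.frame(risk = kd$x, density = 3 * kd$y)
}
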