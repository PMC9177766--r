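#' Point-prediction scores: AUROC, Tjur, log loss, Brier
#'
#' AUROC is the pairwise concordance probability (ties credited 0.5),
#' computed from midranks. Log loss is the mean negative Bernoulli
#' log-likelihood with probabilities clipped to `[1e-15, 1 - 1e-15]`; the
#' Brier score is the mean squared error; Tjur's discrimination coefficient
#' is the mean predicted risk among events minus that among non-events.
#'
#' @param risks Predicted probabilities.
#' @param outcomes Binary 0/1 outcomes of the same length.
#' @return Named list `auroc`, `tjur`, `log_loss`, `brier`.
#' @export
score_predictions <- function(risks, outcomes) {
  if (length(risks) != length(outcomes))
    stop("risks and outcomes must have equal length")
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L)
    stop("auroc/tjur undefined: only one outcome class present")
  r <- rank(risks)
  auroc <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- pmin(pmax(risks, 1e-15), 1 - 1e-15)
  list(auroc = auroc,
       tjur = mean(risks[outcomes == 1]) - mean(risks[outcomes == 0]),
       log_loss = -mean(outcomes * log(p) + (1 - outcomes) * log(1 - p)),
       brier = mean((risks - outcomes)^2))
}

#' Score a distribution-predicting model
#'
#' Each column of the sample matrix is scored as a point-prediction vector
#' and the scores are averaged over columns, so a model predicting many
#' risks per case is evaluated as the mean of its per-sample scores.
#'
#' @param sample_matrix Cases-by-samples matrix of predicted risks.
#' @param outcomes Binary outcomes, one per row.
#' @param include_mace Also average the calibration error across columns
#'   (slower; needs >= 100 cases).
#' @return Named list of mean scores.
#' @export
score_distribution_model <- function(sample_matrix, outcomes,
                                     include_mace = FALSE) {
  if (!is.matrix(sample_matrix))
    sample_matrix <- matrix(sample_matrix, ncol = 1L)
  if (nrow(sample_matrix) != length(outcomes))
    stop("shape error: sample matrix rows must match outcomes length")
  per_col <- apply(sample_matrix, 2L, function(col) {
    s <- score_predictions(col, outcomes)
    if (include_mace)
      s$mace <- calibration_curve(col, outcomes)$mace
    unlist(s)
  })
  as.list(rowMeans(per_col))
}

#' Smooth calibration curve and mean absolute calibration error
#'
#' Regresses the outcome on a natural-spline basis of the logit of the
#' predicted risk (flexible logistic recalibration), evaluates the fitted
#' curve on an equally spaced grid spanning the central 99% of the
#' predictions, and reports the mean absolute error between the curve and
#' the line of identity, weighted by the empirical density of predictions
#' over the grid.
#'
#' @param risks Predicted probabilities (>= 100 cases).
#' @param outcomes Binary 0/1 outcomes.
#' @param df Spline degrees of freedom for the recalibration basis.
#' @param n_grid Grid size.
#' @return List with `curve` (data.frame `risk`, `observed`, `weight`) and
#'   `mace`.
#' @export
calibration_curve <- function(risks, outcomes, df = 4L, n_grid = 100L) {
  if (length(risks) < 100L)
    stop("calibration assessment needs at least 100 cases")
  if (length(unique(outcomes)) < 2L)
    stop("calibration undefined: only one outcome class present")
  p <- pmin(pmax(risks, 1e-15), 1 - 1e-15)
  lp <- stats::qlogis(p)
  if (stats::sd(lp) < 1e-8)
    stop("degenerate calibration: predictions are (near-)constant")
  basis <- splines::ns(lp, df = df)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, basis), outcomes, family = stats::binomial())
  )
  qs <- stats::quantile(p, c(0.005, 0.995), names = FALSE)
  grid <- seq(qs[1L], qs[2L], length.out = n_grid)
  gb <- stats::predict(basis, stats::qlogis(grid))
  curve <- stats::plogis(drop(cbind(1, gb) %*% fit$coefficients))
  # weight grid points by how many predictions fall nearest to each
  cuts <- c(-Inf, (grid[-1L] + grid[-n_grid]) / 2, Inf)
  w <- as.numeric(table(cut(p, cuts)))
  w <- w / sum(w)
  list(curve = data.frame(risk = grid, observed = curve, weight = w),
       mace = sum(w * abs(curve - grid)))
}

#' Hospital-grouped repeated train/test splits
#'
#' Randomly assigns whole hospitals to development or validation — cases
#' follow their hospital, so no hospital contributes to both sides of any
#' split. Splitting is repeated `n_splits` times (default 120) with an 80%
#' development fraction.
#'
#' @param hospital_ids Character vector of hospital identifiers (all
#'   hospitals, duplicates allowed — e.g. the cohort column).
#' @param n_splits Number of repeated splits (default 120).
#' @param train_frac Fraction of hospitals assigned to development.
#' @param seed Integer seed.
#' @return A `"split_plan"`: list of `n_splits` elements, each with
#'   `train_hospitals` and `test_hospitals`.
#' @export
make_split_plan <- function(hospital_ids, n_splits = 120L, train_frac = 0.8,
                            seed = 1L) {
  hospitals <- sort(unique(hospital_ids))
  if (length(hospitals) < 2L)
    stop("split error: need at least 2 hospitals for grouped splitting")
  n_train <- max(1L, min(length(hospitals) - 1L,
                         round(train_frac * length(hospitals))))
  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(i) {
    tr <- sample(hospitals, n_train)
    list(train_hospitals = sort(tr),
         test_hospitals = sort(setdiff(hospitals, tr)))
  })
  structure(splits, class = "split_plan", train_frac = train_frac,
            seed = seed)
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> ", length(x), " hospital-grouped splits (",
      length(x[[1L]]$train_hospitals), " train / ",
      length(x[[1L]]$test_hospitals), " test hospitals)\n", sep = "")
  invisible(x)
}

pctl <- function(v, p) stats::quantile(v, p, names = FALSE, type = 7)

#' Aggregate per-split scores with percentile confidence intervals
#'
#' For every score of every model, reports the median across splits with
#' the 2.5th and 97.5th percentiles as a 95% confidence interval, plus the
#' within-split paired differences of each model against the first
#' (baseline) model, aggregated the same way.
#'
#' @param per_split Data.frame with columns `split`, `model`, and one
#'   column per score.
#' @param baseline Model name the paired differences are taken against;
#'   defaults to the alphabetically first model, so the report is invariant
#'   to the row order of `per_split`.
#' @return A `"score_report"`: list with `summary` (model x score rows:
#'   median, p2.5, p97.5), `differences` (same layout, model minus
#'   baseline), and the raw `per_split` table.
#' @export
aggregate_cv <- function(per_split, baseline = NULL) {
  if (length(unique(per_split$split)) < 2L)
    stop("aggregate_cv needs at least 2 splits")
  score_cols <- setdiff(names(per_split), c("split", "model"))
  models <- sort(unique(per_split$model))
  if (is.null(baseline)) baseline <- models[1L]
  if (!baseline %in% models) stop("baseline model not present")
  models <- c(baseline, setdiff(models, baseline))
  agg <- function(d, model_label) {
    do.call(rbind, lapply(score_cols, function(sc) {
      v <- d[[sc]]
      data.frame(model = model_label, score = sc,
                 median = stats::median(v),
                 p2.5 = pctl(v, 0.025), p97.5 = pctl(v, 0.975))
    }))
  }
  summary <- do.call(rbind, lapply(models, function(mo)
    agg(per_split[per_split$model == mo, ], mo)))
  differences <- NULL
  if (length(models) > 1L) {
    base <- per_split[per_split$model == models[1L], ]
    base <- base[order(base$split), ]
    differences <- do.call(rbind, lapply(models[-1L], function(mo) {
      d <- per_split[per_split$model == mo, ]
      d <- d[order(d$split), ]
      stopifnot(identical(d$split, base$split))
      diff_d <- d
      for (sc in score_cols) diff_d[[sc]] <- d[[sc]] - base[[sc]]
      agg(diff_d, paste0(mo, " - ", models[1L]))
    }))
  }
  structure(list(summary = summary, differences = differences,
                 per_split = per_split),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report> ", length(unique(x$per_split$split)), " splits\n",
      sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %-9s %.4f (%.4f - %.4f)\n", s$model[i], s$score[i],
                s$median[i], s$p2.5[i], s$p97.5[i]))
  invisible(x)
}

#' Default baseline-comparator covariates
#'
#' The re-fitted complete-case logistic baseline uses the routinely
#' measured covariates; cases missing any of them are excluded from both
#' models' test sets so the comparison is on identical cases.
#'
#' @return Character vector of covariate names.
#' @export
baseline_covariates <- function() {
  c("age", "asa", "cardio_status", "resp_status", "heart_rate",
    "arrhythmia", "systolic_bp", "sodium", "potassium", "wcc",
    "creatinine", "bun", "gcs", "ct_performed", "soiling", "malignancy",
    "indication")
}

baseline_frame <- function(d, covariates, specs) {
  out <- list()
  for (v in covariates) {
    kind <- specs[[v]]$kind
    if (kind %in% c("continuous", "binary")) {
      out[[v]] <- as.numeric(d[[v]])
    } else if (kind == "ordinal") {
      out[[v]] <- as.numeric(as.character(d[[v]]))
    } else {
      out[[v]] <- factor(d[[v]], levels = specs[[v]]$categories)
    }
  }
  as.data.frame(out)
}

fit_baseline <- function(train_d, covariates, specs) {
  df <- baseline_frame(train_d, covariates, specs)
  df$died <- train_d$died
  stats::glm(died ~ ., data = df, family = stats::binomial())
}

predict_baseline <- function(fit, test_d, covariates, specs) {
  df <- baseline_frame(test_d, covariates, specs)
  as.numeric(stats::predict(fit, newdata = df, type = "response"))
}

#' Run the full grouped cross-validation harness
#'
#' Per split: Winsor thresholds, imputation sub-models and the pooled GAM
#' are all refit on the development hospitals only; validation cases with
#' missing values among the baseline covariates are excluded from scoring
#' for both models; the distributional model is scored as the mean of its
#' per-sample scores and the complete-case logistic baseline on its point
#' predictions. Risk-distribution-range summaries are stratified by which
#' labs were imputed.
#'
#' @param x Development + validation cohort.
#' @param plan A [make_split_plan()] over the cohort's hospitals.
#' @param spec Model spec for the distributional model.
#' @param imputation An [imputation_config()].
#' @param baseline Covariate names for the complete-case logistic baseline.
#' @param n_coef_draws Coefficient draws per completed version.
#' @param seed Master seed.
#' @param include_mace Include the calibration error among per-split scores.
#' @return A `"score_report"` with an extra `rdr_strata` element: per
#'   split and lab-missingness group (none / albumin-only / lactate-only /
#'   both), the median and 2.5/97.5 percentiles of the risk distribution
#'   range.
#' @export
run_validation <- function(x, plan, spec = default_gam_spec(),
                           imputation = imputation_config(),
                           baseline = baseline_covariates(),
                           n_coef_draws = 5L, seed = 1L,
                           include_mace = TRUE) {
  stopifnot(inherits(x, "cohort"))
  if (!all(unlist(lapply(plan, `[[`, "test_hospitals")) %in%
           x$data$hospital_id))
    stop("split plan references hospitals absent from the cohort")
  rows <- list()
  rdr_rows <- list()
  for (i in seq_along(plan)) {
    sp <- plan[[i]]
    train <- x[x$data$hospital_id %in% sp$train_hospitals]
    test <- x[x$data$hospital_id %in% sp$test_hospitals]
    # complete-case rule on the baseline covariates, applied to both models
    test_complete <- rowSums(is.na(test$data[, baseline, drop = FALSE])) == 0L
    test <- test[test_complete]
    if (nrow(test$data) == 0L || length(unique(test$data$died)) < 2L) {
      warning("split ", i, " skipped: empty or single-class validation set",
              call. = FALSE)
      next
    }
    imp_i <- imputation
    imp_i$seed <- subseed(seed, 17L * i)
    model <- distrisk(train, spec = spec, imputation = imp_i)
    bl_train <- train$data[rowSums(is.na(train$data[, baseline,
                                                    drop = FALSE])) == 0L, ]
    bl_fit <- fit_baseline(bl_train, baseline, x$specs)
    bl_risk <- predict_baseline(bl_fit, test$data, baseline, x$specs)
    samples <- stats::predict(model, test, n_coef_draws = n_coef_draws,
                              seed = subseed(seed, 31L * i),
                              type = "samples")
    y <- test$data$died
    s_model <- score_distribution_model(samples, y,
                                        include_mace = include_mace)
    s_base <- score_predictions(bl_risk, y)
    if (include_mace)
      s_base$mace <- calibration_curve(bl_risk, y)$mace
    rows[[length(rows) + 1L]] <-
      data.frame(split = i, model = "baseline", as.data.frame(s_base))
    rows[[length(rows) + 1L]] <-
      data.frame(split = i, model = "distrisk", as.data.frame(s_model))

    rdr <- apply(samples, 1L, function(r) {
      q <- pctl(r, c(0.025, 0.975)); q[2L] - q[1L]
    })
    lac_mis <- is.na(test$data$lactate)
    alb_mis <- is.na(test$data$albumin)
    group <- ifelse(lac_mis & alb_mis, "both",
                    ifelse(lac_mis, "lactate_only",
                           ifelse(alb_mis, "albumin_only", "none")))
    for (g in unique(group)) {
      v <- rdr[group == g]
      rdr_rows[[length(rdr_rows) + 1L]] <-
        data.frame(split = i, group = g, n = length(v),
                   median = stats::median(v),
                   p2.5 = pctl(v, 0.025), p97.5 = pctl(v, 0.975))
    }
  }
  per_split <- do.call(rbind, rows)
  report <- aggregate_cv(per_split)
  report$rdr_strata <- do.call(rbind, rdr_rows)
  report
}

#' Write a score report to CSV and JSON
#' @param report A `"score_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_score_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_split, file.path(dir, "per_split.csv"),
                   row.names = FALSE)
  if (!is.null(report$differences))
    utils::write.csv(report$differences, file.path(dir, "differences.csv"),
                     row.names = FALSE)
  if (!is.null(report$rdr_strata))
    utils::write.csv(report$rdr_strata, file.path(dir, "rdr_strata.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            differences = report$differences,
                            rdr_strata = report$rdr_strata),
                       file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
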