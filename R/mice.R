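#' Configure the two-stage imputation
#'
#' Stage one multiply imputes the routinely measured covariates by chained
#' equations (with the mortality outcome as a covariate, to avoid biasing
#' coefficients towards the null) and completes the nominal variables by
#' probabilistic categorical imputation. Stage two fits Gaussian GAM
#' sub-models for lactate and albumin on each completed dataset and draws
#' `k_lab` imputations from each model's posterior predictive, yielding
#' `m_mice * k_lab` completed datasets in total.
#'
#' @param m_mice Number of first-stage imputations; `NULL` derives it from
#'   the fraction of incomplete cases via [choose_n_imputations()].
#' @param k_lab Lab imputations per completed dataset (default 3).
#' @param n_cycles Chained-equation cycles (default 10).
#' @param include_outcome_in_mice Include `died` as a predictor in the
#'   chained equations (default `TRUE`).
#' @param include_outcome_in_lab Include `died` in the lactate/albumin
#'   sub-models (default `FALSE`, enabling prospective use before the
#'   outcome exists).
#' @param lab_residual_noise Add residual noise to posterior-predictive lab
#'   draws (default `TRUE`, proper imputation); `FALSE` restricts draw
#'   variability to coefficient uncertainty.
#' @param lactate_log_scale Model lactate on the log scale in its sub-model
#'   (default `TRUE`; it is right-skewed).
#' @param seed Master seed for the imputation streams.
#' @return An `"imputation_config"`.
#' @export
imputation_config <- function(m_mice = NULL, k_lab = 3L, n_cycles = 10L,
                              include_outcome_in_mice = TRUE,
                              include_outcome_in_lab = FALSE,
                              lab_residual_noise = TRUE,
                              lactate_log_scale = TRUE,
                              seed = 1L) {
  if (!is.null(m_mice) && m_mice < 1L) stop("m_mice must be >= 1")
  if (k_lab < 1L) stop("k_lab must be >= 1")
  structure(list(m_mice = if (!is.null(m_mice)) as.integer(m_mice),
                 k_lab = as.integer(k_lab), n_cycles = as.integer(n_cycles),
                 include_outcome_in_mice = isTRUE(include_outcome_in_mice),
                 include_outcome_in_lab = isTRUE(include_outcome_in_lab),
                 lab_residual_noise = isTRUE(lab_residual_noise),
                 lactate_log_scale = isTRUE(lactate_log_scale),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Number of first-stage imputations from the incomplete-case fraction
#'
#' Implements the rule of thumb that the number of imputations should be
#' about the percentage of incomplete cases: `ceiling(100 * frac)`, with a
#' minimum of one. A 27.2% incomplete fraction gives 28 imputations.
#'
#' @param frac_incomplete Proportion of incomplete cases in `[0, 1]`.
#' @return Integer imputation count.
#' @export
choose_n_imputations <- function(frac_incomplete) {
  if (!is.numeric(frac_incomplete) || is.na(frac_incomplete) ||
      frac_incomplete < 0 || frac_incomplete > 1)
    stop("frac_incomplete must be a proportion in [0, 1]")
  max(1L, as.integer(ceiling(100 * frac_incomplete)))
}

# numeric working encoding for chained-equation predictors
mice_numeric_frame <- function(d, vars) {
  out <- lapply(vars, function(v) as.numeric(as.character(d[[v]])))
  names(out) <- vars
  as.data.frame(out)
}

bayes_lm_draw <- function(Xobs, yobs, Xmis) {
  p <- ncol(Xobs)
  A <- crossprod(Xobs) + diag(1e-8, p)
  R <- chol_factor(A)
  bhat <- drop(chol_solve(R, crossprod(Xobs, yobs)))
  resid <- yobs - drop(Xobs %*% bhat)
  df <- max(length(yobs) - p, 1L)
  sigma2 <- sum(resid^2) / stats::rchisq(1L, df)
  Ainv <- chol2inv(R)
  Rb <- chol_factor(sigma2 * Ainv)
  beta <- bhat + drop(t(Rb) %*% stats::rnorm(p))
  drop(Xmis %*% beta) + stats::rnorm(nrow(Xmis), 0, sqrt(sigma2))
}

bayes_logit_draw <- function(Xobs, yobs, Xmis) {
  fit <- suppressWarnings(
    stats::glm.fit(Xobs, yobs, family = stats::binomial())
  )
  bhat <- fit$coefficients
  bhat[is.na(bhat)] <- 0
  w <- pmax(fit$weights, 1e-10)
  A <- crossprod(Xobs, Xobs * w) + diag(1e-8, ncol(Xobs))
  R <- chol_factor(A)
  V <- chol2inv(R)
  Rv <- chol_factor((V + t(V)) / 2)
  beta <- bhat + drop(t(Rv) %*% stats::rnorm(length(bhat)))
  p <- stats::plogis(drop(Xmis %*% beta))
  stats::rbinom(nrow(Xmis), 1L, p)
}

#' First-stage multiple imputation by chained equations
#'
#' Multiply imputes the routinely measured non-nominal covariates
#' (continuous, binary, and ordinal treated on the linear scale then
#' rounded to valid levels). Lactate and albumin are excluded — they keep
#' their missing values for the second stage — as are the nominal
#' variables, which [impute_categoricals()] completes afterwards.
#' Conditional models are proper Bayesian draws: linear regression with
#' scaled inverse-chi-square residual variance for continuous targets,
#' logistic coefficient draws with Bernoulli sampling for binary. Predictors
#' are the other routine non-nominal covariates, the lab missingness
#' indicators and (by default) the outcome. Visit order is increasing
#' missingness; chains are independent across imputations and the whole
#' procedure is deterministic given the config seed.
#'
#' @param x A cohort with non-missing outcome.
#' @param config An [imputation_config()].
#' @return List of `m_mice` completed datasets (cohorts with elements
#'   `mice_index`; lactate/albumin still possibly missing). The number of
#'   imputations used is attached as attribute `"m_mice"`.
#' @export
run_mice <- function(x, config = imputation_config()) {
  d <- x$data
  if (anyNA(d$died)) stop("outcome must be non-missing for every case")
  specs <- x$specs
  routine <- routine_covariates(specs)
  nominal <- routine[vapply(routine, function(v) specs[[v]]$kind == "nominal",
                            logical(1L))]
  chain_vars <- setdiff(routine, nominal)

  for (v in c(chain_vars, nominal, "lactate", "albumin")) {
    if (all(is.na(d[[v]])))
      stop("imputation error: variable '", v, "' is 100% missing")
  }

  # m rule: fraction of cases incomplete for the routine covariates
  incomplete <- rowSums(is.na(d[, routine, drop = FALSE])) > 0L
  m <- config$m_mice %||% choose_n_imputations(mean(incomplete))

  miss_count <- vapply(chain_vars, function(v) sum(is.na(d[[v]])), integer(1L))
  to_impute <- names(miss_count)[miss_count > 0L]
  to_impute <- to_impute[order(miss_count[to_impute])]

  predictors <- chain_vars
  predictors <- c(predictors, "lactate_missing", "albumin_missing")
  if (config$include_outcome_in_mice) predictors <- c(predictors, "died")

  out <- vector("list", m)
  for (i in seq_len(m)) {
    di <- d
    if (length(to_impute) > 0L) {
      set.seed(subseed(config$seed, 1000L + i))
      num <- mice_numeric_frame(di, unique(c(predictors, to_impute)))
      # initialize by sampling observed values
      for (v in to_impute) {
        mis <- is.na(num[[v]])
        num[[v]][mis] <- sample(num[[v]][!mis], sum(mis), replace = TRUE)
      }
      for (cycle in seq_len(config$n_cycles)) {
        for (v in to_impute) {
          mis <- is.na(d[[v]])
          preds <- setdiff(predictors, v)
          Xall <- cbind(1, as.matrix(num[preds]))
          kind <- specs[[v]]$kind
          yobs <- num[[v]][!mis]
          if (kind == "binary") {
            imp <- bayes_logit_draw(Xall[!mis, , drop = FALSE], yobs,
                                    Xall[mis, , drop = FALSE])
          } else {
            imp <- bayes_lm_draw(Xall[!mis, , drop = FALSE], yobs,
                                 Xall[mis, , drop = FALSE])
            if (kind == "ordinal") {
              lev <- as.numeric(specs[[v]]$categories)
              imp <- pmin(pmax(round(imp), min(lev)), max(lev))
            }
          }
          num[[v]][mis] <- imp
        }
      }
      for (v in to_impute) {
        mis <- is.na(di[[v]])
        val <- num[[v]][mis]
        di[[v]][mis] <- if (specs[[v]]$kind == "ordinal")
          as.character(as.integer(val)) else val
      }
    }
    ci <- cohort(di, specs, x$provenance)
    ci$mice_index <- i
    ci$lab_index <- NA_integer_
    out[[i]] <- ci
  }
  attr(out, "m_mice") <- m
  out
}

#' Probabilistic imputation of the nominal covariates
#'
#' Completes soiling, malignancy and surgical indication in one completed
#' dataset by drawing categories from a fitted conditional model
#' (multinomial logistic on age, ASA grade, heart rate and, by default, the
#' outcome), not by modal assignment. A variable observed with a single
#' category is filled with that category.
#'
#' @param completed A completed dataset from [run_mice()].
#' @param config An [imputation_config()].
#' @return The completed dataset with nominal covariates complete.
#' @export
impute_categoricals <- function(completed, config = imputation_config()) {
  d <- completed$data
  specs <- completed$specs
  nominal <- names(specs)[vapply(names(specs), function(v)
    specs[[v]]$kind == "nominal", logical(1L))]
  set.seed(subseed(config$seed, 2000L + (completed$mice_index %||% 0L)))
  preds <- c("age", "asa", "heart_rate")
  if (config$include_outcome_in_mice) preds <- c(preds, "died")
  pd <- mice_numeric_frame(d, preds)
  pred_ok <- rowSums(is.na(pd)) == 0L
  for (v in nominal) {
    mis <- is.na(d[[v]])
    if (!any(mis)) next
    obs_vals <- d[[v]][!mis]
    cats <- unique(obs_vals)
    if (length(cats) == 1L) {
      d[[v]][mis] <- cats
      next
    }
    # rows whose predictors are incomplete (possible when this runs outside
    # the chained-equation pipeline) fall back to marginal frequency draws
    fallback <- mis & !pred_ok
    if (any(fallback))
      d[[v]][fallback] <- sample(obs_vals, sum(fallback), replace = TRUE)
    mis <- mis & pred_ok
    if (!any(mis)) next
    use <- which(!is.na(d[[v]]) & pred_ok)
    yf <- factor(d[[v]][use])
    df <- cbind(.y = yf, pd[use, , drop = FALSE])
    fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200L)
    pr <- stats::predict(fit, newdata = pd[mis, , drop = FALSE], type = "probs")
    if (is.null(dim(pr))) {
      # two-level response: vector of P(second level)
      if (nlevels(yf) == 2L) {
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- levels(yf)
      } else {
        pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
      }
    }
    lev <- colnames(pr)
    draws <- apply(pr, 1L, function(p) sample(lev, 1L, prob = pmax(p, 0)))
    d[[v]][mis] <- draws
  }
  out <- cohort(d, specs, completed$provenance)
  out$mice_index <- completed$mice_index
  out$lab_index <- completed$lab_index
  out
}
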