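test_that("imputation-count rule: ceiling of the incomplete percentage", {
  expect_identical(choose_n_imputations(0.272), 28L)
  expect_identical(choose_n_imputations(0), 1L)
  expect_identical(choose_n_imputations(1), 100L)
  expect_identical(choose_n_imputations(0.001), 1L)
  expect_error(choose_n_imputations(-0.1), "proportion")
  expect_error(choose_n_imputations(1.5), "proportion")
})

test_that("a fully observed cohort yields m identical copies", {
  co <- test_cohorts()$full[1:800]
  out <- run_mice(co, imputation_config(m_mice = 3, seed = 5))
  expect_length(out, 3)
  for (cd in out) expect_identical(cd$data, co$data)
  expect_equal(vapply(out, `[[`, integer(1), "mice_index"), 1:3)
})

test_that("chained equations are deterministic and preserve observed cells", {
  co <- test_cohorts()$missing[1:2000]
  cfg <- imputation_config(m_mice = 2, seed = 11)
  a <- run_mice(co, cfg)
  b <- run_mice(co, cfg)
  expect_identical(a[[1]]$data, b[[1]]$data)
  expect_identical(a[[2]]$data, b[[2]]$data)
  # observed cells bitwise invariant across datasets
  obs <- !is.na(co$data$bun)
  expect_identical(a[[1]]$data$bun[obs], co$data$bun[obs])
  expect_identical(a[[2]]$data$bun[obs], co$data$bun[obs])
  # imputations vary across datasets where missingness exists
  expect_false(identical(a[[1]]$data$bun[!obs], a[[2]]$data$bun[!obs]))
  # routine non-nominal covariates complete afterwards
  expect_false(anyNA(a[[1]]$data$bun))
  expect_false(anyNA(a[[1]]$data$heart_rate))
  # lactate/albumin left for the second stage
  expect_true(anyNA(a[[1]]$data$lactate))
})

test_that("a variable missing everywhere raises a named error", {
  co <- test_cohorts()$missing[1:500]
  d <- co$data
  d$wcc <- NA_real_
  expect_error(run_mice(cohort(d, co$specs), imputation_config(m_mice = 1)),
               "wcc")
})

test_that("post-imputation means track the pre-deletion truth under MAR", {
  tc <- test_cohorts()
  full <- tc$full[1:5000]
  g <- generator_config(n_cases = 5000, n_hospitals = 30, seed = 21,
                        missingness_rates = list(sodium = 0.3))
  co <- inject_missingness(full, g)
  expect_gt(mean(is.na(co$data$sodium)), 0.25)
  out <- run_mice(co, imputation_config(m_mice = 3, seed = 9))
  truth_mean <- mean(full$data$sodium)
  se <- sd(full$data$sodium) / sqrt(nrow(full$data))
  for (cd in out) {
    expect_lt(abs(mean(cd$data$sodium) - truth_mean), 2 * se)
  }
})

test_that("including the outcome in the chained equations reduces bias", {
  tc <- test_cohorts()
  full <- tc$full[1:5000]
  # give BUN a direct outcome dependence that the other covariates cannot
  # proxy, so omitting the outcome from its conditional model must
  # attenuate the association among imputed values
  d <- full$data
  d$bun <- d$bun + 8 * d$died
  full <- cohort(d, full$specs)
  g <- generator_config(n_cases = 5000, n_hospitals = 30, seed = 33,
                        missingness_rates = list(bun = 0.4))
  co <- inject_missingness(full, g)
  with_y <- run_mice(co, imputation_config(m_mice = 2, seed = 3,
                                           include_outcome_in_mice = TRUE))
  without_y <- run_mice(co, imputation_config(m_mice = 2, seed = 3,
                                              include_outcome_in_mice = FALSE))
  truth <- cor(full$data$bun, full$data$died)
  cor_with <- mean(vapply(with_y, function(cd)
    cor(cd$data$bun, cd$data$died), numeric(1)))
  cor_without <- mean(vapply(without_y, function(cd)
    cor(cd$data$bun, cd$data$died), numeric(1)))
  expect_lt(abs(cor_with - truth), abs(cor_without - truth))
})

test_that("categorical imputation is probabilistic and respects frequencies", {
  co <- fixture("big_missing", {
    gen <- {
      g <- generator_config(n_cases = 20000, seed = 1)
      c(generate_cohort(g), list(config = g))
    }
    inject_missingness(gen$cohort, gen$config)
  })
  cd <- co[1:10000]
  cd <- cohort(cd$data, cd$specs)
  cd$mice_index <- 1L
  # complete the continuous stage minimally: drop rows with missing predictors
  keep <- !is.na(cd$data$heart_rate)
  cd <- cohort(cd$data[keep, ], cd$specs)
  cd$mice_index <- 1L
  out <- impute_categoricals(cd, imputation_config(seed = 13))
  expect_false(anyNA(out$data$indication))
  expect_false(anyNA(out$data$soiling))
  mis <- is.na(cd$data$indication)
  obs_freq <- prop.table(table(cd$data$indication[mis == FALSE]))
  imp_freq <- prop.table(table(factor(out$data$indication[mis],
                                      levels = names(obs_freq))))
  expect_lt(max(abs(imp_freq - obs_freq)), 0.03)
  # draws are probabilistic, not modal
  expect_gt(length(unique(out$data$indication[mis])), 1)
})

test_that("degenerate single-category variables impute to that category", {
  co <- test_cohorts()$missing[1:400]
  d <- co$data
  d$malignancy <- "none"
  d$malignancy[1:20] <- NA
  cd <- cohort(d, co$specs)
  cd$mice_index <- 1L
  out <- impute_categoricals(cd, imputation_config(seed = 2))
  expect_true(all(out$data$malignancy[1:20] == "none"))
})

test_that("lab sub-models honour the outcome-exclusion toggle", {
  co <- test_cohorts()$missing[1:3000]
  mice_out <- run_mice(co, imputation_config(m_mice = 1, seed = 4))
  cd <- impute_categoricals(mice_out[[1]], imputation_config(seed = 4))
  off <- suppressWarnings(
    fit_lab_imputer(cd, "lactate", imputation_config(include_outcome_in_lab = FALSE)))
  expect_false("died" %in% off$covariates)
  on <- suppressWarnings(
    fit_lab_imputer(cd, "lactate", imputation_config(include_outcome_in_lab = TRUE)))
  expect_true("died" %in% on$covariates)
})

test_that("zero-variance lab target raises a fit error", {
  co <- test_cohorts()$full[1:600]
  d <- co$data
  d$albumin <- 35
  cd <- cohort(d, co$specs)
  expect_error(
    fit_lab_imputer(cd, "albumin", imputation_config(), min_observed = 100),
    "zero-variance")
})

test_that("lab imputer recovers a known linear signal at the noise floor", {
  co <- test_cohorts()$full[1:4000]
  d <- co$data
  set.seed(42)
  noise_sd <- 4
  d$albumin <- 50 - 2 * (as.numeric(d$asa)) - 0.1 * (d$heart_rate - 90) +
    rnorm(nrow(d), 0, noise_sd)
  train <- cohort(d[1:3000, ], co$specs)
  test <- d[3001:4000, ]
  mdl <- fit_lab_imputer(train, "albumin", imputation_config())
  X <- build_design(test, mdl$fit$spec, mdl$fit$meta)$X
  pred <- drop(X %*% mdl$fit$coef)
  rmse <- sqrt(mean((pred - test$albumin)^2))
  expect_lt(abs(rmse / noise_sd - 1), 0.1)
  expect_lt(abs(mdl$fit$sigma / noise_sd - 1), 0.1)
})

test_that("lab draws respect observed values, determinism and degeneracy", {
  co <- test_cohorts()$missing[1:2500]
  mice_out <- run_mice(co, imputation_config(m_mice = 1, seed = 6))
  cd <- impute_categoricals(mice_out[[1]], imputation_config(seed = 6))
  mdl <- fit_lab_imputer(cd, "albumin", imputation_config())
  draws <- draw_lab_imputations(mdl, cd, k = 3, seed = 8)
  expect_length(draws, 3)
  obs <- !is.na(cd$data$albumin)
  for (dd in draws) {
    expect_identical(dd$data$albumin[obs], cd$data$albumin[obs])
    expect_false(anyNA(dd$data$albumin))
  }
  expect_false(identical(draws[[1]]$data$albumin, draws[[2]]$data$albumin))
  # no missing targets: k identical copies
  complete_cd <- cohort(cd$data[obs, ], cd$specs)
  complete_cd$mice_index <- 1L
  same <- draw_lab_imputations(mdl, complete_cd, k = 2, seed = 8)
  expect_identical(same[[1]]$data, same[[2]]$data)
  # degenerate posterior: zero covariance and zero residual scale
  mdl0 <- mdl
  mdl0$fit$cov[] <- 0
  mdl0$fit$sigma <- 0
  d0 <- draw_lab_imputations(mdl0, cd, k = 2, seed = 1)
  expect_identical(d0[[1]]$data$albumin, d0[[2]]$data$albumin)
})

test_that("coefficient uncertainty adds to residual variance in lab draws", {
  co <- test_cohorts()$missing[1:2500]
  mice_out <- run_mice(co, imputation_config(m_mice = 1, seed = 6))
  cd <- impute_categoricals(mice_out[[1]], imputation_config(seed = 6))
  mdl <- fit_lab_imputer(cd, "albumin", imputation_config())
  mdl_nocov <- mdl
  mdl_nocov$fit$cov[] <- 0
  k <- 84
  first_missing <- which(is.na(cd$data$albumin))[1]
  one_row <- cohort(cd$data[first_missing, , drop = FALSE], cd$specs)
  one_row$mice_index <- 1L
  v_full <- var(vapply(draw_lab_imputations(mdl, one_row, k, seed = 3),
                       function(x) x$data$albumin[1], numeric(1)))
  v_res <- var(vapply(draw_lab_imputations(mdl_nocov, one_row, k, seed = 3),
                      function(x) x$data$albumin[1], numeric(1)))
  expect_gte(v_full, v_res)
})

test_that("lab imputers round-trip through JSON", {
  co <- test_cohorts()$missing[1:2000]
  mice_out <- run_mice(co, imputation_config(m_mice = 1, seed = 2))
  cd <- impute_categoricals(mice_out[[1]], imputation_config(seed = 2))
  mdl <- suppressWarnings(fit_lab_imputer(cd, "lactate", imputation_config()))
  path <- withr::local_tempfile(fileext = ".json")
  write_lab_imputer(mdl, path)
  back <- read_lab_imputer(path)
  expect_equal(back$fit$coef, mdl$fit$coef, tolerance = 1e-12)
  expect_equal(back$fit$sigma, mdl$fit$sigma, tolerance = 1e-12)
  expect_true(back$log_scale)
  # identical predictions from the deserialized model
  rows <- cd$data[1:5, ]
  Xa <- build_design(rows, mdl$fit$spec, mdl$fit$meta)$X
  Xb <- build_design(rows, back$fit$spec, back$fit$meta)$X
  expect_equal(drop(Xb %*% back$fit$coef), drop(Xa %*% mdl$fit$coef),
               tolerance = 1e-10)
})
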