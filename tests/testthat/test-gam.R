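complete_frame <- function(n = 2000) {
  fixture(paste0("complete_frame_", n), {
    co <- test_cohorts()$full
    co$data[seq_len(n), ]
  })
}

test_that("design blocks have the required shapes", {
  d <- complete_frame(500)
  spec <- gam_spec(list(spline_term("sodium"), categorical_term("arrhythmia"),
                        categorical_term("asa"),
                        tensor_term("sodium", "arrhythmia")))
  meta <- fit_design_meta(d, spec)
  des <- build_design(d, spec, meta)
  cm <- des$col_map
  expect_length(cm[["spline sodium"]], 10)       # 10 B-spline bases
  expect_length(cm[["categorical arrhythmia"]], 1)  # base excluded
  expect_length(cm[["categorical asa"]], 4)      # 5 grades minus base
  expect_length(cm[["tensor sodium:arrhythmia"]], 10)
  expect_identical(colnames(des$X)[1], "(Intercept)")
})

test_that("spline bases form a partition of unity over the knot range", {
  d <- complete_frame(500)
  spec <- gam_spec(list(spline_term("sodium")))
  meta <- fit_design_meta(d, spec)
  B <- bspline_basis(seq(meta$sodium$range[1], meta$sodium$range[2],
                         length.out = 101),
                     meta$sodium$range)
  expect_equal(rowSums(B), rep(1, 101), tolerance = 1e-12)
  expect_true(all(B >= 0))
  # out-of-range inputs are clamped, so the property extends everywhere
  Bout <- bspline_basis(c(-1e6, 1e6), meta$sodium$range)
  expect_equal(rowSums(Bout), c(1, 1), tolerance = 1e-12)
})

test_that("missing covariates fail the design with a named error", {
  d <- complete_frame(50)
  d$sodium[7] <- NA
  spec <- gam_spec(list(spline_term("sodium")))
  meta <- fit_design_meta(complete_frame(500), spec)
  expect_error(build_design(d, spec, meta), "sodium")
  expect_error(build_design(d, spec, meta), "row 7")
})

test_that("unpenalized fit agrees with the logistic-regression oracle", {
  d <- complete_frame(500)
  spec <- gam_spec(list(categorical_term("arrhythmia", penalty = 0),
                        categorical_term("ct_performed", penalty = 0),
                        categorical_term("asa", penalty = 0),
                        tensor_term("ct_performed", "arrhythmia",
                                    penalty = c(0, 0))))
  fit <- fit_binomial_gam(d, spec)
  oracle <- glm(died ~ arrhythmia + ct_performed +
                  factor(asa, levels = as.character(1:5)) +
                  I(ct_performed * arrhythmia),
                data = d, family = binomial())
  # same raw columns in a different order: match by coefficient name
  expect_equal(length(fit$coef), length(coef(oracle)))
  mapped <- c("(Intercept)" = unname(coef(oracle)["(Intercept)"]),
              "arrhythmia.1" = unname(coef(oracle)["arrhythmia"]),
              "ct_performed.1" = unname(coef(oracle)["ct_performed"]),
              "asa.2" = unname(coef(oracle)[4]),
              "asa.3" = unname(coef(oracle)[5]),
              "asa.4" = unname(coef(oracle)[6]),
              "asa.5" = unname(coef(oracle)[7]),
              "ct_performed.1:arrhythmia.1" =
                unname(coef(oracle)["I(ct_performed * arrhythmia)"]))
  expect_lt(max(abs(fit$coef[names(mapped)] - mapped)), 1e-4)
})

test_that("the curvature penalty drives spline terms towards a line", {
  d <- complete_frame(2000)
  grid <- seq(130, 144, length.out = 40)
  curvature <- function(penalty) {
    spec <- gam_spec(list(spline_term("sodium", penalty = penalty)))
    fit <- fit_binomial_gam(d, spec)
    ref <- data.frame(sodium = grid, died = 0)
    eta <- gam_linpred(fit, ref)
    sum(diff(eta, differences = 2)^2)
  }
  c_small <- curvature(0.1)
  c_mid <- curvature(100)
  c_big <- curvature(1e7)
  # monotone decline, and essentially straight in the high-penalty limit
  expect_gte(c_small, c_mid)
  expect_gte(c_mid, c_big)
  expect_lt(c_big, 1e-6)
})

test_that("single-class outcomes are rejected", {
  d <- complete_frame(200)
  d$died <- 0
  expect_error(fit_binomial_gam(d, gam_spec(list(spline_term("sodium")))),
               "degenerate outcome")
})

test_that("parameter recovery: fitted logit surface tracks the generator", {
  tc <- test_cohorts()
  m <- fixture("recovery_model_small", {
    distrisk(tc$full, spec = recovery_spec(),
             imputation = imputation_config(m_mice = 1, k_lab = 1, seed = 1))
  })
  held <- generate_cohort(
    generator_config(n_cases = 1500, n_hospitals = 30, seed = 77))$cohort
  heldw <- apply_winsor(held, m$thresholds)
  eta_true <- tc$intercept + true_logit(heldw$data)
  eta_fit <- gam_linpred(m$pooled, heldw$data)
  # estimation noise at this cohort size; the sharp large-n bound is part
  # of the end-to-end acceptance checks
  expect_lt(mean(abs(eta_fit - eta_true)), 0.35)
  expect_true(m$converged)
})

test_that("Rubin's rules match hand arithmetic", {
  mk <- function(coef, var) {
    structure(list(coef = c(b = coef), cov = matrix(var, 1, 1),
                   spec = NULL, meta = NULL, col_map = list(b = 1L),
                   converged = TRUE), class = "fitted_gam")
  }
  pooled <- pool_fits(list(mk(0.2, 0.01), mk(0.4, 0.03)))
  expect_equal(unname(pooled$coef), 0.3)
  # within 0.02; between var of {0.2, 0.4} = 0.02; total 0.02 + 1.5 * 0.02
  expect_equal(pooled$cov[1, 1], 0.05)
  expect_equal(pooled$within_cov[1, 1], 0.02)
  expect_equal(pooled$between_cov[1, 1], 0.02)
})

test_that("pooling a single fit (or identical fits) is the identity", {
  mk <- function(coef, var) {
    structure(list(coef = c(b = coef), cov = matrix(var, 1, 1),
                   spec = NULL, meta = NULL, col_map = list(b = 1L),
                   converged = TRUE), class = "fitted_gam")
  }
  one <- pool_fits(list(mk(0.7, 0.2)))
  expect_equal(unname(one$coef), 0.7)
  expect_equal(one$cov[1, 1], 0.2)
  same <- pool_fits(list(mk(0.7, 0.2), mk(0.7, 0.2), mk(0.7, 0.2)))
  expect_equal(same$between_cov[1, 1], 0)
  expect_equal(same$cov[1, 1], 0.2)
  expect_error(pool_fits(list(mk(1, 1),
                              structure(list(coef = c(z = 1),
                                             cov = matrix(1, 1, 1)),
                                        class = "fitted_gam"))),
               "mismatched term maps")
})

test_that("pooled variances dominate mean within-fit variances", {
  m <- test_model()
  expect_true(all(diag(m$pooled$cov) >= diag(m$pooled$within_cov) - 1e-10))
})

test_that("posterior coefficient sampling is centred, seeded and sized", {
  pooled <- structure(list(coef = c(a = 1, b = -2),
                           cov = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2)),
                      class = "pooled_gam")
  draws <- sample_coefficients(pooled, 5, seed = 3)
  expect_equal(dim(draws), c(5L, 2L))
  expect_identical(draws, sample_coefficients(pooled, 5, seed = 3))
  big <- sample_coefficients(pooled, 1e5, seed = 4)
  se <- sqrt(diag(pooled$cov) / 1e5)
  expect_lt(max(abs(colMeans(big) - pooled$coef) / se), 3)
  expect_equal(unname(cov(big)), unname(pooled$cov), tolerance = 0.05)
  # zero covariance: all draws at the mean
  pooled0 <- pooled
  pooled0$cov[] <- 0
  d0 <- sample_coefficients(pooled0, 7, seed = 1)
  expect_true(all(d0[, 1] == 1 & d0[, 2] == -2))
})

test_that("backward elimination removes noise before signal", {
  d0 <- complete_frame(2000)
  base_terms <- list(spline_term("lactate"), categorical_term("asa"),
                     spline_term("sodium"))
  hits <- 0L
  for (s in 1:5) {
    d <- d0
    set.seed(100 + s)
    d$noise_var <- rnorm(nrow(d))
    specs <- default_variable_specs()
    specs$noise_var <- variable_spec("noise_var", "continuous")
    cand <- gam_spec(c(base_terms, list(spline_term("noise_var"))))
    red <- backward_eliminate(cand, d, n_remove = 1, specs = specs)
    if (identical(attr(red, "removed"), "noise_var")) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("backward elimination bookkeeping is exact", {
  d <- complete_frame(1500)
  cand <- gam_spec(list(spline_term("lactate"), spline_term("sodium"),
                        categorical_term("asa"), spline_term("age"),
                        categorical_term("arrhythmia"),
                        tensor_term("heart_rate", "arrhythmia"),
                        spline_term("heart_rate")))
  expect_length(spec_variables(cand), 6)
  red <- backward_eliminate(cand, d, n_remove = 2)
  expect_length(spec_variables(red), 4)
  expect_length(attr(red, "removed"), 2)
  # n_remove = 0 is the identity
  same <- backward_eliminate(cand, d, n_remove = 0)
  expect_equal(length(same$terms), length(cand$terms))
  expect_error(backward_eliminate(cand, d, n_remove = 6), "smaller")
  # dropping a tensor participant removes the whole interaction term
  no_arr <- drop_variable(cand, "arrhythmia")
  expect_false(any(vapply(no_arr$terms, function(t)
    "arrhythmia" %in% t$vars, logical(1))))
  expect_true("heart_rate" %in% spec_variables(no_arr))
})

test_that("partial dependence bands are nested and collapse without uncertainty", {
  m <- test_model()
  pd <- partial_dependence(m$pooled, "sodium", n_draws = 400, seed = 2)
  expect_equal(names(pd)[-(1:2)],
               c("lo95", "hi95", "lo70", "hi70", "lo45", "hi45",
                 "lo20", "hi20"))
  expect_true(all(pd$lo95 <= pd$lo70 & pd$lo70 <= pd$lo45 &
                    pd$lo45 <= pd$lo20))
  expect_true(all(pd$hi20 <= pd$hi45 & pd$hi45 <= pd$hi70 &
                    pd$hi70 <= pd$hi95))
  expect_true(all(pd$lo20 <= pd$median & pd$median <= pd$hi20))
  # discrete variable profiles over its levels
  pda <- partial_dependence(m$pooled, "asa", n_draws = 200, seed = 2)
  expect_equal(pda$value, as.character(1:5))
  # zero covariance: bands collapse onto the point curve
  p0 <- m$pooled
  p0$cov[] <- 0
  pd0 <- partial_dependence(p0, "sodium", n_draws = 50, seed = 1)
  expect_equal(pd0$lo95, pd0$hi95, tolerance = 1e-12)
  expect_equal(pd0$lo95, pd0$median, tolerance = 1e-12)
  expect_error(partial_dependence(m$pooled, "nonexistent"), "unknown variable")
})

test_that("predicted risks stay inside the unit interval", {
  m <- test_model()
  d <- test_holdout()$data
  # extreme inputs: far outside training range, still finite risks in (0,1)
  d$sodium <- 1e6
  d$lactate <- 1e6
  d$albumin[is.na(d$albumin)] <- 0
  d$lactate[is.na(d$lactate)] <- 1
  eta <- gam_linpred(m$pooled, d)
  p <- plogis(eta)
  expect_true(all(p > 0 & p < 1))
})
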