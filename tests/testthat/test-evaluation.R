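test_that("auroc equals the all-pairs concordance oracle", {
  set.seed(8)
  risks <- round(runif(500), 2)  # rounding forces ties
  outcomes <- rbinom(500, 1, risks)
  s <- score_predictions(risks, outcomes)
  expect_equal(s$auroc, auroc_oracle(risks, outcomes), tolerance = 1e-12)
  # perfect separation
  expect_equal(score_predictions(c(0.9, 0.8, 0.1, 0.2),
                                 c(1, 1, 0, 0))$auroc, 1)
})

test_that("brier, log loss and tjur match their direct formulas", {
  set.seed(9)
  risks <- runif(300, 0.01, 0.99)
  outcomes <- rbinom(300, 1, risks)
  s <- score_predictions(risks, outcomes)
  expect_equal(s$brier, mean((risks - outcomes)^2), tolerance = 1e-12)
  expect_equal(s$log_loss,
               -mean(outcomes * log(risks) + (1 - outcomes) * log(1 - risks)),
               tolerance = 1e-12)
  expect_equal(s$tjur,
               mean(risks[outcomes == 1]) - mean(risks[outcomes == 0]),
               tolerance = 1e-12)
  # closed forms at a constant prediction of one half
  half <- score_predictions(rep(0.5, 100), rep(c(0, 1), 50))
  expect_equal(half$brier, 0.25)
  expect_equal(half$log_loss, log(2))
  expect_error(score_predictions(rep(0.5, 10), rep(1, 10)), "one outcome class")
})

test_that("distribution scoring averages per-sample scores", {
  set.seed(10)
  y <- rbinom(200, 1, 0.3)
  col1 <- runif(200)
  col2 <- runif(200)
  s_avg <- score_distribution_model(cbind(col1, col2), y)
  s1 <- score_predictions(col1, y)
  s2 <- score_predictions(col2, y)
  expect_equal(s_avg$brier, (s1$brier + s2$brier) / 2, tolerance = 1e-12)
  expect_equal(s_avg$auroc, (s1$auroc + s2$auroc) / 2, tolerance = 1e-12)
  # identical columns (or a single column) degenerate to point scoring
  s_same <- score_distribution_model(cbind(col1, col1), y)
  expect_equal(s_same$log_loss, s1$log_loss, tolerance = 1e-12)
  s_one <- score_distribution_model(matrix(col1, ncol = 1), y)
  expect_equal(unlist(s_one), unlist(s1), tolerance = 1e-12)
  expect_error(score_distribution_model(cbind(col1, col2), y[1:100]),
               "shape error")
})

test_that("calibration error is near zero under perfect calibration", {
  set.seed(11)
  risks <- runif(20000, 0.01, 0.5)
  outcomes <- rbinom(20000, 1, risks)
  cc <- calibration_curve(risks, outcomes)
  expect_lt(cc$mace, 0.02)
  expect_equal(sum(cc$curve$weight), 1, tolerance = 1e-12)
})

test_that("known miscalibration is detected", {
  set.seed(12)
  risks <- runif(20000, 0.05, 0.45)
  outcomes <- rbinom(20000, 1, pmin(1, 2 * risks))
  cc <- calibration_curve(risks, outcomes)
  expect_gt(cc$mace, 0.05)
  expect_error(calibration_curve(rep(0.2, 500), rbinom(500, 1, 0.2)),
               "degenerate calibration")
  expect_error(calibration_curve(runif(50), rbinom(50, 1, 0.5)),
               "at least 100")
})

test_that("split plans group by hospital and are reproducible", {
  ids <- rep(sprintf("H%02d", 1:10), times = 1:10)
  plan <- make_split_plan(ids, n_splits = 120, train_frac = 0.8, seed = 5)
  expect_length(plan, 120)
  for (sp in plan[1:10]) {
    expect_length(sp$train_hospitals, 8)
    expect_length(sp$test_hospitals, 2)
    expect_length(intersect(sp$train_hospitals, sp$test_hospitals), 0)
    expect_setequal(c(sp$train_hospitals, sp$test_hospitals), unique(ids))
  }
  expect_identical(make_split_plan(ids, 120, 0.8, seed = 5)[[3]], plan[[3]])
  # splits differ across indices
  expect_gt(length(unique(vapply(plan, function(s)
    paste(s$test_hospitals, collapse = ","), character(1)))), 1)
  expect_error(make_split_plan(rep("H1", 5)), "at least 2 hospitals")
})

test_that("cross-validation aggregation uses percentile intervals", {
  per_split <- data.frame(split = rep(1:10, 2),
                          model = rep(c("baseline", "distrisk"), each = 10),
                          auroc = c(seq(0.1, 1.0, by = 0.1),
                                    seq(0.2, 1.1, by = 0.1)))
  rep1 <- aggregate_cv(per_split)
  med <- rep1$summary[rep1$summary$model == "baseline", "median"]
  expect_equal(med, pct_oracle(seq(0.1, 1, 0.1), 0.5))
  expect_equal(med, 0.55)
  lo <- rep1$summary[rep1$summary$model == "baseline", "p2.5"]
  expect_equal(lo, pct_oracle(seq(0.1, 1, 0.1), 0.025))
  # paired differences computed within split before aggregation
  d <- rep1$differences
  expect_equal(d$median, 0.1, tolerance = 1e-12)
  expect_equal(d$p2.5, 0.1, tolerance = 1e-12)
  # order invariance
  shuffled <- per_split[sample(nrow(per_split)), ]
  rep2 <- aggregate_cv(shuffled)
  expect_equal(rep2$summary$median, rep1$summary$median)
  expect_equal(rep2$differences$median, rep1$differences$median)
  # identical scores give zero-width intervals
  const <- data.frame(split = 1:5, model = "m", brier = 0.2)
  rc <- aggregate_cv(const)
  expect_equal(rc$summary$p2.5, rc$summary$p97.5)
})

test_that("medians always lie inside their percentile intervals", {
  set.seed(13)
  per_split <- data.frame(split = rep(1:30, 2),
                          model = rep(c("a", "b"), each = 30),
                          brier = runif(60), auroc = runif(60))
  rep1 <- aggregate_cv(per_split)
  expect_true(all(rep1$summary$median >= rep1$summary$p2.5))
  expect_true(all(rep1$summary$median <= rep1$summary$p97.5))
})
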