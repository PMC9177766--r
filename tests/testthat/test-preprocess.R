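test_that("winsor thresholds equal the sort-based percentile oracle", {
  co <- test_cohorts()$full
  th <- suppressWarnings(fit_winsor_thresholds(co))
  for (v in c("sodium", "heart_rate", "bun")) {
    vals <- co$data[[v]][!is.na(co$data[[v]])]
    expect_equal(th[[v]]$lower, pct_oracle(vals, 0.001), tolerance = 1e-12)
    expect_equal(th[[v]]$upper, pct_oracle(vals, 0.999), tolerance = 1e-12)
  }
  # values 1..1000 against the same oracle
  d <- co$data[1:1000, ]
  d$sodium <- as.numeric(1:1000)
  th2 <- suppressWarnings(fit_winsor_thresholds(cohort(d, co$specs)))
  expect_equal(th2$sodium$lower, pct_oracle(as.numeric(1:1000), 0.001))
  expect_equal(th2$sodium$upper, pct_oracle(as.numeric(1:1000), 0.999))
})

test_that("a constant variable yields equal lower and upper cuts", {
  co <- test_cohorts()$full
  d <- co$data[1:1200, ]
  d$potassium <- 4.2
  th <- suppressWarnings(fit_winsor_thresholds(cohort(d, co$specs)))
  expect_equal(th$potassium$lower, 4.2)
  expect_equal(th$potassium$upper, 4.2)
})

test_that("age is clamped from above only", {
  co <- test_cohorts()$full
  th <- suppressWarnings(fit_winsor_thresholds(co))
  expect_false(th$age$lower_active)
  expect_true(th$age$upper_active)
  d <- co$data[1:3, ]
  d$age <- c(18, 50, 108)
  out <- apply_winsor(cohort(d, co$specs), th)
  expect_equal(out$data$age[1], 18)  # below the 0.1 percentile, untouched
  expect_lte(out$data$age[3], th$age$upper)
})

test_that("winsorization clamps, is idempotent, and preserves missingness", {
  co <- test_cohorts()$missing
  th <- suppressWarnings(fit_winsor_thresholds(co))
  out <- apply_winsor(co, th)
  expect_identical(is.na(out$data$lactate), is.na(co$data$lactate))
  v <- out$data$sodium[!is.na(out$data$sodium)]
  expect_gte(min(v), th$sodium$lower)
  expect_lte(max(v), th$sodium$upper)
  again <- apply_winsor(out, th)
  expect_identical(again$data, out$data)
  # values already inside the cuts are untouched
  inside <- !is.na(co$data$sodium) & co$data$sodium > th$sodium$lower &
    co$data$sodium < th$sodium$upper
  expect_identical(out$data$sodium[inside], co$data$sodium[inside])
})

test_that("thresholds depend only on training cases", {
  co <- test_cohorts()$full
  train <- co[1:4000]
  th <- suppressWarnings(fit_winsor_thresholds(train))
  # perturbing non-training cases cannot change the thresholds
  d <- co$data
  d$sodium[4001:6000] <- 999
  th2 <- suppressWarnings(fit_winsor_thresholds(cohort(d, co$specs)[1:4000]))
  expect_equal(th2$sodium, th$sodium)
  # validation values beyond the training range clamp to the training cut
  v <- winsor_clamp(c(999, -999), th, "sodium")
  expect_equal(v, c(th$sodium$upper, th$sodium$lower))
})

test_that("winsor thresholds round-trip through JSON", {
  co <- test_cohorts()$full
  th <- suppressWarnings(fit_winsor_thresholds(co))
  path <- withr::local_tempfile(fileext = ".json")
  write_winsor_thresholds(th, path)
  back <- read_winsor_thresholds(path)
  expect_equal(lapply(back, unclass), lapply(th, unclass), tolerance = 1e-12)
})

test_that("ECG categories rationalise to any-arrhythmia", {
  expect_equal(binarize_ecg(c("sinus rhythm", "AF rate > 90", NA,
                              "AF rate < 90", "other arrhythmia")),
               c(0, 1, NA, 1, 1))
  expect_error(binarize_ecg("ventricular pacing"), "unknown ECG category")
})

test_that("indication consolidation keeps top-13, maps the rest to other", {
  top <- top13_indications()
  expect_equal(consolidate_indication(list("small_bowel_obstruction"), top),
               "small_bowel_obstruction")
  expect_equal(consolidate_indication(list("rare indication X"), top), "other")
  expect_true(is.na(consolidate_indication(list(character(0)), top)))
  # multiple simultaneous indications are deferred to imputation
  expect_true(is.na(consolidate_indication(
    list(c("perforation", "ischaemia")), top)))
  expect_error(consolidate_indication(list("x"), top[1:5]), "exactly 13")
})

test_that("missingness indicators flag exactly the absent labs", {
  co <- test_cohorts()$missing
  out <- add_missingness_indicators(co)
  expect_identical(out$data$lactate_missing, as.numeric(is.na(co$data$lactate)))
  expect_identical(out$data$albumin_missing, as.numeric(is.na(co$data$albumin)))
  expect_false(anyNA(out$data$lactate_missing))
  expect_lt(abs(mean(out$data$lactate_missing) - 0.364), 0.02)
  # fully observed cohort: all indicators zero
  full <- add_missingness_indicators(test_cohorts()$full)
  expect_true(all(full$data$lactate_missing == 0))
})

test_that("implausible values are redacted to missing", {
  co <- test_cohorts()$full
  d <- co$data[1:10, ]
  d$potassium[1] <- 99
  d$sodium[2] <- 20
  out <- redact_implausible(cohort(d, co$specs))
  expect_true(is.na(out$data$potassium[1]))
  expect_true(is.na(out$data$sodium[2]))
  expect_identical(out$data$potassium[-1], d$potassium[-1])
})
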