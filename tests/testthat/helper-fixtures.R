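# shared fixtures, built once per test session

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# reduced model spec matching the generator's risk function
recovery_spec <- function() {
  gam_spec(list(
    spline_term("sodium"), spline_term("lactate"), spline_term("age"),
    spline_term("heart_rate"), spline_term("albumin"),
    categorical_term("asa"), categorical_term("arrhythmia"),
    tensor_term("heart_rate", "arrhythmia")
  ))
}

# recovery spec plus the lab missingness indicators, for cohorts with
# injected missingness
test_spec <- function() {
  gam_spec(list(
    spline_term("sodium"), spline_term("lactate"), spline_term("albumin"),
    spline_term("age"), spline_term("heart_rate"),
    categorical_term("asa"), categorical_term("arrhythmia"),
    categorical_term("lactate_missing"), categorical_term("albumin_missing"),
    tensor_term("heart_rate", "arrhythmia")
  ))
}

# medium cohort with injected missingness, plus its fully observed original
test_cohorts <- function() {
  fixture("test_cohorts", {
    g <- generator_config(n_cases = 6000, n_hospitals = 30, seed = 1)
    gen <- generate_cohort(g)
    list(config = g, full = gen$cohort, true_risks = gen$true_risks,
         intercept = gen$intercept,
         missing = inject_missingness(gen$cohort, g))
  })
}

# small fitted model (m = 2 x k = 2) on 24 of the 30 hospitals
test_model <- function() {
  fixture("test_model", {
    co <- test_cohorts()$missing
    train <- co[co$data$hospital_id <= "H024"]
    distrisk(train, spec = test_spec(),
             imputation = imputation_config(m_mice = 2, k_lab = 2, seed = 1))
  })
}

# held-out cases from the remaining hospitals, routine-complete so they can
# be predicted prospectively
test_holdout <- function() {
  fixture("test_holdout", {
    co <- test_cohorts()$missing
    test <- co[co$data$hospital_id > "H024"]
    ok <- rowSums(is.na(test$data[, routine_covariates(), drop = FALSE])) == 0L
    test[ok]
  })
}

# sort-based percentile oracle (linear interpolation between order stats)
pct_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1L))
}

# all-pairs concordance oracle for the AUROC
auroc_oracle <- function(risks, outcomes) {
  pos <- risks[outcomes == 1]
  neg <- risks[outcomes == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
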