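# Cholesky solve with escalating jitter; A must be symmetric.
chol_factor <- function(A) {
  p <- nrow(A)
  jit <- 0
  for (try in 0:8) {
    R <- tryCatch(chol(A + diag(jit, p)), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- if (jit == 0) 1e-10 * max(1, mean(diag(A))) else jit * 100
  }
  stop("numeric error: matrix not positive definite after jitter")
}

chol_solve <- function(R, b) backsolve(R, forwardsolve(t(R), b))

as_case_data <- function(x) {
  if (inherits(x, "cohort")) x$data else as.data.frame(x)
}

#' Fit the penalized binomial-logit GAM on one completed dataset
#'
#' Penalized maximum likelihood by iteratively reweighted least squares.
#' Each spline term is shrunk by a second-difference (curvature) penalty on
#' its B-spline coefficients, each discrete term by an L2 penalty on its
#' dummy coefficients, and tensor terms by the Kronecker sum of their
#' marginal penalties. The coefficient covariance returned is the inverse
#' of the penalized information matrix, which doubles as the approximate
#' (Gaussian) posterior over the coefficients.
#'
#' @param data A completed dataset (cohort or data.frame) with no missing
#'   values among spec covariates; both outcome classes must be present.
#' @param spec A `"gam_spec"`.
#' @param meta Optional `"design_meta"`; fitted from `data` when `NULL`.
#' @param specs Variable specs.
#' @param outcome Outcome column name (default `"died"`).
#' @param max_iter,tol IRLS iteration cap and relative penalized
#'   log-likelihood convergence tolerance.
#' @return A `"fitted_gam"`: `coef`, `cov`, `col_map`, `spec`, `meta`,
#'   `loglik`, `penalized_loglik`, `edf`, `deviance`, `n`, `converged`.
#' @export
fit_binomial_gam <- function(data, spec, meta = NULL,
                             specs = default_variable_specs(),
                             outcome = "died", max_iter = 100L, tol = 1e-6) {
  d <- as_case_data(data)
  y <- d[[outcome]]
  if (is.null(y) || anyNA(y)) stop("outcome '", outcome, "' missing")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: only one class present")
  if (is.null(meta)) meta <- fit_design_meta(d, spec, specs)
  des <- build_design(d, spec, meta)
  X <- des$X
  n <- nrow(X)
  p <- ncol(X)
  # identifiability loading: the curvature penalty's null space aliases each
  # spline block's constant direction with the intercept; a tiny L2 ridge
  # pins the decomposition without measurably changing the fitted surface
  P <- des$penalty + diag(1e-6, p)

  penalized_ll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    list(eta = eta, mu = mu,
         pll = sum(y * log(mu) + (1 - y) * log(1 - mu)) -
           0.5 * drop(crossprod(beta, P %*% beta)))
  }
  mu <- rep(mean(y), n)
  eta <- stats::qlogis(mu)
  beta <- numeric(p)
  pll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w) + P
    b <- crossprod(X, w * z)
    R <- chol_factor(A)
    cand <- drop(chol_solve(R, b))
    st <- penalized_ll(cand)
    # step-halving: plain IRLS is not monotone in the penalized likelihood
    halvings <- 0L
    while (is.finite(pll_old) && st$pll < pll_old && halvings < 30L) {
      cand <- (cand + beta) / 2
      st <- penalized_ll(cand)
      halvings <- halvings + 1L
    }
    beta <- cand
    eta <- st$eta
    mu <- st$mu
    pll <- st$pll
    if (is.finite(pll_old) && abs(pll - pll_old) < tol * (abs(pll) + 0.1)) {
      converged <- TRUE
      break
    }
    pll_old <- pll
  }
  if (!converged)
    warning("IRLS did not converge within ", max_iter, " iterations",
            call. = FALSE)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X, X * w)
  A <- info + P
  R <- chol_factor(A)
  cov <- chol2inv(R)
  edf <- sum(diag(cov %*% info))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, cov = cov, col_map = des$col_map, spec = spec,
                 meta = meta, loglik = ll,
                 penalized_loglik = ll - 0.5 * drop(crossprod(beta, P %*% beta)),
                 edf = edf, deviance = -2 * ll, n = n, converged = converged),
            class = "fitted_gam")
}

#' @export
print.fitted_gam <- function(x, ...) {
  cat("<fitted_gam> binomial-logit, ", length(x$coef), " coefficients, n = ",
      x$n, "\n  log-likelihood ", format(x$loglik), ", edf ",
      format(round(x$edf, 1)), ", converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Evaluate the linear predictor of a fitted or pooled GAM
#' @param object A `"fitted_gam"` or `"pooled_gam"`.
#' @param newdata Data.frame with no missing values among spec covariates.
#' @param coefficients Optional coefficient vector/matrix (draws in rows)
#'   overriding the fitted coefficients.
#' @return Vector of logits, or a cases-by-draws matrix when `coefficients`
#'   is a matrix.
#' @export
gam_linpred <- function(object, newdata, coefficients = NULL) {
  des <- build_design(as_case_data(newdata), object$spec, object$meta)
  if (is.null(coefficients)) coefficients <- object$coef
  if (is.matrix(coefficients)) des$X %*% t(coefficients)
  else drop(des$X %*% coefficients)
}

#' Fit a Gaussian GAM by penalized least squares
#'
#' Used for the lactate/albumin imputation sub-models. Closed-form ridge
#' solution; residual variance uses the effective degrees of freedom;
#' coefficient covariance is `sigma^2 (X'X + P)^{-1}`.
#'
#' @param data Completed dataset with the target observed in every used row.
#' @param spec A `"gam_spec"` for the covariates (link ignored).
#' @param target Name of the continuous response column.
#' @param meta Optional design meta.
#' @param specs Variable specs.
#' @return A `"fitted_gam"`-like list with `sigma` (residual scale).
#' @export
fit_gaussian_gam <- function(data, spec, target, meta = NULL,
                             specs = default_variable_specs()) {
  d <- as_case_data(data)
  y <- d[[target]]
  if (anyNA(y)) stop("fit_gaussian_gam: target contains missing values")
  if (stats::sd(y) == 0) stop("fit error: zero-variance target '", target, "'")
  if (is.null(meta)) meta <- fit_design_meta(d, spec, specs)
  des <- build_design(d, spec, meta)
  X <- des$X
  P <- des$penalty + diag(1e-6, ncol(X))
  XtX <- crossprod(X)
  A <- XtX + P
  R <- chol_factor(A)
  beta <- drop(chol_solve(R, crossprod(X, y)))
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  Ainv <- chol2inv(R)
  edf <- sum(diag(Ainv %*% XtX))
  sigma2 <- rss / max(nrow(X) - edf, 1)
  names(beta) <- colnames(X)
  cov <- sigma2 * Ainv
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, cov = cov, sigma = sqrt(sigma2),
                 col_map = des$col_map, spec = spec, meta = meta,
                 edf = edf, n = nrow(X), converged = TRUE),
            class = c("fitted_gaussian_gam", "fitted_gam"))
}

scale_spec_penalty <- function(spec, multiplier) {
  gam_spec(lapply(spec$terms, function(t) {
    t$penalty <- t$penalty * multiplier
    t
  }))
}

#' Select a global penalty multiplier by generalized cross-validation
#'
#' Scales every term's default penalty weight by a common multiplier and
#' picks the one minimizing the deviance-based GCV score
#' `n * deviance / (n - edf)^2`. Per-term weights can still be overridden
#' on the term specs; this tunes only their common scale.
#'
#' @param data Completed training dataset.
#' @param spec Base `"gam_spec"` whose weights act as relative weights.
#' @param multipliers Candidate multipliers.
#' @param ... Passed to [fit_binomial_gam()].
#' @return List with `multiplier`, `spec` (rescaled), `gcv` (named scores).
#' @export
select_penalty_gcv <- function(data, spec, multipliers = 10^seq(-2, 2), ...) {
  scores <- vapply(multipliers, function(m) {
    fit <- fit_binomial_gam(data, scale_spec_penalty(spec, m), ...)
    fit$n * fit$deviance / (fit$n - fit$edf)^2
  }, numeric(1L))
  names(scores) <- as.character(multipliers)
  best <- multipliers[which.min(scores)]
  list(multiplier = best, spec = scale_spec_penalty(spec, best), gcv = scores)
}
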