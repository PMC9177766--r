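#' Pool fitted GAMs across imputed datasets with Rubin's rules
#'
#' Pooled coefficients are the mean of the per-dataset coefficients; the
#' pooled covariance is the mean within-fit covariance plus
#' `(1 + 1/m)` times the between-fit coefficient covariance, so pooled
#' variances are never smaller than the average within-fit variances.
#'
#' @param fits List of `"fitted_gam"` objects with identical term maps.
#' @return A `"pooled_gam"`: `coef`, `cov`, `m`, `within_cov`,
#'   `between_cov`, plus the shared `spec`, `meta`, `col_map`.
#' @export
pool_fits <- function(fits) {
  if (length(fits) < 1L) stop("pool_fits needs at least one fit")
  maps <- lapply(fits, function(f) names(f$coef))
  if (!all(vapply(maps, identical, logical(1L), maps[[1L]])))
    stop("pooling error: fits have mismatched term maps")
  m <- length(fits)
  coefs <- do.call(rbind, lapply(fits, `[[`, "coef"))
  qbar <- colMeans(coefs)
  ubar <- Reduce(`+`, lapply(fits, `[[`, "cov")) / m
  if (m > 1L) {
    dev <- sweep(coefs, 2L, qbar)
    between <- crossprod(dev) / (m - 1)
  } else {
    between <- ubar * 0
  }
  total <- ubar + (1 + 1 / m) * between
  structure(list(coef = qbar, cov = total, m = m, within_cov = ubar,
                 between_cov = between, spec = fits[[1L]]$spec,
                 meta = fits[[1L]]$meta, col_map = fits[[1L]]$col_map,
                 converged = all(vapply(fits, `[[`, logical(1L), "converged"))),
            class = "pooled_gam")
}

#' @export
print.pooled_gam <- function(x, ...) {
  cat("<pooled_gam> ", length(x$coef), " coefficients pooled over m = ",
      x$m, " imputed-dataset fits (Rubin's rules)\n", sep = "")
  invisible(x)
}

#' Draw coefficient vectors from the approximate posterior
#'
#' Multivariate normal draws centred on the pooled coefficients with the
#' pooled covariance. The covariance is symmetrized and, if needed,
#' jittered minimally to obtain a Cholesky factor.
#'
#' @param pooled A `"pooled_gam"` (or `"fitted_gam"`).
#' @param n_draws Number of draws.
#' @param seed Integer seed; draws are deterministic given it.
#' @return `n_draws` x p matrix of coefficient draws.
#' @export
sample_coefficients <- function(pooled, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- (pooled$cov + t(pooled$cov)) / 2
  p <- ncol(V)
  if (all(abs(V) < 1e-300)) {
    draws <- matrix(rep(pooled$coef, each = n_draws), n_draws, p)
  } else {
    R <- chol_factor(V)
    Z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
    draws <- Z %*% R
    draws <- sweep(draws, 2L, pooled$coef, `+`)
  }
  colnames(draws) <- names(pooled$coef)
  draws
}

term_columns_for_variable <- function(col_map, var) {
  hit <- vapply(names(col_map), function(nm) {
    if (nm == "(Intercept)") return(FALSE)
    vars <- strsplit(sub("^\\S+ ", "", nm), ":", fixed = TRUE)[[1L]]
    var %in% vars
  }, logical(1L))
  sort(unlist(col_map[hit], use.names = FALSE))
}

#' Backward elimination of weakly associated candidate variables
#'
#' At each step, computes for every candidate variable a joint Wald
#' chi-square over all of its design columns (including those of any tensor
#' term it participates in) and removes the variable with the largest
#' p-value, i.e. the one whose removal least degrades the penalized fit.
#' Deterministic given the data.
#'
#' @param candidates A `"gam_spec"` of candidate terms.
#' @param data Complete development dataset (e.g. the first completed
#'   dataset from imputation).
#' @param n_remove How many variables to remove.
#' @param specs Variable specs.
#' @param outcome Outcome column name.
#' @return The reduced `"gam_spec"`; removed variable names (in removal
#'   order) are attached as attribute `"removed"`.
#' @export
backward_eliminate <- function(candidates, data, n_remove,
                               specs = default_variable_specs(),
                               outcome = "died") {
  vars <- spec_variables(candidates)
  if (n_remove >= length(vars))
    stop("n_remove must be smaller than the number of candidate variables")
  spec <- candidates
  removed <- character(0)
  for (step in seq_len(n_remove)) {
    fit <- fit_binomial_gam(data, spec, specs = specs, outcome = outcome)
    vars <- spec_variables(spec)
    pvals <- vapply(vars, function(v) {
      cols <- term_columns_for_variable(fit$col_map, v)
      b <- fit$coef[cols]
      V <- fit$cov[cols, cols, drop = FALSE]
      stat <- drop(crossprod(b, chol_solve(chol_factor(V), b)))
      stats::pchisq(stat, df = length(cols), lower.tail = FALSE)
    }, numeric(1L))
    weakest <- vars[which.max(pvals)]
    spec <- drop_variable(spec, weakest)
    removed <- c(removed, weakest)
  }
  attr(spec, "removed") <- removed
  spec
}

#' Partial dependence of predicted risk with nested confidence bands
#'
#' Profiles predicted mortality risk over one covariate with every other
#' covariate held at its reference value (continuous at the training
#' median, discrete at the base category). Per grid point, risk quantiles
#' across posterior coefficient draws form nested bands at the requested
#' confidence levels (defaults 95, 70, 45 and 20%).
#'
#' @param pooled A `"pooled_gam"`.
#' @param variable Covariate to profile.
#' @param grid Optional grid of values (continuous) or category labels;
#'   defaults to 50 equally spaced points over the training range, or all
#'   levels for discrete variables.
#' @param confidence_levels Band levels in percent, e.g. `c(95, 70, 45, 20)`.
#' @param n_draws Number of coefficient draws.
#' @param seed Seed for the draws.
#' @return A data.frame with `value`, `median`, and `lo<level>` / `hi<level>`
#'   columns per confidence level.
#' @export
partial_dependence <- function(pooled, variable, grid = NULL,
                               confidence_levels = c(95, 70, 45, 20),
                               n_draws = 1000L, seed = 1L) {
  m <- pooled$meta[[variable]]
  if (is.null(m)) stop("unknown variable '", variable, "'")
  if (is.null(grid)) {
    grid <- if (m$kind == "continuous")
      seq(m$range[1L], m$range[2L], length.out = 50L)
    else m$levels
  }
  ref <- lapply(pooled$meta, function(mm) {
    if (mm$kind == "continuous") mm$median else mm$base
  })
  newdata <- as.data.frame(ref, stringsAsFactors = FALSE)
  newdata <- newdata[rep(1L, length(grid)), , drop = FALSE]
  newdata[[variable]] <- grid
  draws <- sample_coefficients(pooled, n_draws, seed)
  risks <- stats::plogis(gam_linpred(pooled, newdata, draws))
  out <- data.frame(value = grid, median = apply(risks, 1L, stats::median))
  for (lev in sort(confidence_levels, decreasing = TRUE)) {
    a <- (1 - lev / 100) / 2
    q <- apply(risks, 1L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    out[[paste0("lo", lev)]] <- q[1L, ]
    out[[paste0("hi", lev)]] <- q[2L, ]
  }
  out
}
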