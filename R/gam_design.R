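#' B-spline basis with linearly spaced knots
#'
#' Builds `n_basis` B-spline basis functions of the given polynomial degree
#' over `range`, with interior knots equally spaced and boundary knots
#' replicated to full multiplicity. Inputs are clamped to the knot range
#' before evaluation (consistent with Winsorization), so the basis rows sum
#' to one everywhere.
#'
#' @param x Numeric vector.
#' @param range Length-2 numeric training range.
#' @param n_basis Number of basis functions (default 10).
#' @param degree Polynomial degree (default 2).
#' @return Matrix with `length(x)` rows and `n_basis` columns.
#' @export
bspline_basis <- function(x, range, n_basis = 10L, degree = 2L) {
  ord <- degree + 1L
  n_interior <- n_basis - ord
  if (n_interior < 0L) stop("n_basis must be at least degree + 1")
  interior <- if (n_interior > 0L)
    seq(range[1L], range[2L], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  else numeric(0)
  knots <- c(rep(range[1L], ord), interior, rep(range[2L], ord))
  xc <- pmin(pmax(x, range[1L]), range[2L])
  splines::splineDesign(knots, xc, ord = ord)
}

second_diff_penalty <- function(k) {
  if (k < 3L) return(diag(k) * 0)
  D <- diff(diag(k), differences = 2L)
  crossprod(D)
}

#' Declare a penalized spline term
#' @param var Continuous variable name.
#' @param n_basis Number of B-spline bases (default 10).
#' @param degree Spline degree (default 2).
#' @param penalty Second-derivative (curvature) penalty weight.
#' @return A `"gam_term"`.
#' @export
spline_term <- function(var, n_basis = 10L, degree = 2L, penalty = 1) {
  stopifnot(penalty >= 0)
  structure(list(kind = "spline", vars = var, n_basis = as.integer(n_basis),
                 degree = as.integer(degree), penalty = penalty),
            class = "gam_term")
}

#' Declare a dummy-coded categorical (or binary) term
#'
#' Categories are encoded with the base category excluded to avoid the
#' dummy-variable trap; inter-category differences are shrunk by an L2
#' penalty on the dummy coefficients.
#'
#' @param var Variable name (binary, ordinal or nominal).
#' @param penalty L2 penalty weight.
#' @return A `"gam_term"`.
#' @export
categorical_term <- function(var, penalty = 1) {
  stopifnot(penalty >= 0)
  structure(list(kind = "categorical", vars = var, penalty = penalty),
            class = "gam_term")
}

#' Declare a tensor-product interaction term
#'
#' The term's columns are all pairwise products of the two marginal bases
#' (B-spline basis for continuous inputs, base-excluded dummies for
#' discrete ones). The penalty is the Kronecker sum of the marginal
#' penalties: curvature along each continuous margin, L2 along each
#' discrete margin.
#'
#' @param var1,var2 The two interacting variable names.
#' @param n_basis,degree Marginal B-spline settings for continuous inputs.
#' @param penalty Length-2 weights for the two marginal penalties.
#' @return A `"gam_term"`.
#' @export
tensor_term <- function(var1, var2, n_basis = 10L, degree = 2L,
                        penalty = c(1, 1)) {
  stopifnot(all(penalty >= 0), length(penalty) == 2L)
  structure(list(kind = "tensor", vars = c(var1, var2),
                 n_basis = as.integer(n_basis), degree = as.integer(degree),
                 penalty = penalty),
            class = "gam_term")
}

#' Assemble a GAM model specification
#'
#' An ordered list of terms plus the binomial-logit link (fixed). Every
#' covariate must appear in at least one term; duplicate terms are
#' rejected.
#'
#' @param terms List of `"gam_term"` objects.
#' @return A `"gam_spec"`.
#' @export
gam_spec <- function(terms) {
  ids <- vapply(terms, function(t) paste(t$kind, paste(t$vars, collapse = ":")),
                character(1L))
  if (anyDuplicated(ids)) stop("duplicate terms in gam_spec")
  structure(list(terms = terms, link = "logit", family = "binomial"),
            class = "gam_spec")
}

#' @export
print.gam_spec <- function(x, ...) {
  cat("<gam_spec> binomial-logit,", length(x$terms), "terms\n")
  for (t in x$terms)
    cat("  ", t$kind, ": ", paste(t$vars, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Covariates referenced by a spec
#' @param spec A `"gam_spec"`.
#' @return Character vector of unique variable names.
#' @export
spec_variables <- function(spec) {
  unique(unlist(lapply(spec$terms, `[[`, "vars")))
}

#' Drop every term referencing a variable
#' @param spec A `"gam_spec"`.
#' @param var Variable name to remove (tensor terms referencing it go too).
#' @return The reduced `"gam_spec"`.
#' @export
drop_variable <- function(spec, var) {
  keep <- vapply(spec$terms, function(t) !var %in% t$vars, logical(1L))
  if (!any(keep)) stop("removing '", var, "' would empty the model spec")
  gam_spec(spec$terms[keep])
}

#' The full default model specification
#'
#' Penalized spline terms (10 second-degree B-splines, linear knots) for
#' each continuous covariate, L2-penalized dummy blocks for the discrete
#' covariates and the two lab missingness indicators, and the six
#' tensor-product interactions: heart rate x arrhythmia, BUN x creatinine,
#' cardiovascular x respiratory status, and CT-performed crossed with each
#' of peritoneal soiling, malignancy and surgical indication.
#'
#' @param include_albumin Set `FALSE` for the albumin-free sensitivity
#'   variant.
#' @param include_missingness_indicators Set `FALSE` to drop the
#'   lactate/albumin missingness indicator covariates.
#' @param spline_penalty,categorical_penalty Default penalty weights.
#' @return A `"gam_spec"`.
#' @export
default_gam_spec <- function(include_albumin = TRUE,
                             include_missingness_indicators = TRUE,
                             spline_penalty = 1,
                             categorical_penalty = 1) {
  cont <- c("age", "heart_rate", "systolic_bp", "sodium", "potassium",
            "wcc", "creatinine", "bun", "lactate", "gcs")
  if (include_albumin) cont <- c(cont, "albumin")
  cats <- c("asa", "cardio_status", "resp_status", "arrhythmia",
            "ct_performed", "soiling", "malignancy", "indication")
  if (include_missingness_indicators) {
    cats <- c(cats, "lactate_missing")
    if (include_albumin) cats <- c(cats, "albumin_missing")
  }
  terms <- c(
    lapply(cont, spline_term, penalty = spline_penalty),
    lapply(cats, categorical_term, penalty = categorical_penalty),
    list(
      tensor_term("heart_rate", "arrhythmia",
                  penalty = c(spline_penalty, categorical_penalty)),
      tensor_term("bun", "creatinine",
                  penalty = c(spline_penalty, spline_penalty)),
      tensor_term("cardio_status", "resp_status",
                  penalty = c(categorical_penalty, categorical_penalty)),
      tensor_term("ct_performed", "soiling",
                  penalty = c(categorical_penalty, categorical_penalty)),
      tensor_term("ct_performed", "malignancy",
                  penalty = c(categorical_penalty, categorical_penalty)),
      tensor_term("ct_performed", "indication",
                  penalty = c(categorical_penalty, categorical_penalty))
    )
  )
  gam_spec(terms)
}

#' Fit design metadata from training data
#'
#' Records, per covariate, what the design matrix needs to be rebuilt
#' identically at prediction time: the training range (spline knot range)
#' and median of continuous variables, and the observed category levels of
#' discrete variables (ordered per the variable specs).
#'
#' @param data Training data.frame (no missing values among spec covariates).
#' @param spec A `"gam_spec"`.
#' @param specs Variable specs.
#' @return A `"design_meta"` list keyed by variable.
#' @export
fit_design_meta <- function(data, spec, specs = default_variable_specs()) {
  meta <- list()
  for (v in spec_variables(spec)) {
    kind <- specs[[v]]$kind
    if (kind == "continuous") {
      x <- data[[v]]
      if (anyNA(x)) stop("design meta: missing values in '", v, "'")
      meta[[v]] <- list(kind = "continuous", range = range(x),
                        median = stats::median(x))
    } else {
      levs <- specs[[v]]$categories
      base <- specs[[v]]$base
      meta[[v]] <- list(kind = "discrete", levels = levs, base = base)
    }
  }
  structure(meta, class = "design_meta")
}

marginal_basis <- function(data, var, meta, term) {
  m <- meta[[var]]
  if (m$kind == "continuous") {
    B <- bspline_basis(data[[var]], m$range, term$n_basis, term$degree)
    colnames(B) <- paste0(var, ".s", seq_len(ncol(B)))
    P <- second_diff_penalty(ncol(B))
  } else {
    lev <- setdiff(m$levels, m$base)
    x <- as.character(data[[var]])
    bad <- !is.na(x) & !x %in% m$levels
    if (any(bad)) stop("unknown category in '", var, "': ",
                       paste(unique(x[bad]), collapse = ", "))
    B <- matrix(0, nrow(data), length(lev),
                dimnames = list(NULL, paste0(var, ".", lev)))
    for (j in seq_along(lev)) B[, j] <- as.numeric(x == lev[j])
    P <- diag(length(lev))
  }
  list(B = B, P = P)
}

#' Build the penalized design matrix
#'
#' Columns are laid out term by term in spec order after a leading
#' intercept: spline blocks, base-excluded dummy blocks, and tensor blocks
#' formed as all column-wise products of the two marginal bases. The
#' returned penalty matrix carries each term's weighted penalty in its
#' block (zero for the intercept).
#'
#' @param data Data.frame with no missing values among spec covariates.
#' @param spec A `"gam_spec"`.
#' @param meta A `"design_meta"` fitted on training data.
#' @return List with `X` (design matrix, intercept first), `penalty`
#'   (matching block-diagonal penalty matrix) and `col_map` (named list of
#'   column indices per term, `"(Intercept)"` included).
#' @export
build_design <- function(data, spec, meta) {
  for (v in spec_variables(spec)) {
    if (is.null(data[[v]]))
      stop("design error: variable '", v, "' absent from data")
    miss <- which(is.na(data[[v]]))
    if (length(miss) > 0L)
      stop("design error: missing value of '", v, "' (first at row ",
           miss[1L], ")")
  }
  n <- nrow(data)
  blocks <- list(matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)")))
  pens <- list(matrix(0, 1L, 1L))
  col_map <- list("(Intercept)" = 1L)
  offset <- 1L
  for (t in spec$terms) {
    if (t$kind == "tensor") {
      m1 <- marginal_basis(data, t$vars[1L], meta, t)
      m2 <- marginal_basis(data, t$vars[2L], meta, t)
      k1 <- ncol(m1$B); k2 <- ncol(m2$B)
      B <- m1$B[, rep(seq_len(k1), each = k2), drop = FALSE] *
        m2$B[, rep(seq_len(k2), times = k1), drop = FALSE]
      colnames(B) <- paste(colnames(m1$B)[rep(seq_len(k1), each = k2)],
                           colnames(m2$B)[rep(seq_len(k2), times = k1)],
                           sep = ":")
      P <- t$penalty[1L] * kronecker(m1$P, diag(k2)) +
        t$penalty[2L] * kronecker(diag(k1), m2$P)
    } else {
      mb <- marginal_basis(data, t$vars[1L], meta, t)
      B <- mb$B
      P <- t$penalty * mb$P
    }
    blocks[[length(blocks) + 1L]] <- B
    pens[[length(pens) + 1L]] <- P
    idx <- offset + seq_len(ncol(B))
    col_map[[paste(t$kind, paste(t$vars, collapse = ":"))]] <- idx
    offset <- offset + ncol(B)
  }
  X <- do.call(cbind, blocks)
  p <- ncol(X)
  penalty <- matrix(0, p, p)
  off <- 0L
  for (b in seq_along(blocks)) {
    k <- ncol(blocks[[b]])
    penalty[off + seq_len(k), off + seq_len(k)] <- pens[[b]]
    off <- off + k
  }
  list(X = X, penalty = penalty, col_map = col_map)
}
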