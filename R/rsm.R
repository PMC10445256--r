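# Response-surface-methodology baseline: face-centred central composite
# designs and full-quadratic least-squares surfaces with grid-search optimum
# prediction. A single-iteration comparator for the sequential strategies.

#' Face-centred central composite design
#'
#' Factorial core (full two-level factorial for up to 4 factors, a
#' resolution-V+ half fraction for 5 or more), two axial points per factor at
#' the faces, and replicated center points, in coded {-1, 0, +1} levels. The
#' run counts reproduce the classic sizes: 29 runs for 5 factors and 47 runs
#' for 6 factors (with 3 center points).
#'
#' @param n_factors number of factors, `>= 2`.
#' @param center_points center replicates, `>= 1` (default 3).
#' @return object of class `ccd_design`: coded run matrix `runs`, plus
#'   `n_factors`, `core` and `center_points`.
#' @examples
#' nrow(ccd_design(5)$runs)  # 29
#' @export
ccd_design <- function(n_factors, center_points = 3L) {
  n_factors <- as.integer(n_factors)
  center_points <- as.integer(center_points)
  if (n_factors < 2L)
    stop_reactbo("need at least 2 factors", "reactbo_bad_request")
  if (center_points < 1L)
    stop_reactbo("need at least 1 center point", "reactbo_bad_request")
  half <- n_factors >= 5L
  base_k <- if (half) n_factors - 1L else n_factors
  core <- as.matrix(expand.grid(rep(list(c(-1, 1)), base_k),
                                KEEP.OUT.ATTRS = FALSE))
  if (half) core <- cbind(core, apply(core, 1L, prod))  # generator: last = product
  colnames(core) <- paste0("x", seq_len(n_factors))
  axial <- matrix(0, 2L * n_factors, n_factors,
                  dimnames = list(NULL, colnames(core)))
  for (j in seq_len(n_factors)) {
    axial[2L * j - 1L, j] <- -1
    axial[2L * j, j] <- 1
  }
  center <- matrix(0, center_points, n_factors,
                   dimnames = list(NULL, colnames(core)))
  runs <- rbind(core, axial, center)
  rownames(runs) <- NULL
  structure(list(runs = runs, n_factors = n_factors,
                 core = if (half) "half-fraction" else "full",
                 center_points = center_points),
            class = "ccd_design")
}

#' @export
print.ccd_design <- function(x, ...) {
  cat(sprintf("Face-centred CCD: %d factors, %s core, %d center point(s), %d runs\n",
              x$n_factors, x$core, x$center_points, nrow(x$runs)))
  invisible(x)
}

#' Decode a coded design into native units
#'
#' Maps coded levels -1/0/+1 to lower/mid/upper of each design-space variable.
#'
#' @param design a [ccd_design()].
#' @param space a [design_space()] with as many variables as design factors.
#' @return matrix of conditions in native units.
#' @export
decode_design <- function(design, space) {
  stopifnot(inherits(design, "ccd_design"))
  k <- length(space$variables)
  if (k != design$n_factors)
    stop_reactbo("design and space dimension differ", "reactbo_dim_mismatch")
  lo <- vapply(space$variables, `[[`, 0, "lower")
  hi <- vapply(space$variables, `[[`, 0, "upper")
  mid <- (lo + hi) / 2
  halfw <- (hi - lo) / 2
  out <- sweep(sweep(design$runs, 2L, halfw, "*"), 2L, mid, "+")
  colnames(out) <- variable_names(space)
  out
}

quad_terms <- function(X) {
  k <- ncol(X)
  nms <- colnames(X) %||% paste0("x", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(X)))
  for (j in seq_len(k)) cols[[nms[j]]] <- X[, j]
  for (j in seq_len(k)) cols[[paste0("I(", nms[j], "^2)")]] <- X[, j]^2
  if (k >= 2L)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      cols[[paste0(nms[i], ":", nms[j])]] <- X[, i] * X[, j]
  do.call(cbind, cols)
}

#' Fit a full quadratic response surface
#'
#' Ordinary least squares for intercept + linear + pure-quadratic + pairwise
#' interaction terms (1 + 2k + k(k-1)/2 coefficients for k factors), the
#' approximate model at the heart of single-iteration RSM.
#'
#' @param X matrix of conditions (native units), e.g. a decoded CCD.
#' @param y response vector.
#' @return object of class `quadratic_surface` with named `coefficients`,
#'   `residuals`, `fitted` and `sigma`.
#' @export
fit_quadratic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  assert_finite(y, "responses")
  M <- quad_terms(X)
  if (nrow(M) < ncol(M))
    stop_reactbo(sprintf("need at least %d runs for %d factors, got %d",
                         ncol(M), ncol(X), nrow(M)), "reactbo_bad_fit")
  fit <- stats::lm.fit(M, y)
  if (fit$rank < ncol(M)) {
    aliased <- colnames(M)[is.na(fit$coefficients)]
    stop_reactbo(paste("rank-deficient design; aliased term(s):",
                       paste(aliased, collapse = ", ")), "reactbo_aliased")
  }
  dfres <- nrow(M) - ncol(M)
  structure(list(coefficients = fit$coefficients,
                 residuals = fit$residuals,
                 fitted = fit$fitted.values,
                 sigma = if (dfres > 0) sqrt(sum(fit$residuals^2) / dfres) else NA_real_,
                 terms = colnames(M), n_factors = ncol(X),
                 var_names = colnames(X)),
            class = "quadratic_surface")
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cat(sprintf("Quadratic response surface: %d factors, %d coefficients, residual sigma %.4g\n",
              x$n_factors, length(x$coefficients), x$sigma))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.quadratic_surface <- function(object, ...) object$coefficients

#' @export
residuals.quadratic_surface <- function(object, ...) object$residuals

#' Evaluate a quadratic surface
#'
#' @param object a [fit_quadratic()] surface.
#' @param newdata matrix of conditions (native units) or a `candidate_set`.
#' @param ... unused.
#' @return predicted response vector.
#' @export
predict.quadratic_surface <- function(object, newdata, ...) {
  if (inherits(newdata, "candidate_set")) newdata <- newdata$points
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_factors)
    stop_reactbo("wrong number of factors", "reactbo_dim_mismatch")
  colnames(newdata) <- object$var_names
  drop(quad_terms(newdata) %*% object$coefficients)
}

#' Predicted optimum of a fitted quadratic surface
#'
#' Grid search over the feasible candidate set (no stationary-point
#' extrapolation outside the bounds, and linear constraints are respected
#' because infeasible grid points were never generated).
#'
#' @param surface a [fit_quadratic()] surface.
#' @param candidates a [build_grid()] candidate set (or a `design_space`).
#' @return list with `point` (named vector), `value` and `index`.
#' @export
predict_optimum <- function(surface, candidates) {
  if (inherits(candidates, "design_space")) candidates <- build_grid(candidates)
  pred <- predict(surface, candidates)
  i <- which.max(pred)
  list(point = candidates$points[i, ], value = pred[i], index = i)
}
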