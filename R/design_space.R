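#' Define one experimental variable
#'
#' A continuous reaction condition (substrate concentration, enzyme loading,
#' pH, cosolvent fraction, ...) with its admissible range and the number of
#' equally spaced grid levels used when candidate conditions are enumerated.
#'
#' @param name variable name (must be unique within a design space).
#' @param lower,upper range bounds in native units; `lower < upper`.
#' @param units free-text units label (e.g. `"mM"`, `"%"`, `"uM"`).
#' @param grid_points number of grid levels (>= 2) for candidate enumeration.
#' @return an object of class `ds_variable`.
#' @examples
#' ds_variable("pH", 6, 9, units = "", grid_points = 7)
#' @export
ds_variable <- function(name, lower, upper, units = "", grid_points = 7L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  grid_points <- as.integer(grid_points)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop_reactbo(sprintf("variable '%s': need finite lower < upper", name),
                 "reactbo_bad_variable")
  if (grid_points < 2L)
    stop_reactbo(sprintf("variable '%s': grid_points must be >= 2", name),
                 "reactbo_bad_variable")
  structure(list(name = name, lower = lower, upper = upper, units = units,
                 grid_points = grid_points),
            class = "ds_variable")
}

#' Define a linear feasibility constraint
#'
#' Linear inequality over variable values in native units, e.g. the reagent
#' solubility limit `28.6*[NH4+] + 2*[DMSO] + 2.1*[enzyme] < 200` of an
#' ammonia-lyase reaction. Variables absent from `coefficients` contribute 0.
#'
#' @param coefficients named numeric vector mapping variable names to
#'   coefficients.
#' @param limit right-hand-side value.
#' @param strict `TRUE` for `<` (boundary infeasible), `FALSE` for `<=`.
#' @return an object of class `linear_constraint`.
#' @examples
#' linear_constraint(c(NH4 = 28.6, DMSO = 2, enzyme = 2.1), limit = 200)
#' @export
linear_constraint <- function(coefficients, limit, strict = TRUE) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))),
            is.numeric(limit), length(limit) == 1L, is.finite(limit),
            is.logical(strict), length(strict) == 1L)
  structure(list(coefficients = coefficients, limit = as.numeric(limit),
                 strict = strict),
            class = "linear_constraint")
}

#' Assemble a design space of reaction conditions
#'
#' The searchable hyperspace: an ordered set of continuous variables plus
#' optional linear feasibility constraints.
#'
#' @param variables list of [ds_variable()] objects (or a single one).
#' @param constraints list of [linear_constraint()] objects.
#' @return an object of class `design_space`.
#' @examples
#' sp <- design_space(list(
#'   ds_variable("substrate", 10, 100, "mM"),
#'   ds_variable("enzyme", 1, 20, "uM")
#' ))
#' @export
design_space <- function(variables, constraints = list()) {
  if (inherits(variables, "ds_variable")) variables <- list(variables)
  stopifnot(length(variables) >= 1L,
            all(vapply(variables, inherits, TRUE, "ds_variable")))
  nms <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop_reactbo("variable names must be unique", "reactbo_bad_space")
  if (inherits(constraints, "linear_constraint")) constraints <- list(constraints)
  stopifnot(all(vapply(constraints, inherits, TRUE, "linear_constraint")))
  for (ct in constraints) {
    unknown <- setdiff(names(ct$coefficients), nms)
    if (length(unknown))
      stop_reactbo(paste("constraint references unknown variable(s):",
                         paste(unknown, collapse = ", ")),
                   "reactbo_bad_space")
  }
  structure(list(variables = variables, constraints = constraints),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("Design space: %d variable(s), %d constraint(s)\n",
              length(x$variables), length(x$constraints)))
  for (v in x$variables)
    cat(sprintf("  %-12s [%g, %g] %s  (%d levels)\n",
                v$name, v$lower, v$upper, v$units, v$grid_points))
  for (ct in x$constraints)
    cat("  s.t. ",
        paste(sprintf("%g*%s", ct$coefficients, names(ct$coefficients)),
              collapse = " + "),
        if (ct$strict) " < " else " <= ", ct$limit, "\n", sep = "")
  invisible(x)
}

variable_names <- function(space) vapply(space$variables, `[[`, "", "name")

# constraint satisfaction for a points matrix (columns named by variable)
feasible_mask <- function(points, space) {
  ok <- rep(TRUE, nrow(points))
  nms <- colnames(points)
  for (ct in space$constraints) {
    coef <- numeric(length(nms)); names(coef) <- nms
    coef[names(ct$coefficients)] <- ct$coefficients
    lhs <- as.vector(points %*% coef)
    ok <- ok & if (ct$strict) lhs < ct$limit else lhs <= ct$limit
  }
  ok
}

#' Check feasibility of candidate points
#'
#' @param points numeric matrix (or vector for a single point) with columns in
#'   design-space variable order.
#' @param space a [design_space()].
#' @return logical vector, one entry per point.
#' @export
is_feasible <- function(points, space) {
  points <- as_point_matrix(points, space)
  feasible_mask(points, space)
}

as_point_matrix <- function(points, space) {
  nms <- variable_names(space)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (ncol(points) != length(nms))
    stop_reactbo("point dimension does not match design space",
                 "reactbo_dim_mismatch")
  colnames(points) <- nms
  points
}

#' Enumerate the feasible candidate grid
#'
#' Builds the full Cartesian product of per-variable equally spaced levels
#' (endpoints included), removes points violating any linear constraint, and
#' attaches a per-variable z-score scaler (mean and population standard
#' deviation of the feasible set). Ordering is lexicographic in variable order:
#' the first variable varies slowest, the last fastest, so two builds of the
#' same space are byte-identical.
#'
#' @param space a [design_space()].
#' @param max_points error if the raw grid exceeds this cap (coarsen the grid).
#' @return an object of class `candidate_set` with elements `points` (native
#'   units), `standardized`, `scaler` (`$mean`, `$sd`) and `space`.
#' @examples
#' sp <- design_space(list(ds_variable("a", 0, 1, grid_points = 3),
#'                         ds_variable("b", 0, 1, grid_points = 3)))
#' nrow(build_grid(sp)$points)  # 9
#' @export
build_grid <- function(space, max_points = 1e6) {
  stopifnot(inherits(space, "design_space"))
  levels <- lapply(space$variables,
                   function(v) seq(v$lower, v$upper, length.out = v$grid_points))
  n_raw <- prod(vapply(levels, length, 1L))
  if (n_raw > max_points)
    stop_reactbo(sprintf(
      "grid has %.0f points (cap %g); use fewer grid_points per variable",
      n_raw, max_points), "reactbo_grid_too_large")
  # expand.grid varies its first argument fastest; feed variables reversed so
  # the first design variable is the most significant digit
  g <- expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g[, rev(seq_along(levels)), drop = FALSE])
  colnames(g) <- variable_names(space)
  rownames(g) <- NULL
  keep <- feasible_mask(g, space)
  if (!any(keep))
    stop_reactbo("infeasible space: no grid point satisfies the constraints",
                 "reactbo_infeasible_space")
  pts <- g[keep, , drop = FALSE]
  mu <- colMeans(pts)
  sd_pop <- sqrt(colMeans(sweep(pts, 2L, mu)^2))
  if (any(sd_pop <= 0))
    stop_reactbo(paste("feasible grid is constant in variable(s):",
                       paste(colnames(pts)[sd_pop <= 0], collapse = ", ")),
                 "reactbo_degenerate_grid")
  scaler <- list(mean = mu, sd = sd_pop)
  structure(list(points = pts,
                 standardized = standardize_points(pts, scaler),
                 scaler = scaler,
                 space = space),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d feasible grid points, %d variable(s)\n",
              nrow(x$points), ncol(x$points)))
  invisible(x)
}

#' Standardize points to z-scores
#'
#' Applies the per-variable `(x - mean)/sd` map of a candidate-set scaler.
#' Distances between standardized points are what the exclusion radius of the
#' batch selector (threshold 1.0 by default) is measured in.
#'
#' @param points matrix or single point in native units.
#' @param scaler list with numeric vectors `mean` and `sd` (all `sd > 0`).
#' @return matrix of standardized coordinates.
#' @export
standardize_points <- function(points, scaler) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (ncol(points) != length(scaler$mean))
    stop_reactbo("point dimension does not match scaler", "reactbo_dim_mismatch")
  if (any(scaler$sd <= 0))
    stop_reactbo("scaler standard deviations must be positive", "reactbo_bad_scaler")
  sweep(sweep(points, 2L, scaler$mean), 2L, scaler$sd, "/")
}

#' Invert [standardize_points()]
#'
#' @inheritParams standardize_points
#' @return matrix in native units.
#' @export
destandardize_points <- function(points, scaler) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (ncol(points) != length(scaler$mean))
    stop_reactbo("point dimension does not match scaler", "reactbo_dim_mismatch")
  sweep(sweep(points, 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
}

#' Draw a random initial design
#'
#' Samples `n` distinct feasible grid points uniformly without replacement —
#' the "randomly selected initial reaction conditions" that seed a campaign.
#'
#' @param space a [design_space()] or a prebuilt [build_grid()] candidate set.
#' @param n number of points.
#' @param seed integer seed; the draw is reproducible and does not disturb the
#'   caller's RNG state.
#' @return matrix of `n` points in native units.
#' @export
sample_initial <- function(space, n, seed) {
  cand <- if (inherits(space, "candidate_set")) space else build_grid(space)
  n <- as.integer(n)
  if (n < 1L) stop_reactbo("n must be >= 1", "reactbo_bad_request")
  m <- nrow(cand$points)
  if (n > m)
    stop_reactbo(sprintf("requested %d initial points but only %d feasible grid points exist",
                         n, m), "reactbo_bad_request")
  idx <- with_seed(seed, sample.int(m, n, replace = FALSE))
  cand$points[idx, , drop = FALSE]
}

#' Read a design space from a YAML config
#'
#' Expected keys: `variables:` (list of `{name, lower, upper, units,
#' grid_points}`) and optional `constraints:` (list of `{coefficients: {name:
#' value}, limit, strict}`).
#'
#' @param path YAML file path.
#' @return a [design_space()].
#' @export
read_design_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables))
    stop_reactbo("config has no 'variables' key", "reactbo_bad_config")
  vars <- lapply(cfg$variables, function(v)
    ds_variable(v$name, v$lower, v$upper, units = v$units %||% "",
                grid_points = v$grid_points %||% 7L))
  cons <- lapply(cfg$constraints %||% list(), function(ct)
    linear_constraint(unlist(ct$coefficients), ct$limit,
                      strict = ct$strict %||% TRUE))
  design_space(vars, cons)
}
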