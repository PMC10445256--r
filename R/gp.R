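# Gaussian-process surrogate: Matern-5/2 kernel with per-dimension (ARD)
# lengthscales, constant prior mean, type-II maximum likelihood via
# multi-restart L-BFGS-B with analytic gradients. Inputs are mapped to [0,1]
# per variable for kernel numerics; outputs pass through an invertible affine
# transform ("zscore", "max10" or "none").

SQRT5 <- sqrt(5)

# squared scaled distances per dimension: list of n1 x n2 matrices
scaled_sqdiff <- function(X1, X2) {
  lapply(seq_len(ncol(X1)), function(j) outer(X1[, j], X2[, j], "-")^2)
}

# Matern 5/2 from per-dimension squared differences and lengthscales
matern52_from_sqdiff <- function(sqd, ell, s2) {
  r2 <- 0
  for (j in seq_along(sqd)) r2 <- r2 + sqd[[j]] / ell[j]^2
  r <- sqrt(pmax(r2, 0))
  e <- exp(-SQRT5 * r)
  k <- s2 * (1 + SQRT5 * r + (5 / 3) * r2) * e
  list(k = k, r = r, e = e)
}

make_transform <- function(type, y_measured) {
  switch(type,
    zscore = {
      ctr <- mean(y_measured)
      scl <- stats::sd(y_measured)
      if (!is.finite(scl) || scl <= 0) scl <- 1
      list(type = "zscore", center = ctr, scale = scl)
    },
    max10 = {
      m <- max(y_measured)
      if (m <= 0)
        stop_reactbo("max-10 scaling needs a positive maximum FoM",
                     "reactbo_bad_transform")
      list(type = "max10", center = 0, scale = m / 10)
    },
    none = list(type = "none", center = 0, scale = 1),
    stop_reactbo(sprintf("unknown output transform '%s'", type),
                 "reactbo_bad_transform")
  )
}

transform_y <- function(tr, y) (y - tr$center) / tr$scale
untransform_y <- function(tr, y) y * tr$scale + tr$center

# negative log marginal likelihood and gradient wrt
# theta = c(log ell (d), log s2, log noise); mean already subtracted from y
gp_nll <- function(theta, sqd, y, grad = TRUE) {
  d <- length(sqd)
  ell <- exp(theta[seq_len(d)])
  s2 <- exp(theta[d + 1L])
  noise <- exp(theta[d + 2L])
  n <- length(y)
  km <- matern52_from_sqdiff(sqd, ell, s2)
  K <- km$k
  diag(K) <- diag(K) + noise + 1e-12 * s2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, gradient = rep(0, d + 2L)))
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  if (!grad) return(list(value = nll))
  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv           # dnll/dtheta = -0.5 * sum(A * dK)
  g <- numeric(d + 2L)
  # dK/dlog ell_j = s2 * (5/3) * (1 + sqrt5 r) * exp(-sqrt5 r) * u_j,
  # u_j = sqd_j / ell_j^2  (the r-cancellation makes this well-defined at r=0)
  base <- s2 * (5 / 3) * (1 + SQRT5 * km$r) * km$e
  for (j in seq_len(d))
    g[j] <- -0.5 * sum(A * (base * (sqd[[j]] / ell[j]^2)))
  g[d + 1L] <- -0.5 * sum(A * km$k)       # dK/dlog s2 = K_f
  g[d + 2L] <- -0.5 * sum(diag(A)) * noise
  list(value = nll, gradient = g)
}

#' Fit a Gaussian-process surrogate
#'
#' Fits a constant-mean Gaussian process with a Matern-5/2 ARD kernel to
#' observed reaction outcomes. Hyperparameters (per-variable lengthscales,
#' signal variance, noise variance) maximize the log marginal likelihood via
#' multi-restart L-BFGS-B with analytic gradients; restarts are seeded so the
#' fit is reproducible. A noise floor keeps the covariance well conditioned —
#' enzymatic measurements carry experimental error, and the floor also
#' tolerates replicated conditions.
#'
#' @param X numeric matrix of conditions (rows) in native units.
#' @param y numeric response vector (native units).
#' @param bounds optional 2-row matrix (`rbind(lower, upper)`) used to map
#'   inputs to the unit cube; defaults to the data range.
#' @param transform output transform: `"zscore"` (default), `"max10"`
#'   (`y' = 10*y/max(y)`, the scaling used by the variance-squared
#'   acquisition), or `"none"`.
#' @param transform_stats optional vector of responses from which the
#'   transform parameters are computed instead of `y` (used so believer
#'   pseudo-observations never shift the transform).
#' @param noise_floor minimum noise variance in transformed units.
#' @param optimize_noise if `FALSE`, noise stays fixed at the floor.
#' @param restarts number of optimizer restarts (first start is deterministic,
#'   the rest are seeded random draws).
#' @param seed integer seed for the random restarts.
#' @return an object of class `gp_fit`.
#' @seealso [predict.gp_fit()], [apply_believer()]
#' @examples
#' X <- matrix(seq(0, 1, length.out = 8))
#' fit <- gp_fit(X, sin(2 * pi * X[, 1]), noise_floor = 1e-8, seed = 1)
#' predict(fit, X)$mean
#' @export
gp_fit <- function(X, y, bounds = NULL, transform = "zscore",
                   transform_stats = NULL, noise_floor = 1e-6,
                   optimize_noise = TRUE, restarts = 8L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 2L)
    stop_reactbo("need at least 2 observations to fit a GP", "reactbo_bad_fit")
  assert_finite(X, "inputs")
  assert_finite(y, "responses")
  if (noise_floor < 0)
    stop_reactbo("noise_floor must be >= 0", "reactbo_bad_fit")

  # duplicate inputs with conflicting responses are unexplainable at zero noise
  if (noise_floor < 1e-10) {
    key <- apply(X, 1L, paste, collapse = "\r")
    for (k in unique(key[duplicated(key)])) {
      ys <- y[key == k]
      if (diff(range(ys)) > 1e-9 * max(1, diff(range(y))))
        stop_reactbo(paste("duplicate conditions with conflicting responses;",
                           "set a nonzero noise_floor"),
                     "reactbo_conflicting_duplicates")
    }
  }

  if (is.null(bounds)) bounds <- rbind(apply(X, 2L, min), apply(X, 2L, max))
  width <- bounds[2L, ] - bounds[1L, ]
  width[width <= 0] <- 1
  Xs <- sweep(sweep(X, 2L, bounds[1L, ]), 2L, width, "/")

  tr <- make_transform(transform, transform_stats %||% y)
  yt <- transform_y(tr, y)
  mean_t <- mean(yt)
  yc <- yt - mean_t
  vy <- stats::var(yt)
  if (!is.finite(vy) || vy <= 0) vy <- 1

  d <- ncol(X)
  sqd <- scaled_sqdiff(Xs, Xs)
  floor_t <- max(noise_floor, 1e-12)
  lower <- c(rep(log(1e-3), d), log(1e-8), log(floor_t))
  upper <- c(rep(log(1e3), d), log(1e4 * vy + 1e-8),
             if (optimize_noise) log(max(vy, floor_t * 10)) else log(floor_t))
  upper[d + 2L] <- max(upper[d + 2L], lower[d + 2L])

  start0 <- c(rep(log(0.5), d), log(vy), log(max(floor_t, 1e-4 * vy)))
  starts <- list(pmin(pmax(start0, lower), upper))
  if (restarts > 1L) {
    extra <- with_seed(seed, lapply(seq_len(restarts - 1L), function(i) {
      s <- start0 + c(stats::rnorm(d, 0, 1), stats::rnorm(1, 0, 0.7),
                      stats::rnorm(1, 0, 1))
      pmin(pmax(s, lower), upper)
    }))
    starts <- c(starts, extra)
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s,
                   fn = function(th) gp_nll(th, sqd, yc, grad = FALSE)$value,
                   gr = function(th) gp_nll(th, sqd, yc, grad = TRUE)$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-10))
      best <- fit   # strict improvement: ties keep the first-found optimum
  }
  if (is.null(best))
    stop_reactbo("marginal-likelihood optimization failed from every start",
                 "reactbo_bad_fit")

  theta <- best$par
  ell <- exp(theta[seq_len(d)])
  s2 <- exp(theta[d + 1L])
  noise <- exp(theta[d + 2L])
  km <- matern52_from_sqdiff(sqd, ell, s2)
  K <- km$k
  diag(K) <- diag(K) + noise + 1e-12 * s2
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))

  structure(list(
    X = X, Xs = Xs, y = y, bounds = bounds, width = width,
    transform = tr, mean_t = mean_t,
    lengthscales = ell, signal_variance = s2, noise_variance = noise,
    L = L, alpha = alpha, nll = best$value,
    noise_floor = noise_floor, restarts = restarts, seed = seed
  ), class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("Matern-5/2 GP fit: n = %d, d = %d, output transform = %s\n",
              nrow(x$X), ncol(x$X), x$transform$type))
  cat("  lengthscales (unit-cube):",
      paste(signif(x$lengthscales, 3), collapse = ", "), "\n")
  cat(sprintf("  signal variance %.4g, noise variance %.4g, -logLik %.3f\n",
              x$signal_variance, x$noise_variance, x$nll))
  invisible(x)
}

#' @export
coef.gp_fit <- function(object, ...) {
  c(stats::setNames(object$lengthscales,
                    paste0("lengthscale.", colnames(object$X) %||%
                             seq_along(object$lengthscales))),
    signal_variance = object$signal_variance,
    noise_variance = object$noise_variance)
}

#' Posterior prediction from a GP fit
#'
#' Predictive mean and standard deviation of the latent response at new
#' conditions. Far from all data the mean reverts to the (transformed) data
#' mean and the standard deviation to the signal amplitude.
#'
#' @param object a [gp_fit()].
#' @param newdata matrix of conditions in native units (or a `candidate_set`).
#' @param native if `TRUE`, return values mapped back to native response
#'   units; default is the fit's transformed output space, which is where the
#'   acquisition functions operate.
#' @param ... unused.
#' @return list with numeric vectors `mean` and `sd`.
#' @export
predict.gp_fit <- function(object, newdata, native = FALSE, ...) {
  if (inherits(newdata, "candidate_set")) newdata <- newdata$points
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop_reactbo("prediction points have wrong dimension", "reactbo_dim_mismatch")
  Xs_new <- sweep(sweep(newdata, 2L, object$bounds[1L, ]), 2L, object$width, "/")
  kstar <- matern52_from_sqdiff(scaled_sqdiff(object$Xs, Xs_new),
                                object$lengthscales, object$signal_variance)$k
  mu <- object$mean_t + drop(crossprod(kstar, object$alpha))
  v <- backsolve(object$L, kstar, transpose = TRUE)
  var <- pmax(object$signal_variance - colSums(v^2), 0)
  sd <- sqrt(var)
  if (native) {
    mu <- untransform_y(object$transform, mu)
    sd <- sd * object$transform$scale
  }
  list(mean = mu, sd = sd)
}

#' Kriging-believer pseudo-observation
#'
#' Returns a one-row believer record at `point`: the GP predictive mean stands
#' in for the unmeasured outcome so the next batch member can be chosen as if
#' the experiment had already been run. Believer rows are tagged
#' `source = "believer"` and are discarded once the batch is assembled.
#'
#' @param fit a [gp_fit()].
#' @param point condition vector (native units).
#' @return list with `point`, `fom` (native predictive mean) and `source`.
#' @export
apply_believer <- function(fit, point) {
  pr <- predict(fit, matrix(point, nrow = 1L), native = TRUE)
  list(point = as.numeric(point), fom = pr$mean[1L], source = "believer")
}

#' Recondition a GP fit on new data without refitting hyperparameters
#'
#' Reuses the lengthscales, signal and noise variances of an existing fit and
#' only recomputes the posterior for a new training set. Used by the batch
#' selector when hyperparameter refitting after each believer insertion is
#' turned off for speed.
#'
#' @param fit a [gp_fit()].
#' @param X,y new training data (native units).
#' @param transform_stats responses defining the output transform (measured
#'   values only).
#' @return a `gp_fit` with the old hyperparameters and the new data.
#' @export
gp_update <- function(fit, X, y, transform_stats = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), ncol(X) == ncol(fit$X))
  Xs <- sweep(sweep(X, 2L, fit$bounds[1L, ]), 2L, fit$width, "/")
  tr <- make_transform(fit$transform$type, transform_stats %||% y)
  yt <- transform_y(tr, y)
  mean_t <- mean(yt)
  yc <- yt - mean_t
  km <- matern52_from_sqdiff(scaled_sqdiff(Xs, Xs), fit$lengthscales,
                             fit$signal_variance)
  K <- km$k
  diag(K) <- diag(K) + fit$noise_variance + 1e-12 * fit$signal_variance
  L <- chol(K)
  out <- fit
  out$X <- X; out$Xs <- Xs; out$y <- y
  out$transform <- tr; out$mean_t <- mean_t
  out$L <- L
  out$alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
  out
}

#' Fit a GP to one figure of merit of a ledger
#'
#' Convenience wrapper around [gp_fit()]: trains on measured plus believer
#' rows of the ledger, computes the output transform from measured rows only
#' (believers never update the max-10 scale factor), and takes input bounds
#' from the design space.
#'
#' @param ledger ledger data frame.
#' @param space a [design_space()].
#' @param fom FoM column to model.
#' @param transform output transform, as in [gp_fit()].
#' @param ... further arguments to [gp_fit()].
#' @return a `gp_fit`.
#' @export
fit_fom_gp <- function(ledger, space, fom = NULL, transform = "zscore", ...) {
  fom <- fom %||% ledger_fom(ledger)
  use <- which(ledger$source %in% c("measured", "believer") & !is.na(ledger[[fom]]))
  meas <- which(ledger$source == "measured" & !is.na(ledger[[fom]]))
  if (length(meas) < 1L)
    stop_reactbo("ledger needs at least one measured observation", "reactbo_bad_fit")
  X <- ledger_points(ledger, space, use)
  b <- rbind(vapply(space$variables, `[[`, 0, "lower"),
             vapply(space$variables, `[[`, 0, "upper"))
  gp_fit(X, ledger[[fom]][use], bounds = b, transform = transform,
         transform_stats = ledger[[fom]][meas], ...)
}
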