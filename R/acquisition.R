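# Acquisition functions for batch Bayesian optimization of reaction
# conditions: expected improvement, its variance-squared variant, and a
# probability-of-feasibility factor for a constrained second figure of merit.

#' Expected improvement
#'
#' EI(x) = (mu - f_best - xi) * Phi(Z) + sigma * phi(Z), with
#' Z = (mu - f_best - xi) / sigma, where `f_best` is the best measured FoM so
#' far, Phi/phi the standard normal CDF/PDF, and `xi` a jitter that biases the
#' search toward exploration (default 0.01). At `sigma = 0` the degenerate
#' limit max(mu - f_best - xi, 0) is returned. Vectorized over all arguments.
#'
#' @param mu predictive mean(s).
#' @param sigma predictive standard deviation(s), `>= 0`.
#' @param f_best incumbent best measured value (never a believer value).
#' @param xi exploration jitter, `>= 0`.
#' @return nonnegative expected improvement value(s).
#' @examples
#' expected_improvement(1, 1, 0)          # approx 1.075
#' expected_improvement(0.5, 0, 0.5)      # 0: no uncertainty, no improvement
#' @export
expected_improvement <- function(mu, sigma, f_best, xi = 0.01) {
  assert_finite(c(mu, sigma, f_best, xi), "expected_improvement inputs")
  if (any(sigma < 0))
    stop_reactbo("sigma must be nonnegative", "reactbo_bad_input")
  if (any(xi < 0))
    stop_reactbo("xi must be nonnegative", "reactbo_bad_input")
  n <- max(length(mu), length(sigma), length(f_best), length(xi))
  imp <- rep_len(mu, n) - rep_len(f_best, n) - rep_len(xi, n)
  sigma <- rep_len(sigma, n)
  out <- pmax(imp, 0)                      # sigma == 0 branch
  pos <- sigma > 0
  if (any(pos)) {
    z <- imp[pos] / sigma[pos]
    out[pos] <- imp[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  }
  pmax(out, 0)
}

#' Variance-squared acquisition (BOA-2)
#'
#' Expected improvement with the predictive standard deviation replaced by its
#' square: EI(mu, sigma^2, f_best, xi). Squaring inflates the exploration term
#' where uncertainty exceeds 1 and deflates it where uncertainty is below 1,
#' so it only behaves as intended on a response rescaled to a fixed magnitude
#' — use it with the max-10 output transform ([scale_fom_max10()]), under
#' which early-campaign uncertainties are large and the variant pushes hard
#' into unexplored regions, decaying to plain EI as data accumulate.
#'
#' @inheritParams expected_improvement
#' @return nonnegative acquisition value(s).
#' @export
boa2_acquisition <- function(mu, sigma, f_best, xi = 0.01) {
  if (any(sigma < 0))
    stop_reactbo("sigma must be nonnegative", "reactbo_bad_input")
  expected_improvement(mu, sigma^2, f_best, xi)
}

#' Constrained acquisition for a second figure of merit
#'
#' Multiplies a base acquisition value by the posterior probability that the
#' second FoM exceeds a threshold: AF(x) = EI(x) * Phi((mu2 - threshold) /
#' sigma2). Used, e.g., to steer a TON optimization toward conditions whose
#' predicted chemoselectivity clears a target. At `sigma2 = 0` the factor is
#' the indicator limit (1 above, 0 below, 0.5 at equality).
#'
#' @param ei base acquisition value(s), `>= 0`.
#' @param mu2 predictive mean(s) of the second FoM (native scale).
#' @param sigma2 predictive standard deviation(s) of the second FoM, `>= 0`.
#' @param threshold required second-FoM value (native scale).
#' @return constrained value(s) in `[0, ei]`.
#' @examples
#' constrained_acquisition(2, mu2 = 75, sigma2 = 5, threshold = 70) # 2*pnorm(1)
#' @export
constrained_acquisition <- function(ei, mu2, sigma2, threshold) {
  assert_finite(c(ei, mu2, sigma2, threshold), "constrained_acquisition inputs")
  if (any(sigma2 < 0))
    stop_reactbo("sigma2 must be nonnegative", "reactbo_bad_input")
  n <- max(length(ei), length(mu2), length(sigma2))
  ei <- rep_len(ei, n); mu2 <- rep_len(mu2, n); sigma2 <- rep_len(sigma2, n)
  factor <- ifelse(sigma2 > 0,
                   stats::pnorm((mu2 - threshold) / ifelse(sigma2 > 0, sigma2, 1)),
                   ifelse(mu2 > threshold, 1, ifelse(mu2 < threshold, 0, 0.5)))
  ei * factor
}

#' Rescale a FoM vector so its maximum is 10
#'
#' The fixed-magnitude rescaling required by the variance-squared acquisition:
#' y' = 10 * y / max(y). Keeps predicted uncertainties commensurate so that
#' squaring them does not blow up on large raw FoM values (TONs in the
#' thousands).
#'
#' @param values numeric vector with `max(values) > 0`.
#' @return list with `scaled` (max exactly 10) and `factor` (`max(values)/10`;
#'   multiply scaled values by it to recover the original scale).
#' @examples
#' scale_fom_max10(c(1573, 3289))$scaled
#' @export
scale_fom_max10 <- function(values) {
  assert_finite(values, "FoM values")
  m <- max(values)
  if (m <= 0)
    stop_reactbo(paste("max-10 scaling requires a positive maximum;",
                       "shift nonpositive FoMs before scaling"),
                 "reactbo_bad_input")
  list(scaled = 10 * values / m, factor = m / 10)
}

#' Acquisition strategy configuration
#'
#' @param strategy `"conventional"` (plain EI), `"boa1"` (EI plus
#'   standardized-distance candidate exclusion) or `"boa2"` (variance-squared
#'   EI on the max-10 scale).
#' @param xi exploration jitter (default 0.01).
#' @param distance_threshold exclusion radius in standardized units
#'   (default 1.0; used by `"boa1"`).
#' @param fom2_threshold optional second-FoM threshold activating the
#'   constrained acquisition.
#' @param batch_size proposals per iteration (default 5).
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(strategy = c("conventional", "boa1", "boa2"),
                               xi = 0.01, distance_threshold = 1.0,
                               fom2_threshold = NULL, batch_size = 5L) {
  strategy <- match.arg(strategy)
  stopifnot(xi >= 0, distance_threshold >= 0, batch_size >= 1L)
  structure(list(strategy = strategy, xi = xi,
                 distance_threshold = distance_threshold,
                 fom2_threshold = fom2_threshold,
                 batch_size = as.integer(batch_size)),
            class = "acquisition_config")
}

# output transform each strategy expects the primary-FoM GP to use
strategy_transform <- function(strategy) {
  if (strategy == "boa2") "max10" else "zscore"
}

#' Score every candidate under an acquisition strategy
#'
#' Applies the configured scorer pointwise over a candidate set; when a
#' second-FoM threshold is configured, each score is multiplied by the
#' probability-of-feasibility factor from the second fit. The argmax is the
#' lowest index among maximal scores; exact ties are flagged.
#'
#' @param fit primary-FoM [gp_fit()] (its output transform must match the
#'   strategy: z-score for conventional/boa1, max-10 for boa2).
#' @param candidates a [build_grid()] candidate set (or plain matrix).
#' @param config an [acquisition_config()].
#' @param f_best best measured primary FoM in the fit's transformed space.
#' @param fit2 optional second-FoM `gp_fit` (predictions taken on the native
#'   scale, where the threshold lives).
#' @return list with `scores`, `argmax` and `tie`.
#' @export
score_candidates <- function(fit, candidates, config, f_best, fit2 = NULL) {
  pts <- if (inherits(candidates, "candidate_set")) candidates$points else as.matrix(candidates)
  pr <- predict(fit, pts)
  scores <- switch(config$strategy,
    conventional = ,
    boa1 = expected_improvement(pr$mean, pr$sd, f_best, config$xi),
    boa2 = boa2_acquisition(pr$mean, pr$sd, f_best, config$xi))
  if (!is.null(config$fom2_threshold)) {
    if (is.null(fit2))
      stop_reactbo("fom2_threshold set but no second-FoM fit supplied",
                   "reactbo_bad_input")
    pr2 <- predict(fit2, pts, native = TRUE)
    scores <- constrained_acquisition(scores, pr2$mean, pr2$sd,
                                      config$fom2_threshold)
  }
  mx <- max(scores)
  list(scores = scores,
       argmax = which.max(scores),
       tie = sum(scores == mx) > 1L)
}
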