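# Synthetic enzyme-response surfaces: mechanistically sensible ground truths
# (Michaelis-Menten with substrate inhibition, Gaussian pH optimum,
# exponential cosolvent inactivation, hyperbolic enzyme-loading dilution,
# optional cofactor optimum and cosubstrate saturation) against which the
# optimization strategies can be exercised without wet-lab data.

#' Parameters of a synthetic enzyme response surface
#'
#' Defines a deterministic TON landscape over named reaction conditions plus a
#' noise model and an optional logistic chemoselectivity trade-off. The `roles`
#' map ties mechanistic roles to design-space variable names, e.g.
#' `c(substrate = "benzoylformate", enzyme = "BFD")`.
#'
#' @param ttn_max plateau total turnover number (all factors at 1).
#' @param km substrate half-saturation constant (mM).
#' @param ki substrate-inhibition constant (mM); the TON-vs-substrate profile
#'   peaks at `sqrt(km * ki)`.
#' @param ph_opt,ph_width optimum pH and Gaussian width.
#' @param cosolvent_decay exponential inactivation rate per percent cosolvent.
#' @param enzyme_half enzyme loading (uM) at which TON halves (TON falls with
#'   loading because turnover is product per enzyme).
#' @param cofactor_opt,cofactor_width optional cofactor optimum (e.g. TPP,
#'   inhibitory in excess).
#' @param cosubstrate_km optional cosubstrate half-saturation (no inhibition).
#' @param noise_cv lognormal coefficient of variation of measured TON.
#' @param selectivity optional list `list(coef = named numeric, intercept,
#'   noise_sd)` defining a logistic chemoselectivity surface in percent.
#' @param roles named character vector mapping roles (`substrate`, `enzyme`,
#'   `ph`, `cosolvent`, `cofactor`, `cosubstrate`) to variable names.
#' @return object of class `response_surface_params`.
#' @export
response_surface_params <- function(ttn_max, km, ki = Inf, ph_opt, ph_width,
                                    cosolvent_decay = 0, enzyme_half,
                                    cofactor_opt = NULL, cofactor_width = NULL,
                                    cosubstrate_km = NULL,
                                    noise_cv = 0.05, selectivity = NULL,
                                    roles = c(substrate = "substrate",
                                              enzyme = "enzyme", ph = "pH",
                                              cosolvent = "DMSO")) {
  stopifnot(ttn_max > 0, km > 0, ki > 0, ph_width > 0, cosolvent_decay >= 0,
            enzyme_half > 0, noise_cv >= 0, noise_cv < 1)
  if (!is.null(cofactor_opt)) stopifnot(cofactor_width > 0)
  structure(list(ttn_max = ttn_max, km = km, ki = ki, ph_opt = ph_opt,
                 ph_width = ph_width, cosolvent_decay = cosolvent_decay,
                 enzyme_half = enzyme_half, cofactor_opt = cofactor_opt,
                 cofactor_width = cofactor_width,
                 cosubstrate_km = cosubstrate_km, noise_cv = noise_cv,
                 selectivity = selectivity, roles = roles),
            class = "response_surface_params")
}

role_value <- function(point, params, role, required = TRUE) {
  var <- params$roles[[role]]
  if (is.null(var) || !var %in% names(point)) {
    if (required)
      stop_reactbo(sprintf("point lacks the '%s' axis (variable '%s')",
                           role, var %||% "?"), "reactbo_missing_axis")
    return(NULL)
  }
  unname(point[[var]])
}

#' Deterministic TON response
#'
#' TON = ttn_max * S/(S + km + S^2/ki) * exp(-((pH - ph_opt)/ph_width)^2) *
#' exp(-decay * cosolvent) * enzyme_half/(enzyme_half + E), times optional
#' Gaussian cofactor and saturating cosubstrate factors. Always in
#' `[0, ttn_max]`; decreasing in enzyme loading and cosolvent fraction.
#'
#' @param point named condition vector (or one-row matrix) in native units.
#' @param params a [response_surface_params()].
#' @return nonnegative TON value.
#' @export
ton_response <- function(point, params) {
  if (!is.null(dim(point)))
    return(vapply(seq_len(nrow(point)),
                  function(i) ton_response(point[i, ], params), 0))
  point <- as.list(point)
  S <- role_value(point, params, "substrate")
  E <- role_value(point, params, "enzyme")
  pH <- role_value(point, params, "ph")
  ton <- params$ttn_max * S / (S + params$km + S^2 / params$ki)
  ton <- ton * exp(-((pH - params$ph_opt) / params$ph_width)^2)
  if (params$cosolvent_decay > 0) {
    cs <- role_value(point, params, "cosolvent")
    ton <- ton * exp(-params$cosolvent_decay * cs)
  }
  ton <- ton * params$enzyme_half / (params$enzyme_half + E)
  if (!is.null(params$cofactor_opt)) {
    cf <- role_value(point, params, "cofactor")
    ton <- ton * exp(-((cf - params$cofactor_opt) / params$cofactor_width)^2)
  }
  if (!is.null(params$cosubstrate_km)) {
    co <- role_value(point, params, "cosubstrate")
    ton <- ton * co / (co + params$cosubstrate_km)
  }
  ton
}

#' Chemoselectivity response surface
#'
#' Logistic map of an affine function of the conditions, scaled to [0, 100]
#' percent; under the shipped presets it is anti-correlated with the TON
#' surface (the recurring trade-off: the higher the TON, the lower the
#' chemoselectivity).
#'
#' @inheritParams ton_response
#' @return selectivity in percent, in `[0, 100]`.
#' @export
selectivity_response <- function(point, params) {
  if (!is.null(dim(point)))
    return(vapply(seq_len(nrow(point)),
                  function(i) selectivity_response(point[i, ], params), 0))
  sel <- params$selectivity
  if (is.null(sel))
    stop_reactbo("surface has no selectivity parameters", "reactbo_bad_input")
  point <- as.list(point)
  aff <- sel$intercept %||% 0
  for (v in names(sel$coef)) {
    if (!v %in% names(point))
      stop_reactbo(sprintf("point lacks variable '%s'", v), "reactbo_missing_axis")
    aff <- aff + sel$coef[[v]] * point[[v]]
  }
  100 * stats::plogis(aff)
}

#' Simulate a noisy measurement
#'
#' TON is multiplied by a lognormal factor with unit mean and coefficient of
#' variation `noise_cv`; selectivity (when modelled) gets additive Gaussian
#' noise truncated to [0, 100].
#'
#' @inheritParams ton_response
#' @param seed optional seed; when `NULL` the ambient RNG stream is used (so a
#'   seeded campaign is reproducible end-to-end).
#' @return named list with `TON` and, when modelled, `selectivity`.
#' @export
measure_point <- function(point, params, seed = NULL) {
  run <- function() {
    ton <- ton_response(point, params)
    if (params$noise_cv > 0) {
      sdlog <- sqrt(log(1 + params$noise_cv^2))
      ton <- ton * stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    out <- list(TON = ton)
    if (!is.null(params$selectivity)) {
      s <- selectivity_response(point, params)
      nsd <- params$selectivity$noise_sd %||% 0
      if (nsd > 0) s <- min(100, max(0, s + stats::rnorm(1L, 0, nsd)))
      out$selectivity <- s
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Chemoselectivity from an isomer ratio
#'
#' 100 * (major - minor) / (major + minor): an 85:15 isomer ratio corresponds
#' to 70 percent chemoselectivity.
#'
#' @param major,minor nonnegative isomer amounts, not both zero.
#' @return chemoselectivity in percent.
#' @examples
#' chemoselectivity_from_ratio(85, 15)  # 70
#' @export
chemoselectivity_from_ratio <- function(major, minor) {
  stopifnot(all(major >= 0), all(minor >= 0))
  tot <- major + minor
  if (any(tot == 0))
    stop_reactbo("major + minor must be positive", "reactbo_bad_input")
  100 * (major - minor) / tot
}

#' Load a shipped synthetic enzyme preset
#'
#' Three desk-scale ground-truth systems are shipped as versioned YAML
#' fixtures: `"bfd5"` (5 variables incl. a cofactor optimum), `"pal5"` (5
#' variables with a linear solubility constraint) and `"bal6"` (6 variables
#' with a TON/selectivity trade-off). Each records its design space, surface
#' parameters and the true optimum of the default candidate grid.
#'
#' @param name preset name.
#' @return list with `name`, `space` ([design_space()]), `params`
#'   ([response_surface_params()]) and `optimum` (`$point`, `$TON`).
#' @export
enzyme_preset <- function(name = c("bfd5", "pal5", "bal6")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "reactbo", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  vars <- lapply(cfg$space$variables, function(v)
    ds_variable(v$name, v$lower, v$upper, units = v$units %||% "",
                grid_points = v$grid_points %||% 7L))
  cons <- lapply(cfg$space$constraints %||% list(), function(ct)
    linear_constraint(unlist(ct$coefficients), ct$limit,
                      strict = ct$strict %||% TRUE))
  p <- cfg$params
  params <- response_surface_params(
    ttn_max = p$ttn_max, km = p$km, ki = p$ki %||% Inf,
    ph_opt = p$ph_opt, ph_width = p$ph_width,
    cosolvent_decay = p$cosolvent_decay %||% 0,
    enzyme_half = p$enzyme_half,
    cofactor_opt = p$cofactor_opt, cofactor_width = p$cofactor_width,
    cosubstrate_km = p$cosubstrate_km,
    noise_cv = p$noise_cv %||% 0.05,
    selectivity = if (!is.null(p$selectivity))
      list(coef = unlist(p$selectivity$coef),
           intercept = p$selectivity$intercept %||% 0,
           noise_sd = p$selectivity$noise_sd %||% 0),
    roles = unlist(cfg$roles))
  optimum <- list(point = unlist(cfg$optimum$point), TON = cfg$optimum$TON)
  list(name = name, space = design_space(vars, cons), params = params,
       optimum = optimum)
}

#' Oracle closure for a preset
#'
#' @param preset an [enzyme_preset()] (or preset name).
#' @param noisy simulate measurement noise (default) or return the exact
#'   deterministic surface.
#' @return function mapping a named condition vector to a named list of FoM
#'   values, suitable for [run_closed_loop()].
#' @export
preset_oracle <- function(preset, noisy = TRUE) {
  if (is.character(preset)) preset <- enzyme_preset(preset)
  params <- preset$params
  if (noisy) {
    function(point) measure_point(point, params)
  } else {
    function(point) {
      out <- list(TON = ton_response(point, params))
      if (!is.null(params$selectivity))
        out$selectivity <- selectivity_response(point, params)
      out
    }
  }
}
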