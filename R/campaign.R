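# Campaign orchestration: initial random design, iterate suggest -> measure ->
# append, in human-in-the-loop (CSV round-trip) or closed-loop (simulator
# oracle) mode.

#' Campaign configuration
#'
#' Defaults mirror the standard screening shape: 5 randomly selected initial
#' conditions, 5 proposals per cycle, 5 cycles.
#'
#' @param n_initial initial random conditions.
#' @param batch_size proposals per iteration.
#' @param n_iterations number of suggest/measure cycles.
#' @param strategy acquisition strategy (see [acquisition_config()]).
#' @param seed campaign seed; drives the initial design, measurement noise in
#'   closed-loop mode and GP restarts.
#' @param stop_target optional FoM value that ends the loop early once a
#'   measured observation reaches it.
#' @param xi,distance_threshold,fom2_threshold passed to [acquisition_config()].
#' @param refit_believers see [select_batch()].
#' @param restarts GP optimizer restarts per fit.
#' @return an object of class `campaign_config`.
#' @export
campaign_config <- function(n_initial = 5L, batch_size = 5L, n_iterations = 5L,
                            strategy = "conventional", seed = 1L,
                            stop_target = NULL, xi = 0.01,
                            distance_threshold = 1.0, fom2_threshold = NULL,
                            refit_believers = TRUE, restarts = 8L) {
  stopifnot(n_initial >= 1L, batch_size >= 1L, n_iterations >= 0L)
  acq <- acquisition_config(strategy, xi = xi,
                            distance_threshold = distance_threshold,
                            fom2_threshold = fom2_threshold,
                            batch_size = batch_size)
  structure(list(n_initial = as.integer(n_initial),
                 batch_size = as.integer(batch_size),
                 n_iterations = as.integer(n_iterations),
                 strategy = acq$strategy, seed = as.integer(seed),
                 stop_target = stop_target, acquisition = acq,
                 refit_believers = refit_believers,
                 restarts = as.integer(restarts)),
            class = "campaign_config")
}

#' Initialize a campaign ledger
#'
#' Draws the initial random design over the feasible grid and returns (and
#' optionally writes) a ledger with those conditions marked `proposed`, FoM
#' fields empty, awaiting measurement.
#'
#' @param space a [design_space()].
#' @param config a [campaign_config()].
#' @param fom,fom2 FoM column names.
#' @param path optional CSV path; refuses to overwrite unless `force`.
#' @param force overwrite an existing ledger file.
#' @return the initial ledger.
#' @export
init_campaign <- function(space, config, fom = "TON", fom2 = NULL,
                          path = NULL, force = FALSE) {
  pts <- sample_initial(space, config$n_initial, seed = config$seed)
  ledger <- ledger_append(new_ledger(space, fom = fom, fom2 = fom2),
                          pts, iteration = 0L, source = "proposed")
  if (!is.null(path)) write_ledger(ledger, path, force = force)
  ledger
}

measure_with_oracle <- function(oracle, points, fom, fom2) {
  vals <- lapply(seq_len(nrow(points)), function(i) {
    v <- oracle(points[i, ])
    if (is.numeric(v) && is.null(names(v))) v <- stats::setNames(as.list(v), fom)[1]
    v <- as.list(v)
    if (!all(is.finite(unlist(v[c(fom, fom2)]))))
      stop_reactbo(paste("oracle returned a non-finite value at condition:",
                         paste(signif(points[i, ], 4), collapse = ", ")),
                   "reactbo_bad_oracle")
    v
  })
  out <- stats::setNames(list(vapply(vals, function(v) v[[fom]], 0)), fom)
  if (!is.null(fom2)) out[[fom2]] <- vapply(vals, function(v) v[[fom2]], 0)
  out
}

#' Run a closed-loop optimization campaign
#'
#' Executes the full iterate-until-budget loop against a response oracle
#' (typically a synthetic enzyme surface, see [preset_oracle()]): evaluate the
#' initial random design, then repeat propose-batch / measure / append for
#' `n_iterations` cycles, stopping early if `stop_target` is reached. The
#' whole run is driven by `config$seed`, so identical configurations replay
#' identical histories.
#'
#' @param space a [design_space()].
#' @param oracle function taking a named condition vector and returning the
#'   FoM value (or a named list with both FoMs).
#' @param config a [campaign_config()].
#' @param fom,fom2 FoM column names.
#' @param candidates optional prebuilt candidate grid (built from `space`
#'   otherwise).
#' @return an object of class `bo_campaign` with the final `ledger`, the
#'   per-iteration `iterations` records, and `best_so_far` (index 1 = after
#'   the initial design).
#' @export
run_closed_loop <- function(space, oracle, config, fom = "TON", fom2 = NULL,
                            candidates = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  cand <- candidates %||% build_grid(space)
  with_seed(config$seed, {
    ledger <- init_campaign(space, config, fom = fom, fom2 = fom2)
    pts0 <- ledger_points(ledger, space)
    ledger <- record_measurements(ledger,
                                  measure_with_oracle(oracle, pts0, fom, fom2))
    iterations <- list()
    best <- max(ledger[[fom]][measured_rows(ledger)])
    best_so_far <- best
    it <- 0L
    while (it < config$n_iterations &&
           (is.null(config$stop_target) || best < config$stop_target)) {
      it <- it + 1L
      prop <- select_batch(ledger, cand, config$acquisition, space = space,
                           fom = fom, fom2 = fom2,
                           seed = config$seed + 1000L * it,
                           refit_believers = config$refit_believers,
                           restarts = config$restarts)
      vals <- measure_with_oracle(oracle, prop$points, fom, fom2)
      ledger <- ledger_append(ledger, prop$points, iteration = it,
                              source = "proposed")
      ledger <- record_measurements(ledger, vals)
      best <- max(best, vals[[fom]])
      best_so_far <- c(best_so_far, best)
      iterations[[it]] <- list(iteration = it, proposal = prop,
                               measured = vals, best = best)
    }
    structure(list(config = config, space = space, ledger = ledger,
                   iterations = iterations, best_so_far = best_so_far,
                   fom = fom, fom2 = fom2),
              class = "bo_campaign")
  })
}

#' @export
print.bo_campaign <- function(x, ...) {
  cat(sprintf("Bayesian-optimization campaign ('%s'): %d initial + %d iteration(s) x %d\n",
              x$config$strategy, x$config$n_initial,
              length(x$iterations), x$config$batch_size))
  cat(sprintf("  measured experiments: %d\n", length(measured_rows(x$ledger))))
  cat(sprintf("  best %s: %.4g\n", x$fom, max(x$best_so_far)))
  invisible(x)
}

#' @export
summary.bo_campaign <- function(object, ...) {
  n_iter <- length(object$iterations)
  df <- data.frame(iteration = 0:n_iter,
                   n_measured = c(object$config$n_initial,
                                  vapply(object$iterations,
                                         function(i) nrow(i$proposal$points), 0L)),
                   best_so_far = object$best_so_far)
  best <- best_observed(object$ledger, fom = object$fom)
  structure(list(trajectory = df, best = best, fom = object$fom,
                 strategy = object$config$strategy),
            class = "summary.bo_campaign")
}

#' @export
print.summary.bo_campaign <- function(x, ...) {
  cat(sprintf("Campaign summary (strategy '%s', FoM '%s')\n", x$strategy, x$fom))
  print(x$trajectory, row.names = FALSE)
  cat("Best measured condition:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Plot the best-so-far trajectory of a campaign
#'
#' @param x a `bo_campaign`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bo_campaign <- function(x, ...) {
  graphics::plot(seq_along(x$best_so_far) - 1L, x$best_so_far, type = "b",
                 xlab = "iteration", ylab = paste("best", x$fom),
                 main = sprintf("Campaign trajectory (%s)", x$config$strategy),
                 ...)
}

#' Benchmark acquisition strategies on an oracle
#'
#' Runs repeated seeded campaigns for each strategy at an equal experiment
#' budget and records the best-so-far trajectory. `"random"` draws the whole
#' budget uniformly from the feasible grid; `"rsm"` runs the one-shot
#' central-composite-design baseline (design evaluation, quadratic fit,
#' predicted-optimum confirmation run).
#'
#' @param space a [design_space()].
#' @param oracle response oracle as in [run_closed_loop()].
#' @param strategies character vector from `{"conventional", "boa1", "boa2",
#'   "random", "rsm"}`.
#' @param n_seeds campaigns per strategy (seeds `seed0 + 1:n_seeds`).
#' @param config base [campaign_config()] (its seed is overridden per run).
#' @param seed0 seed offset.
#' @param fom FoM column name.
#' @return data frame: `strategy`, `seed`, `iteration`, `n_measured`,
#'   `best_so_far`.
#' @export
benchmark_strategies <- function(space, oracle,
                                 strategies = c("boa1", "boa2", "random"),
                                 n_seeds = 20L,
                                 config = campaign_config(),
                                 seed0 = 0L, fom = "TON") {
  cand <- build_grid(space)
  budget <- config$n_initial + config$n_iterations * config$batch_size
  out <- list()
  for (strat in strategies) {
    for (s in seq_len(n_seeds)) {
      seed <- seed0 + s
      if (strat %in% c("conventional", "boa1", "boa2")) {
        cfg <- config
        cfg$strategy <- strat
        cfg$acquisition$strategy <- strat
        cfg$seed <- as.integer(seed)
        camp <- run_closed_loop(space, oracle, cfg, fom = fom,
                                candidates = cand)
        n_meas <- cumsum(c(cfg$n_initial,
                           vapply(camp$iterations,
                                  function(i) nrow(i$proposal$points), 0L)))
        rec <- data.frame(strategy = strat, seed = seed,
                          iteration = seq_along(camp$best_so_far) - 1L,
                          n_measured = n_meas,
                          best_so_far = camp$best_so_far)
      } else if (strat == "random") {
        rec <- with_seed(seed, {
          idx <- sample.int(nrow(cand$points),
                            min(budget, nrow(cand$points)))
          vals <- measure_with_oracle(oracle,
                                      cand$points[idx, , drop = FALSE],
                                      fom, NULL)[[fom]]
          # chunk like the sequential campaigns: initial design, then batches
          cuts <- c(config$n_initial,
                    rep(config$batch_size, config$n_iterations))
          cuts <- pmin(cumsum(cuts), length(vals))
          data.frame(strategy = strat, seed = seed,
                     iteration = seq_along(cuts) - 1L,
                     n_measured = cuts,
                     best_so_far = vapply(cuts, function(k) max(vals[1:k]), 0))
        })
      } else if (strat == "rsm") {
        rec <- with_seed(seed, {
          res <- rsm_one_shot(space, oracle, fom = fom, candidates = cand)
          data.frame(strategy = strat, seed = seed, iteration = 0:1,
                     n_measured = c(res$n_design, res$n_design + 1L),
                     best_so_far = c(res$best_design, res$best_final))
        })
      } else {
        stop_reactbo(sprintf("unknown strategy '%s'", strat), "reactbo_bad_request")
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

# one-shot RSM baseline run: evaluate the CCD, fit the quadratic, confirm the
# predicted optimum with one extra experiment
rsm_one_shot <- function(space, oracle, fom = "TON", candidates = NULL) {
  k <- length(space$variables)
  des <- ccd_design(k)
  pts <- decode_design(des, space)
  keep <- feasible_mask(pts, space)
  pts <- pts[keep, , drop = FALSE]
  vals <- measure_with_oracle(oracle, pts, fom, NULL)[[fom]]
  fit <- fit_quadratic(pts, vals)
  cand <- candidates %||% build_grid(space)
  opt <- predict_optimum(fit, cand)
  conf <- measure_with_oracle(oracle, matrix(opt$point, nrow = 1L,
                                             dimnames = list(NULL, names(opt$point))),
                              fom, NULL)[[fom]]
  list(n_design = nrow(pts), best_design = max(vals),
       predicted = opt$value, confirmed = conf,
       best_final = max(max(vals), conf), optimum_point = opt$point)
}
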