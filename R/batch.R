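# Batch proposal via the Kriging-believer heuristic, with the BOA-1
# standardized-distance exclusion rule.

#' Exclude candidates near existing data
#'
#' Removes every candidate whose minimum Euclidean distance — measured on
#' standardized (z-scored) coordinates — to any reference point is less than
#' or equal to `threshold`; candidates strictly farther away are kept. This is
#' the BOA-1 rule that stops a batch from piling proposals into the
#' neighbourhood of conditions already tested.
#'
#' @param candidates a [build_grid()] candidate set.
#' @param reference_points matrix of reference conditions in native units
#'   (they are standardized with the candidate set's own scaler).
#' @param threshold exclusion radius in standardized units, `>= 0`.
#' @return the filtered `candidate_set`, with attribute `n_excluded`. If every
#'   candidate is excluded, an error of class `reactbo_search_exhausted` is
#'   signalled so callers can fall back gracefully.
#' @export
exclusion_filter <- function(candidates, reference_points, threshold) {
  stopifnot(inherits(candidates, "candidate_set"), threshold >= 0)
  if (is.null(dim(reference_points)))
    reference_points <- matrix(reference_points, nrow = 1L)
  refs <- standardize_points(as.matrix(reference_points), candidates$scaler)
  mind <- min_sq_distances(candidates$standardized, refs)
  # relative guard so distances exactly at the threshold are excluded even
  # when the expanded distance formula is off in the last ulp
  keep <- mind > threshold^2 * (1 + 1e-9) + 1e-12
  if (!any(keep))
    stop_reactbo(sprintf(
      "search exhausted: all %d candidates within %.3g standardized units of existing data",
      nrow(candidates$points), threshold), "reactbo_search_exhausted")
  out <- candidates
  out$points <- candidates$points[keep, , drop = FALSE]
  out$standardized <- candidates$standardized[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# squared min distance from each row of A to any row of B
min_sq_distances <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  cross <- A %*% t(B)
  d2 <- outer(a2, b2, "+") - 2 * cross
  pmax(apply(d2, 1L, min), 0)
}

#' Propose a batch of conditions to test next
#'
#' The per-iteration engine: loops `batch_size` times, each round (1)
#' (re)fitting the GP on measured plus believer records, (2) for the BOA-1
#' strategy, excluding candidates within the standardized-distance threshold
#' of all measured points and of believers already chosen this batch, (3)
#' scoring the remaining candidates with the configured acquisition, (4)
#' taking the argmax as the next proposal and (5) appending its
#' Kriging-believer pseudo-observation. Believer rows are internal and are
#' not part of the returned proposal or any persisted ledger.
#'
#' If the BOA-1 exclusion empties the candidate set, the radius is halved
#' once; if still empty, the filter is dropped for that pick. Both fallbacks
#' are recorded in the result.
#'
#' @param ledger ledger with at least 2 measured observations.
#' @param candidates a [build_grid()] candidate set.
#' @param config an [acquisition_config()].
#' @param space the [design_space()] (defaults to the candidate set's).
#' @param fom primary FoM column; `fom2` the optional constrained second FoM.
#' @param seed integer seed controlling GP restart randomness.
#' @param refit_believers refit hyperparameters after each believer insertion
#'   (full Kriging believer, default) or freeze them after the first fit.
#' @param restarts GP optimizer restarts per fit.
#' @return an object of class `batch_proposal`: `points` (q x d matrix),
#'   `scores`, `excluded_counts`, `fallback` (per-pick 0/1/2), `exhausted`
#'   flag when fewer than `batch_size` points could be proposed.
#' @export
select_batch <- function(ledger, candidates, config, space = NULL,
                         fom = NULL, fom2 = NULL, seed = 1L,
                         refit_believers = TRUE, restarts = 8L) {
  stopifnot(inherits(candidates, "candidate_set"),
            inherits(config, "acquisition_config"))
  space <- space %||% candidates$space
  fom <- fom %||% ledger_fom(ledger)
  fom2 <- fom2 %||% attr(ledger, "fom2")
  meas <- measured_rows(ledger)
  if (length(meas) < 2L)
    stop_reactbo("need at least 2 measured observations before proposing",
                 "reactbo_bad_request")

  transform <- strategy_transform(config$strategy)
  work <- ledger[ledger$source == "measured", , drop = FALSE]
  attributes(work)[c("fom", "fom2")] <- list(fom, fom2)
  meas_pts <- ledger_points(work, space)

  q <- config$batch_size
  d <- ncol(candidates$points)
  chosen <- matrix(numeric(0), ncol = d, dimnames = list(NULL, colnames(candidates$points)))
  scores_out <- numeric(0)
  excluded <- integer(0)
  fallback <- integer(0)
  exhausted <- FALSE
  fit <- NULL
  fit2 <- NULL

  avail <- candidates      # candidates not yet chosen this batch
  for (b in seq_len(q)) {
    use <- which(work$source %in% c("measured", "believer") & !is.na(work[[fom]]))
    msr <- which(work$source == "measured" & !is.na(work[[fom]]))
    if (refit_believers || b == 1L) {
      fit <- fit_fom_gp(work, space, fom = fom, transform = transform,
                        seed = seed + b, restarts = restarts)
      if (!is.null(config$fom2_threshold))
        fit2 <- fit_fom_gp(work, space, fom = fom2, transform = "zscore",
                           seed = seed + 100L + b, restarts = restarts)
    } else {
      fit <- gp_update(fit, ledger_points(work, space, use), work[[fom]][use],
                       transform_stats = work[[fom]][msr])
      if (!is.null(config$fom2_threshold)) {
        use2 <- which(work$source %in% c("measured", "believer") & !is.na(work[[fom2]]))
        fit2 <- gp_update(fit2, ledger_points(work, space, use2), work[[fom2]][use2])
      }
    }
    f_best <- max(transform_y(fit$transform,
                              work[[fom]][work$source == "measured"]))

    cand_b <- avail
    n_exc <- 0L
    fb <- 0L
    if (config$strategy == "boa1") {
      refs <- rbind(meas_pts, chosen)
      thr <- config$distance_threshold
      filtered <- tryCatch(exclusion_filter(cand_b, refs, thr),
                           reactbo_search_exhausted = function(e) NULL)
      if (is.null(filtered)) {           # fall back: halve the radius once
        fb <- 1L
        filtered <- tryCatch(exclusion_filter(cand_b, refs, thr / 2),
                             reactbo_search_exhausted = function(e) NULL)
      }
      if (is.null(filtered)) {           # last resort: unfiltered argmax
        fb <- 2L
        filtered <- cand_b
      }
      n_exc <- attr(filtered, "n_excluded") %||% 0L
      cand_b <- filtered
    }
    if (nrow(cand_b$points) == 0L) { exhausted <- TRUE; break }

    sc <- score_candidates(fit, cand_b, config, f_best, fit2 = fit2)
    pick <- cand_b$points[sc$argmax, , drop = FALSE]
    chosen <- rbind(chosen, pick)
    scores_out <- c(scores_out, sc$scores[sc$argmax])
    excluded <- c(excluded, n_exc)
    fallback <- c(fallback, fb)

    # believer record: predictive mean stands in for the unmeasured outcome
    bel <- apply_believer(fit, pick[1L, ])
    bel_fom2 <- if (!is.null(config$fom2_threshold))
      predict(fit2, pick, native = TRUE)$mean[1L]
    vals <- stats::setNames(list(bel$fom), fom)
    if (!is.null(fom2) && !is.null(bel_fom2)) vals[[fom2]] <- bel_fom2
    work <- ledger_append(work, pick, vals, iteration = max(work$iteration),
                          source = "believer")

    # remove the exact chosen point from future picks so batch points stay distinct
    keep <- !duplicated(rbind(pick, avail$points))[-1L]
    avail$points <- avail$points[keep, , drop = FALSE]
    avail$standardized <- avail$standardized[keep, , drop = FALSE]
    if (nrow(avail$points) == 0L && b < q) { exhausted <- TRUE; break }
  }

  if (nrow(chosen) < q) exhausted <- TRUE
  structure(list(points = chosen, scores = scores_out,
                 excluded_counts = excluded, fallback = fallback,
                 exhausted = exhausted, config = config),
            class = "batch_proposal")
}

#' @export
print.batch_proposal <- function(x, ...) {
  cat(sprintf("Batch proposal: %d point(s), strategy '%s'%s\n",
              nrow(x$points), x$config$strategy,
              if (x$exhausted) " [candidate set exhausted early]" else ""))
  df <- as.data.frame(x$points)
  df$acq_score <- signif(x$scores, 4)
  if (x$config$strategy == "boa1") df$excluded <- x$excluded_counts
  print(df, row.names = FALSE)
  invisible(x)
}
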