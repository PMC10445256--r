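#' Create an empty experiment ledger
#'
#' The ledger is the campaign's single source of truth: one row per reaction
#' condition, with the variable columns in native units followed by the
#' figure(s) of merit, the iteration index and a `source` tag. `source` is
#' `"proposed"` for suggested-but-unmeasured rows, `"measured"` for completed
#' experiments, and `"believer"` for in-memory Kriging-believer
#' pseudo-observations (these never persist to disk).
#'
#' @param space a [design_space()].
#' @param fom name of the primary figure of merit column (e.g. `"TON"`).
#' @param fom2 optional name of a second figure of merit (e.g.
#'   `"selectivity"`).
#' @return a zero-row data frame with the ledger columns.
#' @export
new_ledger <- function(space, fom = "TON", fom2 = NULL) {
  nms <- variable_names(space)
  cols <- c(as.list(stats::setNames(rep(list(numeric(0)), length(nms)), nms)),
            stats::setNames(list(numeric(0)), fom))
  if (!is.null(fom2)) cols <- c(cols, stats::setNames(list(numeric(0)), fom2))
  cols$iteration <- integer(0)
  cols$source <- character(0)
  out <- as.data.frame(cols, check.names = FALSE)
  attr(out, "fom") <- fom
  attr(out, "fom2") <- fom2
  out
}

ledger_fom <- function(ledger, default = "TON") attr(ledger, "fom") %||% default

# variable columns = everything before the first FoM column
ledger_vars <- function(ledger, space) {
  nms <- variable_names(space)
  missing <- setdiff(nms, names(ledger))
  if (length(missing))
    stop_reactbo(paste("ledger lacks variable column(s):",
                       paste(missing, collapse = ", ")), "reactbo_bad_ledger")
  nms
}

ledger_points <- function(ledger, space, which = NULL) {
  rows <- if (is.null(which)) seq_len(nrow(ledger)) else which
  as.matrix(ledger[rows, ledger_vars(ledger, space), drop = FALSE])
}

measured_rows <- function(ledger) which(ledger$source == "measured")

#' Append rows to a ledger
#'
#' @param ledger ledger data frame.
#' @param points matrix of conditions (native units).
#' @param fom_values named list of FoM vectors (may be `NA` for proposals).
#' @param iteration iteration index.
#' @param source one of `"proposed"`, `"measured"`, `"believer"`.
#' @return the extended ledger.
#' @export
ledger_append <- function(ledger, points, fom_values = list(), iteration = 0L,
                          source = "proposed") {
  stopifnot(source %in% c("proposed", "measured", "believer"))
  points <- as.matrix(points)
  n <- nrow(points)
  var_cols <- utils::head(names(ledger), ncol(points))
  if (is.null(colnames(points))) colnames(points) <- var_cols
  if (!setequal(colnames(points), var_cols))
    stop_reactbo("point columns do not match the ledger's variables",
                 "reactbo_bad_ledger")
  new <- as.data.frame(points[, var_cols, drop = FALSE])
  fom_cols <- setdiff(names(ledger), c(var_cols, "iteration", "source"))
  for (fc in fom_cols)
    new[[fc]] <- if (!is.null(fom_values[[fc]])) as.numeric(fom_values[[fc]]) else NA_real_
  new$iteration <- as.integer(iteration)
  new$source <- source
  out <- rbind(ledger, new[, names(ledger), drop = FALSE])
  attributes(out)[c("fom", "fom2")] <- attributes(ledger)[c("fom", "fom2")]
  rownames(out) <- NULL
  out
}

#' Write a ledger to CSV
#'
#' Believer rows are in-memory artifacts of batch selection and are dropped
#' before writing; a ledger file only ever contains proposed and measured rows.
#'
#' @param ledger ledger data frame.
#' @param path output CSV path.
#' @param force overwrite an existing file.
#' @export
write_ledger <- function(ledger, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop_reactbo(sprintf("ledger file '%s' exists; use force = TRUE to overwrite",
                         path), "reactbo_ledger_exists")
  utils::write.csv(ledger[ledger$source != "believer", , drop = FALSE],
                   path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a ledger CSV
#'
#' @param path CSV path.
#' @param fom,fom2 FoM column names (recorded as attributes).
#' @return ledger data frame.
#' @export
read_ledger <- function(path, fom = "TON", fom2 = NULL) {
  out <- utils::read.csv(path, check.names = FALSE, na.strings = c("NA", ""))
  out$iteration <- as.integer(out$iteration)
  out$source <- as.character(out$source)
  attr(out, "fom") <- fom
  attr(out, "fom2") <- fom2
  out
}

#' Record measured FoM values for proposed rows
#'
#' Marks proposed rows as measured, filling in their figure-of-merit values.
#' Existing measured rows are never modified.
#'
#' @param ledger ledger data frame.
#' @param values named list mapping FoM column name to a numeric vector, one
#'   value per currently proposed row (in row order).
#' @return the updated ledger.
#' @export
record_measurements <- function(ledger, values) {
  idx <- which(ledger$source == "proposed")
  if (!length(idx))
    stop_reactbo("no proposed rows awaiting measurement", "reactbo_bad_ledger")
  for (fc in names(values)) {
    v <- as.numeric(values[[fc]])
    if (length(v) != length(idx))
      stop_reactbo(sprintf("expected %d values for '%s', got %d",
                           length(idx), fc, length(v)), "reactbo_bad_ledger")
    assert_finite(v, fc)
    ledger[[fc]][idx] <- v
  }
  ledger$source[idx] <- "measured"
  ledger
}

#' Best measured observation
#'
#' Returns the measured ledger row with the highest primary FoM, optionally
#' restricted to rows whose second FoM meets a threshold (e.g. best TON among
#' conditions with chemoselectivity >= 70 percent). Ties break to the earliest
#' row. Believer and proposed rows are never considered.
#'
#' @param ledger ledger data frame.
#' @param fom primary FoM column (default: the ledger's `fom` attribute).
#' @param fom2 optional second FoM column.
#' @param fom2_threshold optional threshold applied to `fom2` (`>=`).
#' @return a one-row data frame, or a zero-row data frame when no measured row
#'   passes the threshold.
#' @export
best_observed <- function(ledger, fom = NULL, fom2 = NULL, fom2_threshold = NULL) {
  fom <- fom %||% ledger_fom(ledger)
  idx <- measured_rows(ledger)
  if (!length(idx))
    stop_reactbo("ledger has no measured rows", "reactbo_bad_ledger")
  if (!is.null(fom2_threshold)) {
    fom2 <- fom2 %||% attr(ledger, "fom2")
    idx <- idx[!is.na(ledger[[fom2]][idx]) & ledger[[fom2]][idx] >= fom2_threshold]
  }
  if (!length(idx)) return(ledger[0L, , drop = FALSE])
  best <- idx[which.max(ledger[[fom]][idx])]
  ledger[best, , drop = FALSE]
}
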