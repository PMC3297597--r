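# Experiment sweep drivers: cross-product parameter grids around a base
# scenario, one fixation estimate or coexistence run per cell, CSV output
# with the full resolved parameter set in '#' comment header lines.

# Scalar model_params fields a sweep may vary.
sweepable_fields <- function() {
  setdiff(names(formals(model_params)), "competition")
}

# Cross product of axes as a data frame of cells, in row-major order over
# the axes as given (last axis fastest).
expand_axes <- function(axes) {
  if (length(axes) == 0L) stop("sweep needs at least one axis", call. = FALSE)
  bad <- setdiff(names(axes), sweepable_fields())
  if (length(bad) > 0L)
    stop("sweep axis is not a model parameter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid[, rev(seq_along(axes)), drop = FALSE]
}

# Flatten a params object into a one-row data frame of scalar columns.
params_row <- function(params) {
  x <- unclass(params)
  cp <- x$competition
  x$competition <- NULL
  row <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(cp)) row <- cbind(row, as.data.frame(unclass(cp)))
  row
}

#' Sweep fixation-frequency estimates over a parameter grid
#'
#' Runs [estimate_fixation_frequency()] once per cell of the cross product
#' of `axes`, each axis a named list entry `parameter = values` over scalar
#' [model_params()] fields.  By default every cell shares the base seed, so
#' replicate i sees common random numbers in every cell — the pairing used
#' by the monotonicity comparisons across an axis; set
#' `vary_seed_by_cell = TRUE` for independent cells.
#'
#' @param base_params A `model_params` object giving the fixed parameters.
#' @param axes Named list of parameter values to cross, e.g.
#'   `list(init_freq_f = seq(0, 1, 0.1), n_total = c(50, 200))`.
#' @param n_replicates Replicates per cell (default: the base params').
#' @param base_seed Root seed (default: the base params').
#' @param vary_seed_by_cell If `TRUE`, cell k uses
#'   `replicate_seed(base_seed, k)` as its own base seed.
#' @param engine Passed to [estimate_fixation_frequency()].
#' @param verbose Emit one progress message per cell on standard error.
#' @return A data frame of class `fixation_sweep`: one row per cell with
#'   all resolved parameter values, outcome counts, `rho_f`, the Wilson CI
#'   and the cell seed.
#' @export
run_fixation_sweep <- function(base_params, axes,
                               n_replicates = NULL, base_seed = NULL,
                               vary_seed_by_cell = FALSE,
                               engine = c("cpp", "r"),
                               verbose = FALSE) {
  engine <- match.arg(engine)
  validate_params(base_params)
  cells <- expand_axes(axes)
  if (is.null(n_replicates)) n_replicates <- base_params$n_replicates
  if (is.null(base_seed)) base_seed <- base_params$base_seed
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    p <- base_params
    for (nm in names(cells)) p[[nm]] <- cells[[nm]][k]
    p$base_seed <- if (vary_seed_by_cell)
      replicate_seed(base_seed, k) else as.integer(base_seed)
    p <- validate_params(p)
    if (verbose)
      message(sprintf("cell %d/%d: %s", k, nrow(cells),
                      paste(names(cells), unlist(cells[k, , drop = FALSE]),
                            sep = "=", collapse = ", ")))
    est <- estimate_fixation_frequency(p, n_replicates = n_replicates,
                                       engine = engine)
    rows[[k]] <- cbind(
      params_row(p),
      data.frame(n_replicates_run = est$n_replicates,
                 n_f_fixed = est$n_f_fixed, n_b_fixed = est$n_b_fixed,
                 n_timeout = est$n_timeout, n_extinct = est$n_extinct,
                 rho_f = est$rho_f, ci_low = est$ci_low,
                 ci_high = est$ci_high, seed = p$base_seed)
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fixation_sweep", class(out))
  out
}

#' Sweep coexistence trajectory experiments over a parameter grid
#'
#' Runs [run_coexistence_experiment()] once per cell of the cross product
#' of `axes`.  The base parameters must have competition enabled.
#'
#' @inheritParams run_fixation_sweep
#' @param n_seasons Seasons per trajectory.
#' @param window Trailing window for the summary statistics (default 100).
#' @return A data frame of class `coexistence_sweep`: one row per cell with
#'   all resolved parameter values, `seasons_run`, `window`,
#'   `mean_freq_f_window`, `sd_freq_f_window`, `persisted` and the cell
#'   seed.
#' @export
run_coexistence_sweep <- function(base_params, axes, n_seasons,
                                  window = 100L, base_seed = NULL,
                                  vary_seed_by_cell = FALSE,
                                  engine = c("cpp", "r"),
                                  verbose = FALSE) {
  engine <- match.arg(engine)
  validate_params(base_params)
  if (is.null(base_params$competition))
    stop("run_coexistence_sweep: competition (background fitness) must be ",
         "enabled in the base parameters", call. = FALSE)
  cells <- expand_axes(axes)
  if (is.null(base_seed)) base_seed <- base_params$base_seed
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    p <- base_params
    for (nm in names(cells)) p[[nm]] <- cells[[nm]][k]
    p$base_seed <- if (vary_seed_by_cell)
      replicate_seed(base_seed, k) else as.integer(base_seed)
    p <- validate_params(p)
    if (verbose)
      message(sprintf("cell %d/%d", k, nrow(cells)))
    cx <- run_coexistence_experiment(p, n_seasons = n_seasons,
                                     window = window, engine = engine)
    rows[[k]] <- cbind(
      params_row(p),
      data.frame(seasons_run = cx$seasons_run, window = cx$window,
                 mean_freq_f_window = cx$mean_freq_f_window,
                 sd_freq_f_window = cx$sd_freq_f_window,
                 persisted = cx$persisted, seed = p$base_seed)
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("coexistence_sweep", class(out))
  out
}

#' Write a results table as CSV with a reproducibility header
#'
#' Writes `header_lines` as `#`-prefixed comment lines (used for the full
#' resolved parameter set, so any row is reproducible from the file alone),
#' then the column header, then the data rows in their given order.
#' Floating-point columns are written at 8 significant digits.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param header_lines Character vector of comment lines (without the
#'   leading `#`).
#' @return `path`, invisibly.
#' @seealso [read_results_csv()]
#' @export
write_results_csv <- function(rows, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0L)
    writeLines(paste0("# ", header_lines), con)
  fmt <- rows
  for (nm in names(fmt)) {
    if (is.double(fmt[[nm]])) fmt[[nm]] <- signif(fmt[[nm]], 8)
  }
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results_csv()]
#' @param path CSV path.
#' @return A data frame (comment header lines are skipped).
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# One-line-per-field description of a parameter set for CSV headers.
params_header_lines <- function(params) {
  row <- params_row(params)
  c(paste0("fearbold results; resolved parameters:"),
    paste0(names(row), " = ", vapply(row, function(v) format(v[[1]]), "")))
}
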