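#' Write trajectories to CSV
#'
#' Plain-text trajectory exchange format: first column `time_min` on the
#' 5-minute grid, one column per cell (`cell_0001`, ...). A sidecar CSV of
#' per-cell failure flags is written when a path is given.
#'
#' @param x a `smad_ensemble` or list with `time` and `ratio`.
#' @param path output CSV path.
#' @param failures_path optional sidecar CSV (`cell`, `failed`,
#'   `fail_time`).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path, failures_path = NULL) {
  m <- ratio_matrix2(x)
  df <- data.frame(time_min = time_of(x), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(failures_path) && inherits(x, "smad_ensemble")) {
    utils::write.csv(data.frame(cell = colnames(m), failed = x$failed,
                                fail_time = x$fail_time),
                     failures_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Loader for externally measured (or previously written) nuc/cyt ratio
#' tables with a `time_min` column and one column per cell.
#'
#' @param path CSV path.
#' @param failures_path optional sidecar CSV of failure flags.
#' @return list with `time`, `ratio` (matrix), and `failed` when the
#'   sidecar is given.
#' @export
read_trajectories <- function(path, failures_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_min" %in% names(df)) stop("missing 'time_min' column")
  tt <- df$time_min
  if (length(tt) > 1 && stats::sd(diff(tt)) > 1e-8) {
    stop("time grid must be uniform")
  }
  m <- as.matrix(df[setdiff(names(df), "time_min")])
  out <- list(time = tt, ratio = m)
  if (!is.null(failures_path)) {
    fl <- utils::read.csv(failures_path)
    out$failed <- stats::setNames(as.logical(fl$failed), fl$cell)[colnames(m)]
  }
  out
}

#' Write a burst catalog to CSV
#'
#' @param catalog a `burst_catalog`.
#' @param bursts_path CSV of burst records (`cell_id`, `burst_index`,
#'   `peak_time_min`, `height`, `duration_min`).
#' @param cells_path optional CSV of per-cell summaries (`cell_id`,
#'   `count`, `auc`, `failed_flag`).
#' @return `bursts_path`, invisibly.
#' @export
write_burst_catalog <- function(catalog, bursts_path, cells_path = NULL) {
  b <- catalog$bursts
  utils::write.csv(data.frame(cell_id = b$cell, burst_index = b$burst_index,
                              peak_time_min = b$peak_time, height = b$height,
                              duration_min = b$duration),
                   bursts_path, row.names = FALSE)
  if (!is.null(cells_path)) {
    cc <- catalog$cells
    utils::write.csv(data.frame(cell_id = cc$cell, count = cc$count,
                                auc = cc$auc, failed_flag = cc$failed),
                     cells_path, row.names = FALSE)
  }
  invisible(bursts_path)
}

#' Write an objective report as JSON
#'
#' Named components, weights, raw and weighted values, and the scalar.
#'
#' @param objective a `smad_objective`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_objective_report <- function(objective, path) {
  jsonlite::write_json(list(
    components = objective,
    scalar = attr(objective, "scalar"),
    failure_rates = as.list(attr(objective, "failure_rates"))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
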