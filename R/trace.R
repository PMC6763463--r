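#' Per-cell intensity trace
#'
#' One scalar quantification per timepoint for one cell, e.g. the percentage
#' of endosomal photoactivated cargo residing in a Rab compartment, the
#' percent increase of plasma-membrane signal over baseline, or a vesicle
#' count.
#'
#' @param times_s ordered numeric times (s).
#' @param values numeric values, same length as `times_s`; `NA` marks frames
#'   where the quantity is undefined (e.g. empty photoactivation mask).
#' @param units unit string (e.g. `"percent"`, `"camera units"`,
#'   `"vesicles"`).
#' @param normalization `"raw"`, `"percent_of_endosomal"` or
#'   `"percent_increase_over_baseline"`.
#' @param cell_id,condition,experiment_id labels.
#' @return object of class `intensity_trace`.
#' @export
intensity_trace <- function(times_s, values, units = "camera units",
                            normalization = c("raw", "percent_of_endosomal",
                                              "percent_increase_over_baseline"),
                            cell_id = NA_character_, condition = NA_character_,
                            experiment_id = NA_character_) {
  normalization <- match.arg(normalization)
  times_s <- as.numeric(times_s); values <- as.numeric(values)
  if (length(times_s) != length(values))
    stop("times_s and values must have equal length")
  if (length(times_s) > 1L && any(diff(times_s) <= 0))
    stop("times_s must be strictly increasing")
  if (normalization == "percent_of_endosomal") {
    ok <- is.finite(values)
    if (any(values[ok] < -1e-9 | values[ok] > 100 + 1e-9))
      stop("percent_of_endosomal values must lie in [0, 100]")
  }
  structure(list(times_s = times_s, values = values, units = units,
                 normalization = normalization, cell_id = cell_id,
                 condition = condition, experiment_id = experiment_id),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace [%s, %s]: %d timepoints, t = %.3g .. %.3g s\n",
              x$units, x$normalization, length(x$times_s),
              min(x$times_s), max(x$times_s)))
  fin <- x$values[is.finite(x$values)]
  if (length(fin))
    cat(sprintf("  values: %.4g .. %.4g (mean %.4g)\n",
                min(fin), max(fin), mean(fin)))
  invisible(x)
}

#' @export
plot.intensity_trace <- function(x, ..., xlab = "time (s)", ylab = NULL,
                                 type = "l") {
  if (is.null(ylab)) ylab <- x$units
  plot(x$times_s, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.intensity_trace <- function(x, ...) {
  data.frame(cell_id = x$cell_id, condition = x$condition,
             experiment_id = x$experiment_id, time_s = x$times_s,
             value = x$values, units = x$units,
             stringsAsFactors = FALSE)
}

#' Mean of a trace over a time window
#'
#' Arithmetic mean of the values with `t0_s <= t <= t1_s` (both ends
#' inclusive), e.g. the 900-1200 s plateau mean of a recycling trace.
#' Non-finite values are excluded.
#'
#' @param trace an [intensity_trace()].
#' @param t0_s,t1_s window bounds in seconds.
#' @return numeric scalar.
#' @export
window_mean <- function(trace, t0_s, t1_s) {
  stopifnot(inherits(trace, "intensity_trace"), t0_s <= t1_s)
  sel <- trace$times_s >= t0_s & trace$times_s <= t1_s
  if (!any(sel)) stop("no timepoints in window [", t0_s, ", ", t1_s, "] s")
  v <- trace$values[sel]
  if (!any(is.finite(v))) stop("window contains no finite values")
  mean(v[is.finite(v)])
}

#' Tidy results table
#'
#' Long-format results: one row per (experiment, cell, condition, metric,
#' time) with a value and its units. Keys `(cell_id, metric_name, time_s)`
#' must be unique and units non-empty.
#'
#' @param experiment_id,cell_id,condition,metric_name character columns.
#' @param time_s numeric column (`NA` for time-free metrics).
#' @param value numeric column.
#' @param units character column (non-empty).
#' @return `data.frame` of class `results_table`.
#' @export
results_table <- function(experiment_id, cell_id, condition, metric_name,
                          time_s, value, units) {
  tab <- data.frame(experiment_id = as.character(experiment_id),
                    cell_id = as.character(cell_id),
                    condition = as.character(condition),
                    metric_name = as.character(metric_name),
                    time_s = as.numeric(time_s),
                    value = as.numeric(value),
                    units = as.character(units),
                    stringsAsFactors = FALSE)
  validate_results_table(tab)
  class(tab) <- c("results_table", "data.frame")
  tab
}

#' @rdname results_table
#' @param tab a results table (data.frame with the columns above).
#' @export
validate_results_table <- function(tab) {
  req <- c("experiment_id", "cell_id", "condition", "metric_name",
           "time_s", "value", "units")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(tab$units) | is.na(tab$units)))
    stop("units must be non-empty")
  key <- paste(tab$cell_id, tab$metric_name, tab$time_s, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cell_id, metric_name, time_s) keys")
  invisible(tab)
}

#' Write / read a results table as CSV
#'
#' Stable column order, UTF-8, "." decimal separator; a round trip
#' reproduces the table exactly (to numeric print precision 15 digits).
#'
#' @param tab a [results_table()].
#' @param path CSV path.
#' @return [read_results()] returns a `results_table`; [write_results()]
#'   returns `path` invisibly.
#' @export
write_results <- function(tab, path) {
  validate_results_table(tab)
  cols <- c("experiment_id", "cell_id", "condition", "metric_name",
            "time_s", "value", "units")
  df <- as.data.frame(tab)[, cols]
  # 17 significant digits make the double round trip exact
  df$time_s <- ifelse(is.na(df$time_s), NA,
                      formatC(df$time_s, digits = 17, format = "g"))
  df$value <- ifelse(is.na(df$value), NA,
                     formatC(df$value, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  results_table(df$experiment_id, df$cell_id, df$condition, df$metric_name,
                df$time_s, df$value, df$units)
}
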