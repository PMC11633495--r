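# Time-series container shared by all three simulators.

#' Quantity-of-interest trajectory on a fixed time grid
#'
#' Light S3 container for a simulated or observed quantity of interest:
#' mean degradation depth (MDD, um), elemental weight percentages in the
#' degradation layer (wt%), volume loss (VL, %) or degradation rate
#' (DR, mm/yr).
#'
#' @param times Numeric vector of times in days, strictly increasing.
#' @param values Numeric vector or matrix of QoI values; rows match `times`.
#' @param qoi_label Character label, e.g. `"MDD_um"` or `"VL_percent"`.
#' @return An object of class `mguq_ts`.
#' @export
time_series <- function(times, values, qoi_label = "qoi") {
  if (!is.numeric(times) || any(!is.finite(times)))
    stop("'times' must be finite numeric", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(values) != length(times))
    stop("length of 'values' must match 'times'", call. = FALSE)
  structure(list(times = times, values = values, qoi_label = qoi_label),
            class = "mguq_ts")
}

#' @export
print.mguq_ts <- function(x, ...) {
  cat(sprintf("<mguq_ts> %s: %d time points over [%g, %g] days, %d column(s)\n",
              x$qoi_label, length(x$times), min(x$times), max(x$times),
              ncol(x$values)))
  invisible(x)
}

#' @export
as.data.frame.mguq_ts <- function(x, ...) {
  df <- data.frame(time_days = x$times)
  v <- x$values
  if (is.null(colnames(v)))
    colnames(v) <- if (ncol(v) == 1) x$qoi_label else
      paste0(x$qoi_label, "_", seq_len(ncol(v)))
  cbind(df, as.data.frame(v))
}

#' Write a time series to CSV
#'
#' Columns are `time_days` followed by one column per QoI component.
#'
#' @param ts A [time_series()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path) {
  stopifnot(inherits(ts, "mguq_ts"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Read a time series written by [write_time_series()]
#'
#' @param path CSV file path.
#' @param qoi_label Optional label override; defaults to the first QoI column
#'   name.
#' @return A [time_series()] object.
#' @export
read_time_series <- function(path, qoi_label = NULL) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_days")
    stop("first column must be 'time_days'", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  time_series(df$time_days, vals,
              qoi_label = qoi_label %||% colnames(vals)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# interpolate a single-column series at requested days
ts_at <- function(ts, days) {
  stats::approx(ts$times, ts$values[, 1], xout = days, rule = 2)$y
}
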