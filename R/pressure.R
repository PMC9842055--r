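# Airway-pressure traces: the ventilator-side signal recorded simultaneously
# with the intrapleural sound. Stored as a tibble (time_s, pressure_cmh2o)
# with the ambient pressure carried as an attribute.

#' Construct an airway-pressure trace
#'
#' @param time_s Strictly increasing times in seconds.
#' @param pressure_cmh2o Airway pressure in cmH2O, same length as `time_s`.
#' @param ambient_cmh2o Ambient (pleural-side) pressure in cmH2O; default 0.
#'   The driving pressure difference is `max(pressure) - ambient`.
#' @return A `pressure_trace` tibble with columns `time_s`, `pressure_cmh2o`.
#' @examples
#' tr <- pressure_trace(c(0, 0.1, 0.2), c(5, 16.2, 5))
#' delta_p(tr)
#' @export
pressure_trace <- function(time_s, pressure_cmh2o, ambient_cmh2o = 0) {
  abort_if(length(time_s) != length(pressure_cmh2o),
           "`time_s` and `pressure_cmh2o` must have the same length",
           class = "airleakr_argument_error")
  abort_if(length(time_s) < 1L, "trace must contain at least one sample",
           class = "airleakr_argument_error")
  abort_if(any(!is.finite(time_s)) || any(!is.finite(pressure_cmh2o)),
           "times and pressures must be finite", class = "airleakr_argument_error")
  abort_if(any(diff(time_s) <= 0), "`time_s` must be strictly increasing",
           class = "airleakr_argument_error")
  check_number(ambient_cmh2o, "ambient_cmh2o")
  out <- tibble(time_s = as.double(time_s), pressure_cmh2o = as.double(pressure_cmh2o))
  attr(out, "ambient_cmh2o") <- ambient_cmh2o
  class(out) <- c("pressure_trace", class(out))
  out
}

#' Driving pressure difference of a trace
#'
#' Peak airway pressure minus ambient pressure (cmH2O), the force driving air
#' through a pleural defect during positive-pressure ventilation.
#'
#' @param trace A [pressure_trace()].
#' @return Pressure difference in cmH2O.
#' @export
delta_p <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  max(trace$pressure_cmh2o) - attr(trace, "ambient_cmh2o")
}

#' Read an airway-pressure CSV
#'
#' Expects a comma-separated file with header columns `time_s` and
#' `pressure_cmH2O` ('.' decimal separator). Times must be strictly
#' increasing; duplicate or non-monotone timestamps and non-numeric cells are
#' rejected with the offending row reported.
#'
#' @param path Path to the CSV file.
#' @param ambient_cmh2o Ambient pressure in cmH2O (not stored in the file).
#' @return A [pressure_trace()].
#' @export
read_pressure_csv <- function(path, ambient_cmh2o = 0) {
  abort_if(!file.exists(path), "file not found: ", path, class = "airleakr_io_error")
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("time_s", "pressure_cmH2O"), names(df))
  abort_if(length(missing) > 0,
           "missing column(s): ", paste(missing, collapse = ", "),
           class = "airleakr_format_error")
  parse_col <- function(col, name) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    abort_if(length(bad) > 0, "non-numeric ", name, " in row ", bad[1],
             class = "airleakr_format_error")
    v
  }
  t <- parse_col("time_s", "time_s")
  p <- parse_col("pressure_cmH2O", "pressure_cmH2O")
  bad <- which(diff(t) <= 0)
  abort_if(length(bad) > 0,
           "times not strictly increasing at row ", bad[1] + 1L,
           class = "airleakr_format_error")
  pressure_trace(t, p, ambient_cmh2o = ambient_cmh2o)
}

#' Write an airway-pressure CSV
#'
#' Inverse of [read_pressure_csv()]: writes the fixed `time_s,pressure_cmH2O`
#' schema.
#'
#' @param trace A [pressure_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(trace, path) {
  stopifnot(inherits(trace, "pressure_trace"))
  df <- data.frame(time_s = trace$time_s, pressure_cmH2O = trace$pressure_cmh2o,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
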