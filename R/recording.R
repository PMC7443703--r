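#' Multichannel phantom recording
#'
#' The universal currency of the pipeline: a channels x samples matrix in
#' Tesla with its sampling rate, sensor geometry and condition label.
#'
#' @param data Numeric matrix, channels x samples, Tesla; all finite.
#' @param fs Sampling rate, Hz.
#' @param sensors A [make_sensor_array()] object with as many channels as
#'   `data` has rows.
#' @param condition One of `"reference"`, `"dmw"`, `"dsmw"`, `"empty_room"`.
#' @param t0 Start time in seconds (defaults to 0).
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, sensors,
                      condition = c("reference", "dmw", "dsmw", "empty_room"),
                      t0 = 0) {
  condition <- match.arg(condition)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix")
  }
  if (anyNA(data) || !all(is.finite(data))) {
    stop("recording data must contain only finite values")
  }
  if (nrow(data) != n_sensors(sensors)) {
    stop("channel count of data does not match the sensor array")
  }
  structure(
    list(data = data, fs = fs, sensors = sensors, condition = condition,
         t0 = t0),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording:%s> %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [recording()].
#' @return Seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

with_data <- function(rec, data) {
  rec$data <- data
  rec
}
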