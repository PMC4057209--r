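#' Paired MAP/MCAv recording
#'
#' Container for one uniformly sampled, paired recording of mean arterial
#' blood pressure (MAP, mmHg) and middle cerebral artery blood flow velocity
#' (MCAv, cm/s), together with its sampling rate and study metadata. All
#' analysis stages consume and return this class.
#'
#' Gaps are an ingest error: the two channels must be equal-length, finite
#' numeric vectors with no missing samples. Imputation is deliberately not
#' offered, because interpolated samples would bias the cross-spectral phase.
#'
#' @param map Numeric vector, mean arterial pressure in mmHg.
#' @param mcav Numeric vector, blood flow velocity in cm/s; same length as
#'   `map`.
#' @param sampling_rate Sampling rate in Hz (> 0), shared by both channels.
#' @param time Optional time stamps in seconds. If omitted, a uniform grid
#'   starting at 0 is constructed. If supplied it must be a uniform grid
#'   consistent with `sampling_rate`.
#' @param subject_id Subject label.
#' @param condition `"baseline"` or `"LPS"`.
#' @param intervention `"normoxia"`, `"hyperoxia"` or `"hypoxia"`.
#'
#' @return An object of class `hemodynamic_recording`: a list with elements
#'   `time`, `map`, `mcav`, `sampling_rate`, `subject_id`, `condition`,
#'   `intervention`.
#' @export
hemodynamic_recording <- function(map, mcav, sampling_rate, time = NULL,
                                  subject_id = NA_character_,
                                  condition = NA_character_,
                                  intervention = NA_character_) {
  if (length(map) != length(mcav)) {
    stop_dcar("MAP and MCAv channels must have equal length.", "dcar_ingest_error")
  }
  if (length(map) < 1L) {
    stop_dcar("Recording must contain at least one sample.", "dcar_ingest_error")
  }
  assert_positive_scalar(sampling_rate, "sampling_rate", "dcar_ingest_error")
  if (anyNA(map) || anyNA(mcav) || !all(is.finite(map)) || !all(is.finite(mcav))) {
    stop_dcar(
      "Recording contains missing or non-finite samples; gaps are rejected at ingest.",
      "dcar_ingest_error"
    )
  }
  n <- length(map)
  if (is.null(time)) {
    time <- (seq_len(n) - 1L) / sampling_rate
  } else {
    if (length(time) != n) {
      stop_dcar("`time` must match the channel length.", "dcar_ingest_error")
    }
    dt <- diff(time)
    if (n > 1L && (any(dt <= 0) ||
                   max(abs(dt - 1 / sampling_rate)) > 1e-6 / sampling_rate)) {
      stop_dcar(
        "`time` is not a uniform grid at `sampling_rate`; gappy recordings are rejected.",
        "dcar_ingest_error"
      )
    }
  }
  structure(
    list(
      time = as.double(time), map = as.double(map), mcav = as.double(mcav),
      sampling_rate = as.double(sampling_rate),
      subject_id = subject_id, condition = condition, intervention = intervention
    ),
    class = "hemodynamic_recording"
  )
}

#' @export
print.hemodynamic_recording <- function(x, ...) {
  cat(sprintf(
    "<hemodynamic_recording> %s / %s / %s: %d samples at %g Hz (%.1f s)\n",
    x$subject_id, x$condition, x$intervention,
    length(x$map), x$sampling_rate, recording_duration(x)
  ))
  invisible(x)
}

#' Recording duration in seconds
#'
#' @param rec A [hemodynamic_recording()].
#' @return Duration in seconds (`n / sampling_rate`).
#' @export
recording_duration <- function(rec) {
  length(rec$map) / rec$sampling_rate
}

#' @export
as.data.frame.hemodynamic_recording <- function(x, ...) {
  data.frame(time_s = x$time, map_mmHg = x$map, mcav_cm_s = x$mcav)
}
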