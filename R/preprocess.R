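#' Extract the trailing analysis window of a recording
#'
#' Keeps the last `window_s` seconds of a recording, the steady-state stretch
#' used for spectral analysis (by default the last 10 minutes of an
#' intervention). Metadata and absolute time stamps are preserved, so the
#' operation is idempotent.
#'
#' @param rec A [hemodynamic_recording()].
#' @param window_s Window length in seconds (default 600).
#' @return A [hemodynamic_recording()] of exactly `window_s` seconds.
#' @export
extract_analysis_window <- function(rec, window_s = 600) {
  assert_positive_scalar(window_s, "window_s")
  n <- length(rec$map)
  n_keep <- as.integer(round(window_s * rec$sampling_rate))
  if (n < n_keep) {
    stop_dcar(
      sprintf(
        "Recording is %.1f s long but a %.1f s window was requested (short by %.1f s).",
        n / rec$sampling_rate, window_s, (n_keep - n) / rec$sampling_rate
      ),
      "dcar_insufficient_data"
    )
  }
  if (n == n_keep) return(rec)
  idx <- (n - n_keep + 1L):n
  hemodynamic_recording(
    map = rec$map[idx], mcav = rec$mcav[idx],
    sampling_rate = rec$sampling_rate, time = rec$time[idx],
    subject_id = rec$subject_id, condition = rec$condition,
    intervention = rec$intervention
  )
}

# Zero-phase FFT low-pass: unit gain up to pass_hz, raised-cosine roll-off to
# stop_hz, zero beyond. The channel mean is removed before filtering and
# restored afterwards so the mean is preserved exactly.
fft_lowpass <- function(x, fs, pass_hz, stop_hz) {
  n <- length(x)
  m <- mean(x)
  X <- stats::fft(x - m)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  g <- ifelse(
    f <= pass_hz, 1,
    ifelse(f >= stop_hz, 0, 0.5 * (1 + cos(pi * (f - pass_hz) / (stop_hz - pass_hz))))
  )
  Re(stats::fft(X * g, inverse = TRUE)) / n + m
}

#' Resample a recording to the spectral analysis rate
#'
#' Downsamples both channels to `target_rate` (default 10 Hz) with a
#' zero-phase anti-alias low-pass filter (unit passband to 1.5 Hz,
#' raised-cosine roll-off, fully attenuated beyond 2.5 Hz) followed by
#' interpolation onto the target grid. Zero phase matters here: the
#' MAP-to-MCAv phase difference is the headline quantity and must not be
#' shifted by the filter. Upsampling is refused rather than silently
#' interpolated.
#'
#' @param rec A [hemodynamic_recording()] sampled at >= `target_rate`.
#' @param target_rate Target sampling rate in Hz (default 10).
#' @return A [hemodynamic_recording()] at `target_rate`.
#' @export
resample_to_analysis_rate <- function(rec, target_rate = 10) {
  assert_positive_scalar(target_rate, "target_rate")
  fs <- rec$sampling_rate
  if (isTRUE(all.equal(fs, target_rate))) return(rec)
  if (fs < target_rate) {
    stop_dcar(
      sprintf(
        "Recording is sampled at %g Hz; upsampling to %g Hz is not supported.",
        fs, target_rate
      ),
      "dcar_unsupported_operation"
    )
  }
  n <- length(rec$map)
  duration <- n / fs
  n_new <- max(1L, as.integer(floor(duration * target_rate)))
  t_new <- rec$time[1L] + (seq_len(n_new) - 1L) / target_rate
  resample_channel <- function(x) {
    xf <- fft_lowpass(x, fs, pass_hz = 1.5, stop_hz = 2.5)
    stats::approx(rec$time, xf, xout = t_new, rule = 2)$y
  }
  hemodynamic_recording(
    map = resample_channel(rec$map), mcav = resample_channel(rec$mcav),
    sampling_rate = target_rate, time = t_new,
    subject_id = rec$subject_id, condition = rec$condition,
    intervention = rec$intervention
  )
}

#' Trailing-window mean of a channel
#'
#' Arithmetic mean over the last `window_s` seconds (default 240 s, i.e. the
#' last four minutes preceding a measurement point) of a channel or numeric
#' series. Used as the steady-state MCAv / MAP value for vasoreactivity.
#'
#' @param x A [hemodynamic_recording()] or a numeric series.
#' @param window_s Averaging window in seconds (default 240).
#' @param sampling_rate Required when `x` is a bare numeric vector.
#' @param channel Which channel to average when `x` is a recording.
#' @return The scalar mean of the trailing window.
#' @export
segment_mean <- function(x, window_s = 240, sampling_rate = NULL,
                         channel = c("mcav", "map")) {
  assert_positive_scalar(window_s, "window_s")
  if (inherits(x, "hemodynamic_recording")) {
    channel <- match.arg(channel)
    series <- x[[channel]]
    fs <- x$sampling_rate
  } else {
    if (is.null(sampling_rate)) {
      stop_dcar("`sampling_rate` is required for a bare numeric series.",
                "dcar_invalid_config")
    }
    series <- as.double(x)
    fs <- sampling_rate
  }
  n_keep <- as.integer(round(window_s * fs))
  if (length(series) < n_keep) {
    stop_dcar(
      sprintf(
        "Series is %.1f s long but a %.1f s averaging window was requested.",
        length(series) / fs, window_s
      ),
      "dcar_insufficient_data"
    )
  }
  mean(series[(length(series) - n_keep + 1L):length(series)])
}
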