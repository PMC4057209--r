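#' Welch estimator configuration
#'
#' Settings for segmented cross-spectral estimation: 1200-point segments at
#' 10 Hz (120 s), 60 s overlap between successive segments (50%), and a
#' Hanning taper to limit spectral leakage. With a 600 s analysis window
#' these defaults give nine segments.
#'
#' @param segment_length Segment length in samples (default 1200).
#' @param overlap_s Overlap between successive segments in seconds
#'   (default 60).
#' @param window Taper name; only `"hanning"` is provided.
#' @param sampling_rate Sampling rate of the analysed series in Hz
#'   (default 10).
#' @return A list of class `welch_config`.
#' @export
welch_config <- function(segment_length = 1200L, overlap_s = 60,
                         window = "hanning", sampling_rate = 10) {
  segment_length <- as.integer(segment_length)
  if (is.na(segment_length) || segment_length < 2L) {
    stop_dcar("`segment_length` must be an integer >= 2.", "dcar_invalid_config")
  }
  assert_positive_scalar(sampling_rate, "sampling_rate")
  overlap_n <- as.integer(round(overlap_s * sampling_rate))
  if (overlap_s < 0 || overlap_n >= segment_length) {
    stop_dcar(
      "`overlap_s` must satisfy 0 <= overlap_s * sampling_rate < segment_length.",
      "dcar_invalid_config"
    )
  }
  window <- match.arg(window, "hanning")
  structure(
    list(
      segment_length = segment_length, overlap_s = as.double(overlap_s),
      overlap_n = overlap_n, window = window,
      sampling_rate = as.double(sampling_rate)
    ),
    class = "welch_config"
  )
}

# Symmetric Hanning taper.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

#' Welch auto- and cross-spectral densities of a MAP/MCAv pair
#'
#' Splits the two series into overlapping segments, removes each segment's
#' mean, applies the Hanning taper, and averages one-sided auto- and
#' cross-spectral densities over segments with the usual window power
#' correction (density scale `2 / (fs * sum(w^2))`, halved at DC and
#' Nyquist). The cross-spectrum is `conj(FFT(map)) * FFT(mcav)`, so a
#' positive cross-spectral phase means MCAv leads MAP.
#'
#' @param map_series Numeric MAP series (mmHg) at `cfg$sampling_rate`.
#' @param mcav_series Numeric MCAv series (cm/s), same length.
#' @param cfg A [welch_config()].
#' @return An object of class `spectral_estimate`: list with `frequencies`
#'   (Hz, 0 to Nyquist), `s_map` (mmHg^2/Hz), `s_mcav` (cm^2 s^-2 / Hz),
#'   `s_cross` (complex, mmHg cm s^-1 / Hz), `n_segments`, `mean_map`,
#'   `mean_mcav`, and the `config` used.
#' @export
welch_cross_spectra <- function(map_series, mcav_series, cfg = welch_config()) {
  if (length(map_series) != length(mcav_series)) {
    stop_dcar("The two series must have equal length.", "dcar_invalid_config")
  }
  n <- length(map_series)
  L <- cfg$segment_length
  if (n < L) {
    stop_dcar(
      sprintf("Series of %d samples is shorter than one %d-sample segment.", n, L),
      "dcar_insufficient_data"
    )
  }
  step <- L - cfg$overlap_n
  n_seg <- (n - L) %/% step + 1L
  w <- hann_window(L)
  u <- sum(w^2)
  fs <- cfg$sampling_rate
  n_bins <- L %/% 2L + 1L
  bins <- seq_len(n_bins)

  s_map <- numeric(n_bins)
  s_mcav <- numeric(n_bins)
  s_cross <- complex(n_bins)
  for (k in seq_len(n_seg)) {
    idx <- ((k - 1L) * step + 1L):((k - 1L) * step + L)
    x <- map_series[idx]
    y <- mcav_series[idx]
    X <- stats::fft((x - mean(x)) * w)[bins]
    Y <- stats::fft((y - mean(y)) * w)[bins]
    s_map <- s_map + Re(X * Conj(X))
    s_mcav <- s_mcav + Re(Y * Conj(Y))
    s_cross <- s_cross + Conj(X) * Y
  }
  # one-sided density scaling; DC (and Nyquist for even L) are not doubled
  scale <- rep(2 / (fs * u * n_seg), n_bins)
  scale[1L] <- scale[1L] / 2
  if (L %% 2L == 0L) scale[n_bins] <- scale[n_bins] / 2
  structure(
    list(
      frequencies = (bins - 1L) * fs / L,
      s_map = s_map * scale, s_mcav = s_mcav * scale, s_cross = s_cross * scale,
      n_segments = n_seg,
      mean_map = mean(map_series), mean_mcav = mean(mcav_series),
      config = cfg
    ),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate> %d bins, df = %.5f Hz, %d segment(s)\n",
    length(x$frequencies), x$frequencies[2L] - x$frequencies[1L], x$n_segments
  ))
  invisible(x)
}

#' Per-frequency transfer function and coherence
#'
#' Derives, at each frequency bin, the transfer gain
#' `|S_xy| / S_xx` (cm s^-1 mmHg^-1), the MAP-to-MCAv phase difference
#' `Arg(S_xy)` in (-pi, pi] (positive = MCAv leads MAP, so a pure output
#' delay gives negative phase), and the magnitude-squared coherence
#' `|S_xy|^2 / (S_xx S_yy)`. Bins with zero MAP power are returned as `NA`
#' rather than infinite. Coherence from a single segment is identically 1
#' and therefore meaningless; it is returned as `NA` with a warning.
#'
#' @param est A `spectral_estimate` from [welch_cross_spectra()].
#' @return A tibble with columns `frequency`, `gain`, `phase`, `coherence`.
#' @export
transfer_function <- function(est) {
  stopifnot(inherits(est, "spectral_estimate"))
  defined <- est$s_map > 0 & est$s_mcav > 0
  gain <- phase <- coh <- rep(NA_real_, length(est$frequencies))
  gain[defined] <- Mod(est$s_cross[defined]) / est$s_map[defined]
  phase[defined] <- Arg(est$s_cross[defined])
  if (est$n_segments < 2L) {
    rlang::warn(
      "Coherence from a single Welch segment is identically 1 and carries no information; returning NA."
    )
  } else {
    coh[defined] <- Mod(est$s_cross[defined])^2 /
      (est$s_map[defined] * est$s_mcav[defined])
    coh <- pmin(pmax(coh, 0), 1)
  }
  tibble::tibble(frequency = est$frequencies, gain = gain, phase = phase,
                 coherence = coh)
}

#' Default analysis bands
#'
#' Very-low (0.02–0.07 Hz), low (0.07–0.20 Hz) and high (0.20–0.30 Hz)
#' frequency bands. Bins are assigned by half-open intervals
#' `[f_lo, f_hi)`, with the upper edge of HF closed at 0.30 Hz, so shared
#' band edges can never be double-counted.
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi`, `closed_upper`.
#' @export
default_bands <- function() {
  tibble::tibble(
    band = c("VLF", "LF", "HF"),
    f_lo = c(0.02, 0.07, 0.20),
    f_hi = c(0.07, 0.20, 0.30),
    closed_upper = c(FALSE, FALSE, TRUE)
  )
}

#' Band-averaged transfer function summaries
#'
#' Averages per-bin gain, phase and coherence across the bins of each
#' analysis band and integrates the MAP and MCAv spectral power over the
#' band (PSD x bin width, in mmHg^2 and cm^2 s^-2). Normalised gain is
#' `gain * mean(MAP) / mean(MCAv)` (percent MCAv change per percent MAP
#' change, dimensionless). A band is flagged valid when its band-averaged
#' coherence is at or above `coherence_threshold` (>= 0.4 by default);
#' gain/phase estimates from invalid bands should not be interpreted.
#'
#' @param tf Per-frequency tibble from [transfer_function()]; computed
#'   internally when `NULL`.
#' @param est A `spectral_estimate` from [welch_cross_spectra()].
#' @param bands Band definition tibble, see [default_bands()].
#' @param coherence_threshold Validity threshold on band coherence
#'   (default 0.4).
#' @return A tibble with one row per band: `band`, `f_lo`, `f_hi`,
#'   `n_bins`, `gain`, `normalised_gain`, `phase`, `coherence`,
#'   `map_power`, `mcav_power`, `valid`.
#' @export
band_average <- function(est, tf = NULL, bands = default_bands(),
                         coherence_threshold = 0.4) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (is.null(tf)) tf <- suppressWarnings(transfer_function(est))
  freq <- est$frequencies
  df <- freq[2L] - freq[1L]
  nyquist <- max(freq)
  if (any(bands$f_lo >= bands$f_hi) || any(bands$f_hi > nyquist + 1e-12)) {
    stop_dcar("Bands must satisfy 0 < f_lo < f_hi <= Nyquist.", "dcar_invalid_config")
  }
  nb <- nrow(bands)
  n_bins <- integer(nb)
  gain <- phase <- coh <- map_power <- mcav_power <- numeric(nb)
  for (i in seq_len(nb)) {
    idx <- which(freq >= bands$f_lo[i] - 1e-12 &
                   (freq < bands$f_hi[i] - 1e-12 |
                      (bands$closed_upper[i] &
                         abs(freq - bands$f_hi[i]) <= 1e-12)))
    if (length(idx) == 0L) {
      stop_dcar(
        sprintf(
          "Band %s [%g, %g] contains no frequency bins at resolution %.5f Hz.",
          bands$band[i], bands$f_lo[i], bands$f_hi[i], df
        ),
        "dcar_invalid_config"
      )
    }
    n_bins[i] <- length(idx)
    gain[i] <- mean(tf$gain[idx])
    phase[i] <- mean(tf$phase[idx])
    coh[i] <- mean(tf$coherence[idx])
    map_power[i] <- sum(est$s_map[idx]) * df
    mcav_power[i] <- sum(est$s_mcav[idx]) * df
  }
  tibble::tibble(
    band = bands$band, f_lo = bands$f_lo, f_hi = bands$f_hi, n_bins = n_bins,
    gain = gain,
    normalised_gain = gain * est$mean_map / est$mean_mcav,
    phase = phase, coherence = coh,
    map_power = map_power, mcav_power = mcav_power,
    valid = !is.na(coh) & coh >= coherence_threshold
  )
}

#' Qualitative autoregulation verdict between two band summaries
#'
#' Compares two valid band summaries (typically baseline vs. after an
#' intervention) metric by metric under the standard interpretation: an
#' increased MAP-to-MCAv phase difference, or a decreased transfer gain or
#' normalised gain, is evidence of enhanced dynamic autoregulation, and
#' vice versa. Verdicts are reported per metric and never fused into a
#' single score. If either summary fails the coherence validity criterion
#' the verdict is withheld.
#'
#' @param before,after Single-row band summaries from [band_average()] for
#'   the same band.
#' @param tol Absolute difference below which a metric is called
#'   `"unchanged"` (default 0).
#' @return A tibble with columns `metric`, `before`, `after`, `verdict`
#'   (`"enhanced"`, `"diminished"`, `"unchanged"` or `"withheld"`) and
#'   `reason`.
#' @export
interpret_direction <- function(before, after, tol = 0) {
  stopifnot(nrow(before) == 1L, nrow(after) == 1L)
  metrics <- c("gain", "normalised_gain", "phase")
  if (!isTRUE(before$valid) || !isTRUE(after$valid)) {
    bad <- c(if (!isTRUE(before$valid)) "before", if (!isTRUE(after$valid)) "after")
    reason <- sprintf(
      "coherence validity criterion not met in the '%s' summary",
      paste(bad, collapse = "' and '")
    )
    return(tibble::tibble(
      metric = metrics,
      before = as.double(unlist(before[, metrics])),
      after = as.double(unlist(after[, metrics])),
      verdict = "withheld", reason = reason
    ))
  }
  verdict_of <- function(metric) {
    d <- after[[metric]] - before[[metric]]
    if (abs(d) <= tol) return("unchanged")
    if (metric == "phase") {
      if (d > 0) "enhanced" else "diminished"
    } else {
      if (d < 0) "enhanced" else "diminished"
    }
  }
  tibble::tibble(
    metric = metrics,
    before = as.double(unlist(before[, metrics])),
    after = as.double(unlist(after[, metrics])),
    verdict = unname(vapply(metrics, verdict_of, character(1))),
    reason = NA_character_
  )
}
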