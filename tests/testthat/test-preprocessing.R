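make_rec <- function(duration, fs, map = NULL, mcav = NULL, seed = 1) {
  n <- round(duration * fs)
  withr::with_seed(seed, {
    if (is.null(map)) map <- 88 + rnorm(n)
    if (is.null(mcav)) mcav <- 72 + rnorm(n)
  })
  hemodynamic_recording(map, mcav, fs, subject_id = "s1",
                        condition = "baseline", intervention = "normoxia")
}

test_that("recordings with gaps or mismatched channels are rejected at ingest", {
  expect_error(hemodynamic_recording(c(1, NA, 3), c(1, 2, 3), 10),
               class = "dcar_ingest_error")
  expect_error(hemodynamic_recording(1:3, 1:4, 10), class = "dcar_ingest_error")
  expect_error(
    hemodynamic_recording(1:3, 1:3, 10, time = c(0, 0.1, 0.3)),
    class = "dcar_ingest_error"
  )
})

test_that("the trailing analysis window is extracted and is idempotent", {
  rec <- make_rec(1200, 10)
  win <- extract_analysis_window(rec, 600)
  expect_equal(recording_duration(win), 600)
  expect_equal(win$time[1], 600)
  expect_equal(win$map, rec$map[6001:12000])
  expect_identical(win$subject_id, "s1")
  # idempotent
  expect_identical(extract_analysis_window(win, 600), win)
  # exact-length boundary: returned unchanged
  rec600 <- make_rec(600, 10)
  expect_identical(extract_analysis_window(rec600, 600), rec600)
  expect_error(extract_analysis_window(make_rec(300, 10), 600),
               class = "dcar_insufficient_data")
})

test_that("resampling is the identity at the target rate and refuses upsampling", {
  rec <- make_rec(60, 10)
  expect_identical(resample_to_analysis_rate(rec, 10), rec)
  slow <- make_rec(60, 5)
  expect_error(resample_to_analysis_rate(slow, 10),
               class = "dcar_unsupported_operation")
})

test_that("a slow sinusoid survives resampling with < 1% amplitude distortion", {
  fs <- 1000
  t <- (0:(60 * fs - 1)) / fs
  map <- 88 + sin(2 * pi * 0.1 * t)
  rec <- hemodynamic_recording(map, map, fs)
  out <- resample_to_analysis_rate(rec, 10)
  expect_equal(out$sampling_rate, 10)
  tt <- out$time
  fit <- lm(out$map ~ sin(2 * pi * 0.1 * tt) + cos(2 * pi * 0.1 * tt))
  amplitude <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(amplitude, 1, tolerance = 0.01)
  # channel mean preserved within 0.1%
  expect_equal(mean(out$map), mean(map), tolerance = 1e-3)
})

test_that("out-of-band components are attenuated by at least 40 dB", {
  fs <- 1000
  t <- (0:(120 * fs - 1)) / fs
  for (f_bad in c(6, 9.9)) { # 9.9 Hz would alias onto 0.1 Hz at 10 Hz
    map <- 88 + sin(2 * pi * f_bad * t)
    rec <- hemodynamic_recording(map, map, fs)
    out <- resample_to_analysis_rate(rec, 10)
    expect_lt(var(out$map) / var(map), 1e-4)
  }
})

test_that("band power in 0.02-0.30 Hz is conserved through resampling", {
  fs <- 40
  t <- (0:(600 * fs - 1)) / fs
  map <- 88 + 2 * sin(2 * pi * 0.1 * t) + sin(2 * pi * 0.25 * t)
  rec <- hemodynamic_recording(map, map, fs)
  full_band <- tibble::tibble(band = "full", f_lo = 0.02, f_hi = 0.30,
                              closed_upper = TRUE)
  before <- band_average(
    welch_cross_spectra(map, map, welch_config(segment_length = 4800,
                                               sampling_rate = 40)),
    bands = full_band
  )$map_power
  out <- resample_to_analysis_rate(rec, 10)
  after <- band_average(
    welch_cross_spectra(out$map, out$map, welch_config()),
    bands = full_band
  )$map_power
  expect_equal(after, before, tolerance = 0.02)
})

test_that("segment_mean averages exactly the trailing window", {
  fs <- 10
  expect_equal(segment_mean(rep(70, 3000), 240, sampling_rate = fs), 70)
  # integer number of cycles on the trailing window: sinusoid averages out
  t <- (0:(2999)) / fs
  x <- 69 + sin(2 * pi * 0.1 * t) # 24 full cycles in 240 s
  expect_equal(segment_mean(x, 240, sampling_rate = fs), 69, tolerance = 1e-9)
  expect_error(segment_mean(rep(1, 1000), 240, sampling_rate = fs),
               class = "dcar_insufficient_data")
  expect_error(segment_mean(rep(1, 1000), 240), class = "dcar_invalid_config")
  # recording interface
  rec <- make_rec(600, 10, map = rep(90, 6000), mcav = rep(65, 6000))
  expect_equal(segment_mean(rec, 240, channel = "map"), 90)
  expect_equal(segment_mean(rec, 240, channel = "mcav"), 65)
})
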