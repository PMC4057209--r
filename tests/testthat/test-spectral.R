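test_that("welch configuration invariants are enforced", {
  expect_error(welch_config(segment_length = 1), class = "dcar_invalid_config")
  expect_error(welch_config(overlap_s = 120), class = "dcar_invalid_config")
  expect_silent(welch_config(overlap_s = 0))
})

test_that("single-segment estimates equal the brute-force DFT periodogram", {
  for (n in c(600L, 1200L)) {
    x <- withr::with_seed(n, 88 + rnorm(n))
    y <- withr::with_seed(n + 1L, 72 + rnorm(n))
    cfg <- welch_config(segment_length = n, overlap_s = 0, sampling_rate = 10)
    est <- welch_cross_spectra(x, y, cfg)
    oracle <- direct_hann_csd(x, y, 10)
    expect_identical(est$n_segments, 1L)
    expect_equal(est$frequencies, oracle$frequencies)
    expect_equal(est$s_map, oracle$s_x, tolerance = 1e-10)
    expect_equal(est$s_mcav, oracle$s_y, tolerance = 1e-10)
    expect_equal(est$s_cross, oracle$s_xy, tolerance = 1e-10)
  }
})

test_that("segmenting follows the 1200-point / 60 s overlap convention", {
  x <- withr::with_seed(2, rnorm(6000))
  est <- welch_cross_spectra(x, x, welch_config())
  expect_identical(est$n_segments, 9L) # 600 s at 10 Hz
  expect_equal(est$frequencies[2] - est$frequencies[1], 10 / 1200)
  expect_error(welch_cross_spectra(rnorm(1000), rnorm(1000), welch_config()),
               class = "dcar_insufficient_data")
})

test_that("constant channels have zero spectral density after mean removal", {
  est <- welch_cross_spectra(rep(88, 2400), rep(72, 2400), welch_config())
  expect_true(all(est$s_map == 0))
  expect_true(all(est$s_mcav == 0))
  expect_true(all(Mod(est$s_cross) == 0))
})

test_that("a unit sinusoid integrates to A^2/2 total power (Parseval)", {
  t <- (0:5999) / 10
  x <- 88 + sin(2 * pi * 0.1 * t)
  est <- welch_cross_spectra(x, x, welch_config())
  df <- est$frequencies[2] - est$frequencies[1]
  expect_equal(sum(est$s_map) * df, 0.5, tolerance = 0.05)
})

test_that("identity and scalar systems give exact gain, phase and coherence", {
  map <- withr::with_seed(3, 88 + rnorm(6000))
  est1 <- welch_cross_spectra(map, map, welch_config())
  tf1 <- transfer_function(est1)
  expect_equal(tf1$gain, rep(1, nrow(tf1)), tolerance = 1e-10)
  expect_equal(tf1$phase, rep(0, nrow(tf1)), tolerance = 1e-10)
  expect_equal(tf1$coherence, rep(1, nrow(tf1)), tolerance = 1e-10)

  est2 <- welch_cross_spectra(map, 2 * map, welch_config())
  tf2 <- transfer_function(est2)
  expect_equal(tf2$gain, rep(2, nrow(tf2)), tolerance = 1e-10)
  expect_equal(tf2$phase, rep(0, nrow(tf2)), tolerance = 1e-10)
})

test_that("the phase sign convention distinguishes output lag from lead", {
  map <- withr::with_seed(4, 88 + rnorm(6000))
  lagged <- c(map[1], map[-6000]) # MCAv delayed by one sample (0.1 s)
  est <- welch_cross_spectra(map, lagged, welch_config())
  tf <- transfer_function(est)
  sel <- tf$frequency > 0.02 & tf$frequency <= 1
  expect_equal(tf$phase[sel], -2 * pi * tf$frequency[sel] * 0.1,
               tolerance = 0.01)
  # a time-advanced output leads: positive phase
  led <- c(map[-1], map[6000])
  tf_led <- transfer_function(welch_cross_spectra(map, led, welch_config()))
  expect_true(all(tf_led$phase[sel] > 0))
})

test_that("Cauchy-Schwarz holds at every bin of random fixtures", {
  cfg <- welch_config(segment_length = 256, overlap_s = 12.8,
                      sampling_rate = 10)
  for (seed in 1:50) {
    xy <- withr::with_seed(seed, list(x = rnorm(1024), y = rnorm(1024)))
    est <- welch_cross_spectra(xy$x, xy$y, cfg)
    expect_true(all(Mod(est$s_cross)^2 <=
                      est$s_map * est$s_mcav * (1 + 1e-9)))
    coh <- transfer_function(est)$coherence
    expect_true(all(coh >= 0 & coh <= 1, na.rm = TRUE))
  }
})

test_that("single-segment coherence is reported as undefined with a warning", {
  x <- withr::with_seed(5, rnorm(1200))
  est <- welch_cross_spectra(x, x, welch_config())
  expect_warning(tf <- transfer_function(est), "single")
  expect_true(all(is.na(tf$coherence)))
})

test_that("band averages equal direct bin means and integrated powers", {
  cfg <- broadband_config(
    transfer_model("frequency_template", template = band_transfer_template()),
    output_noise_sd = 0.5, seed = 21
  )
  rec <- simulate_recording(cfg)
  est <- welch_cross_spectra(rec$map, rec$mcav, welch_config())
  tf <- transfer_function(est)
  ba <- band_average(est, tf = tf)
  df <- est$frequencies[2] - est$frequencies[1]
  for (i in seq_len(nrow(ba))) {
    idx <- which(est$frequencies >= ba$f_lo[i] - 1e-12 &
                   (est$frequencies < ba$f_hi[i] - 1e-12 |
                      (ba$band[i] == "HF" &
                         abs(est$frequencies - ba$f_hi[i]) <= 1e-12)))
    expect_equal(ba$gain[i], mean(tf$gain[idx]))
    expect_equal(ba$phase[i], mean(tf$phase[idx]))
    expect_equal(ba$coherence[i], mean(tf$coherence[idx]))
    expect_equal(ba$map_power[i], sum(est$s_map[idx]) * df)
  }
  # shared band edges are never double counted
  expect_identical(sum(ba$n_bins), length(which(
    est$frequencies >= 0.02 - 1e-12 & est$frequencies <= 0.30 + 1e-12
  )))
  # normalised gain definition
  expect_equal(ba$normalised_gain, ba$gain * est$mean_map / est$mean_mcav)
  # band powers are additive and bounded by the total integral
  expect_lte(sum(ba$map_power), sum(est$s_map) * df)
  expect_lte(sum(ba$mcav_power), sum(est$s_mcav) * df)
})

test_that("the coherence validity rule is a >= comparison at 0.4", {
  cfg <- broadband_config(
    transfer_model("frequency_template", template = band_transfer_template()),
    output_noise_sd = 0.5, seed = 22
  )
  rec <- simulate_recording(cfg)
  est <- welch_cross_spectra(rec$map, rec$mcav)
  lf_coh <- band_average(est)$coherence[2]
  # threshold exactly at the measured coherence: still valid (>= rule)
  expect_true(band_average(est, coherence_threshold = lf_coh)$valid[2])
  expect_false(band_average(est, coherence_threshold = lf_coh + 1e-9)$valid[2])
  # a noise-dominated recording fails the 0.4 criterion
  noisy <- simulate_recording(broadband_config(
    transfer_model("frequency_template", template = band_transfer_template()),
    output_noise_sd = 50, seed = 23
  ))
  expect_false(lf_summary(noisy)$valid)
})

test_that("bands with no bins at the current resolution are refused", {
  x <- withr::with_seed(6, rnorm(256))
  est <- welch_cross_spectra(x, x, welch_config(segment_length = 64,
                                                overlap_s = 3.2))
  expect_error(band_average(est), "resolution",
               class = "dcar_invalid_config")
})

test_that("direction verdicts follow the interpretation convention", {
  mk <- function(gain, ngain, phase, valid = TRUE, coherence = 0.9) {
    tibble::tibble(band = "LF", gain = gain, normalised_gain = ngain,
                   phase = phase, coherence = coherence, valid = valid)
  }
  # phase up, gains unchanged: enhanced autoregulation on phase only
  v <- interpret_direction(mk(1.26, 1.49, 0.58), mk(1.26, 1.49, 0.82))
  expect_identical(v$verdict[v$metric == "phase"], "enhanced")
  expect_identical(v$verdict[v$metric == "gain"], "unchanged")
  expect_identical(v$verdict[v$metric == "normalised_gain"], "unchanged")
  # gain up = diminished; identical summaries unchanged throughout
  v2 <- interpret_direction(mk(1.0, 1.2, 0.6), mk(1.3, 1.2, 0.6))
  expect_identical(v2$verdict[v2$metric == "gain"], "diminished")
  expect_true(all(interpret_direction(mk(1, 1, 1), mk(1, 1, 1))$verdict ==
                    "unchanged"))
  # an invalid summary withholds all verdicts with a reason
  v3 <- interpret_direction(mk(1, 1, 1), mk(1, 1, 1, valid = FALSE,
                                            coherence = 0.28))
  expect_true(all(v3$verdict == "withheld"))
  expect_match(v3$reason[1], "coherence")
})
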