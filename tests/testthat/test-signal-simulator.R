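test_that("a degenerate configuration yields a constant pressure trace", {
  cfg <- sim_config(
    duration = 30, map_setpoint = 88,
    oscillators = tibble::tibble(frequency = numeric(), amplitude = numeric(),
                                 phase = numeric()),
    background_noise_sd = 0, transfer_model = transfer_model("unity"),
    output_noise_sd = 0, seed = 1
  )
  map <- simulate_map(cfg)
  expect_length(map, 300L)
  expect_true(all(map == 88))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration = -5), class = "dcar_invalid_config")
  expect_error(sim_config(sampling_rate = 0), class = "dcar_invalid_config")
  expect_error(
    sim_config(oscillators = tibble::tibble(frequency = 0.1, amplitude = -1,
                                            phase = 0)),
    class = "dcar_invalid_config"
  )
  # Nyquist violation: oscillator faster than half the sampling rate
  expect_error(
    sim_config(sampling_rate = 10,
               oscillators = tibble::tibble(frequency = 6, amplitude = 1,
                                            phase = 0)),
    class = "dcar_invalid_config"
  )
})

test_that("a fixed seed reproduces the whole recording bitwise", {
  cfg <- sim_config(duration = 120, seed = 42)
  expect_identical(simulate_map(cfg), simulate_map(cfg))
  rec1 <- simulate_recording(cfg)
  rec2 <- simulate_recording(cfg)
  expect_identical(rec1$map, rec2$map)
  expect_identical(rec1$mcav, rec2$mcav)
  cfg2 <- sim_config(duration = 120, seed = 43)
  expect_false(identical(simulate_map(cfg), simulate_map(cfg2)))
})

test_that("a pure Mayer oscillation carries A^2/2 of band-integrated power", {
  cfg <- pure_tone_config(frequency = 0.1, amplitude = 3)
  map <- simulate_map(cfg)
  est <- welch_cross_spectra(map, map)
  ba <- band_average(est)
  expect_equal(ba$map_power[ba$band == "LF"], 3^2 / 2, tolerance = 0.05)
})

test_that("the unity model shifts the input to the velocity setpoint", {
  cfg <- sim_config(duration = 120, seed = 5, background_noise_sd = 1,
                    transfer_model = transfer_model("unity", mcav_setpoint = 72),
                    output_noise_sd = 0)
  map <- simulate_map(cfg)
  mcav <- simulate_mcav(map, cfg$transfer_model, 0, sampling_rate = 10)
  expect_equal(mcav, map - mean(map) + 72, tolerance = 1e-10)
})

test_that("a pure output delay realises the analytic phase response", {
  model <- transfer_model("pure_delay", delay = 0.1, mcav_setpoint = 72)
  cfg <- broadband_config(model, seed = 8)
  map <- simulate_map(cfg)
  mcav <- simulate_mcav(map, model, 0, sampling_rate = 10)
  est <- welch_cross_spectra(map, mcav)
  tf <- transfer_function(est)
  i01 <- which.min(abs(tf$frequency - 0.1))
  expect_equal(tf$frequency[i01], 0.1)
  expect_equal(tf$phase[i01], -2 * pi * 0.1 * 0.1, tolerance = 1e-4)
})

test_that("a frequency template round-trips through the full estimator", {
  model <- transfer_model(
    "frequency_template",
    template = band_transfer_template(gain_lf = 1.26, phase_lf = 0.80),
    mcav_setpoint = 72
  )
  cfg <- broadband_config(model, seed = 9)
  map <- simulate_map(cfg)
  mcav <- simulate_mcav(map, model, 0, sampling_rate = 10)
  est <- welch_cross_spectra(map, mcav)
  expect_identical(est$n_segments, 9L)
  lf <- band_average(est)[2, ]
  expect_equal(lf$phase, 0.80, tolerance = 0.05)
  expect_equal(lf$gain, 1.26, tolerance = 1.26 * 0.02)
})

test_that("a template not covering the analysis bands is rejected", {
  expect_error(
    transfer_model(
      "frequency_template",
      template = tibble::tibble(frequency = c(0.05, 0.1), gain = c(1, 1),
                                phase = c(0, 0))
    ),
    class = "dcar_invalid_config"
  )
  expect_error(
    transfer_model(
      "frequency_template",
      template = tibble::tibble(frequency = c(0.01, 0.01, 0.4),
                                gain = c(1, 1, 1), phase = c(0, 0, 0))
    ),
    class = "dcar_invalid_config"
  )
})

test_that("blood-gas panels honour targets, ordering and oxygen content", {
  eff0 <- cohort_effect_config(gas_rel_sd = 0, seed = 1)
  norm <- simulate_blood_gases(eff0, "baseline", "normoxia", seed = 1)
  hyper <- simulate_blood_gases(eff0, "baseline", "hyperoxia", seed = 2)
  hypo <- simulate_blood_gases(eff0, "baseline", "hypoxia", seed = 3)
  expect_equal(norm$paO2_kPa, 13.2)
  expect_equal(hyper$paO2_kPa, 28.5)
  expect_equal(hypo$paO2_kPa, 7.5)
  expect_true(hyper$paO2_kPa > norm$paO2_kPa && norm$paO2_kPa > hypo$paO2_kPa)

  eff <- cohort_effect_config(gas_rel_sd = 0.05, seed = 2)
  for (i in 1:20) {
    p <- simulate_blood_gases(eff, "LPS", "hypoxia", seed = i)
    expect_true(p$saO2_frac >= 0 && p$saO2_frac <= 1)
    expect_equal(p$caO2_mM, compute_cao2(p$saO2_frac, p$hb_mM, p$paO2_kPa))
  }
  expect_error(simulate_blood_gases(eff, "baseline", "normobaric"),
               class = "dcar_invalid_config")
})

test_that("cohort structure, determinism and the two-level seed contract hold", {
  eff <- cohort_effect_config(n_subjects = 2, duration = 60, seed = 3)
  coh <- simulate_cohort(eff)
  expect_length(coh$recordings, 2 * 2 * 3)
  expect_identical(nrow(coh$panels), 12L)
  expect_identical(nrow(coh$truth), 12L)

  # full determinism
  coh2 <- simulate_cohort(eff)
  expect_identical(coh$recordings[["sub01.baseline.normoxia"]]$map,
                   coh2$recordings[["sub01.baseline.normoxia"]]$map)

  # different realisation seed: new data, identical ground truth
  coh3 <- simulate_cohort(eff, realisation_seed = 99L)
  expect_false(identical(coh$recordings[["sub01.baseline.normoxia"]]$map,
                         coh3$recordings[["sub01.baseline.normoxia"]]$map))
  expect_identical(coh$truth, coh3$truth)

  # minimal cohort
  one <- simulate_cohort(cohort_effect_config(n_subjects = 1, duration = 60))
  expect_length(one$recordings, 6)
  expect_error(cohort_effect_config(n_subjects = 0),
               class = "dcar_invalid_config")
})

test_that("the condition effect raises the subject's true LF phase", {
  eff <- cohort_effect_config(n_subjects = 3, duration = 60,
                              between_subject_sd = 0, seed = 4)
  coh <- simulate_cohort(eff)
  tr <- coh$truth
  expect_true(all(tr$lf_phase_true[tr$condition == "baseline"] == 0.58))
  expect_true(all(tr$lf_phase_true[tr$condition == "LPS"] == 0.82))
})

test_that("output noise monotonically lowers band coherence", {
  mean_coh <- vapply(c(0.3, 1, 3), function(sd) {
    mean(vapply(1:4, function(seed) {
      cfg <- broadband_config(
        transfer_model("frequency_template",
                       template = band_transfer_template()),
        output_noise_sd = sd, seed = seed
      )
      rec <- simulate_recording(cfg)
      lf_summary(rec)$coherence
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_coh) < 0))
})
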