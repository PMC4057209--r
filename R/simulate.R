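#' Default spontaneous MAP oscillators
#'
#' Minimal oscillatory structure giving spectral power in all three
#' analysis bands: a slow vasomotor component at 0.05 Hz, a Mayer-wave
#' component at 0.10 Hz (amplitude 3 mmHg, so its band-integrated power
#' A^2/2 = 4.5 mmHg^2 is of the order of observed low-frequency MAP
#' spectral power), and a respiratory component at 0.25 Hz.
#'
#' @return A tibble with columns `frequency` (Hz), `amplitude` (mmHg),
#'   `phase` (rad).
#' @export
default_map_oscillators <- function() {
  tibble::tibble(
    frequency = c(0.05, 0.10, 0.25),
    amplitude = c(2, 3, 2),
    phase = c(0, 0, 0)
  )
}

#' Linear MAP-to-MCAv transfer model
#'
#' Ground-truth linear system used by the simulator to derive the MCAv
#' channel from MAP. Four kinds are supported:
#' * `"unity"` — identity response (gain 1, phase 0);
#' * `"scalar_gain"` — frequency-flat gain `gain_value`;
#' * `"pure_delay"` — gain `gain_value` and phase `-2 pi f delay`;
#' * `"frequency_template"` — gain and phase interpolated linearly in
#'   frequency between template nodes (constant extension outside), the
#'   fully general case used for cohort simulation.
#'
#' @param kind Model kind, see above.
#' @param gain_value Scalar gain in cm s^-1 mmHg^-1 (`scalar_gain`,
#'   `pure_delay`; default 1).
#' @param delay Delay of the output channel in seconds (`pure_delay`).
#' @param template Data frame with columns `frequency` (strictly
#'   increasing, Hz), `gain` (>= 0) and `phase` (rad, in (-pi, pi]);
#'   required for `frequency_template` and it must cover the analysis
#'   bands (0.02–0.30 Hz).
#' @param mcav_setpoint Mean MCAv of the simulated output channel (cm/s,
#'   default 72).
#' @return An object of class `transfer_model`.
#' @export
transfer_model <- function(kind = c("unity", "scalar_gain", "pure_delay",
                                    "frequency_template"),
                           gain_value = 1, delay = 0, template = NULL,
                           mcav_setpoint = 72) {
  kind <- match.arg(kind)
  if (gain_value < 0) {
    stop_dcar("`gain_value` must be >= 0.", "dcar_invalid_config")
  }
  assert_positive_scalar(mcav_setpoint, "mcav_setpoint")
  if (kind == "pure_delay" && (!is.finite(delay))) {
    stop_dcar("`delay` must be finite.", "dcar_invalid_config")
  }
  if (kind == "frequency_template") {
    if (is.null(template) ||
        !all(c("frequency", "gain", "phase") %in% names(template))) {
      stop_dcar(
        "`template` with columns frequency, gain, phase is required for kind = 'frequency_template'.",
        "dcar_invalid_config"
      )
    }
    if (any(diff(template$frequency) <= 0)) {
      stop_dcar("Template frequencies must be strictly increasing.",
                "dcar_invalid_config")
    }
    if (any(template$gain < 0)) {
      stop_dcar("Template gains must be >= 0.", "dcar_invalid_config")
    }
    if (any(template$phase <= -pi | template$phase > pi)) {
      stop_dcar("Template phases must lie in (-pi, pi].", "dcar_invalid_config")
    }
    if (min(template$frequency) > 0.02 || max(template$frequency) < 0.30) {
      stop_dcar(
        "Template must cover the analysis bands (0.02 to 0.30 Hz).",
        "dcar_invalid_config"
      )
    }
  }
  structure(
    list(kind = kind, gain_value = as.double(gain_value),
         delay = as.double(delay), template = template,
         mcav_setpoint = as.double(mcav_setpoint)),
    class = "transfer_model"
  )
}

#' Band-plateau frequency template
#'
#' Builds a `frequency_template` whose gain and phase are constant across
#' each analysis band, with narrow linear transitions placed between band
#' edges. Because every in-band frequency bin of the default Welch grid
#' sits on a plateau, the band-averaged ground truth equals the plateau
#' value exactly, which makes estimator recovery checks sharp. The default
#' shape is the usual high-pass autoregulation pattern: phase falls and
#' gain rises with frequency.
#'
#' @param gain_lf Low-frequency gain plateau (cm s^-1 mmHg^-1,
#'   default 1.26).
#' @param phase_lf Low-frequency phase plateau (rad, default 0.58).
#' @param gain_vlf,gain_hf Very-low- and high-frequency gain plateaus
#'   (defaults 0.75 and 1.15 times `gain_lf`).
#' @param phase_vlf,phase_hf Very-low- and high-frequency phase plateaus
#'   (defaults `phase_lf + 0.3` and `max(phase_lf - 0.4, 0.05)` rad).
#' @return A tibble usable as the `template` of [transfer_model()].
#' @export
band_transfer_template <- function(gain_lf = 1.26, phase_lf = 0.58,
                                   gain_vlf = 0.75 * gain_lf,
                                   gain_hf = 1.15 * gain_lf,
                                   phase_vlf = phase_lf + 0.3,
                                   phase_hf = max(phase_lf - 0.4, 0.05)) {
  tibble::tibble(
    frequency = c(0.000, 0.017, 0.023, 0.0675, 0.0730, 0.1925, 0.1980, 0.3100),
    gain = c(gain_vlf, gain_vlf, gain_vlf, gain_vlf, gain_lf, gain_lf,
             gain_hf, gain_hf),
    phase = c(0, 0, phase_vlf, phase_vlf, phase_lf, phase_lf,
              phase_hf, phase_hf)
  )
}

#' Simulator configuration for one recording
#'
#' @param duration Recording length in seconds (default 1200, i.e. a
#'   20-minute intervention).
#' @param sampling_rate Sampling rate in Hz (default 10); must exceed
#'   twice the fastest oscillator.
#' @param map_setpoint Mean arterial pressure in mmHg (default 88).
#' @param oscillators Tibble of sinusoidal MAP components
#'   (`frequency`, `amplitude`, `phase`), see [default_map_oscillators()].
#' @param background_noise_sd SD of broadband Gaussian MAP noise in mmHg
#'   (default 1).
#' @param transfer_model A [transfer_model()] generating MCAv from MAP.
#' @param output_noise_sd SD of independent Gaussian noise added to the
#'   MCAv channel (cm/s, default 0.5); this is the only mechanism that
#'   lowers coherence, so band coherence has the closed form
#'   `S_signal / (S_signal + S_noise)`.
#' @param seed Integer seed; the same seed reproduces the realisation
#'   bitwise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 1200, sampling_rate = 10, map_setpoint = 88,
                       oscillators = default_map_oscillators(),
                       background_noise_sd = 1,
                       transfer_model = dcar::transfer_model(
                         "frequency_template",
                         template = band_transfer_template()
                       ),
                       output_noise_sd = 0.5, seed = 1L) {
  assert_positive_scalar(duration, "duration")
  assert_positive_scalar(sampling_rate, "sampling_rate")
  assert_positive_scalar(map_setpoint, "map_setpoint")
  if (background_noise_sd < 0 || output_noise_sd < 0) {
    stop_dcar("Noise standard deviations must be >= 0.", "dcar_invalid_config")
  }
  if (nrow(oscillators) > 0) {
    if (any(oscillators$amplitude < 0)) {
      stop_dcar("Oscillator amplitudes must be >= 0.", "dcar_invalid_config")
    }
    if (sampling_rate <= 2 * max(oscillators$frequency)) {
      stop_dcar(
        "`sampling_rate` must exceed twice the fastest oscillator frequency.",
        "dcar_invalid_config"
      )
    }
  }
  stopifnot(inherits(transfer_model, "transfer_model"))
  structure(
    list(
      duration = as.double(duration), sampling_rate = as.double(sampling_rate),
      map_setpoint = as.double(map_setpoint), oscillators = oscillators,
      background_noise_sd = as.double(background_noise_sd),
      transfer_model = transfer_model,
      output_noise_sd = as.double(output_noise_sd), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a spontaneous MAP series
#'
#' Mean pressure plus deterministic sinusoidal oscillators (Mayer-wave,
#' respiratory, slow vasomotor components) plus broadband Gaussian noise.
#'
#' @param config A [sim_config()].
#' @return Numeric MAP series (mmHg) of length
#'   `duration * sampling_rate`; identical for identical seeds.
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$duration * config$sampling_rate))
  t <- (seq_len(n) - 1L) / config$sampling_rate
  x <- rep(config$map_setpoint, n)
  osc <- config$oscillators
  if (nrow(osc) > 0) {
    for (i in seq_len(nrow(osc))) {
      x <- x + osc$amplitude[i] * sin(2 * pi * osc$frequency[i] * t + osc$phase[i])
    }
  }
  if (config$background_noise_sd > 0) {
    x <- x + withr::with_seed(
      config$seed, rnorm(n, 0, config$background_noise_sd)
    )
  }
  x
}

# Complex frequency response of a transfer model at non-negative freqs (Hz).
freq_response <- function(model, f) {
  switch(
    model$kind,
    unity = rep(complex(real = 1), length(f)),
    scalar_gain = rep(complex(real = model$gain_value), length(f)),
    pure_delay = model$gain_value * exp(-2i * pi * f * model$delay),
    frequency_template = {
      g <- stats::approx(model$template$frequency, model$template$gain,
                         xout = f, rule = 2)$y
      p <- stats::approx(model$template$frequency, model$template$phase,
                         xout = f, rule = 2)$y
      g * exp(1i * p)
    }
  )
}

#' Simulate the MCAv channel from a MAP series
#'
#' Applies the model's frequency response to the mean-removed MAP series
#' by frequency-domain multiplication (linear interpolation between
#' template nodes, conjugate-symmetric extension to negative frequencies),
#' re-centres the output at the model's MCAv setpoint, and finally adds
#' independent Gaussian output noise. Because the noise enters after the
#' filter, the expected coherence at any frequency is
#' `S_signal / (S_signal + S_noise)`.
#'
#' @param map_series Uniformly sampled MAP series (mmHg).
#' @param model A [transfer_model()].
#' @param output_noise_sd SD of the additive output noise (cm/s).
#' @param seed Integer seed for the noise draw.
#' @param sampling_rate Sampling rate of `map_series` in Hz (default 10).
#' @return Numeric MCAv series (cm/s) of the same length.
#' @export
simulate_mcav <- function(map_series, model, output_noise_sd = 0, seed = 1L,
                          sampling_rate = 10) {
  stopifnot(inherits(model, "transfer_model"))
  if (output_noise_sd < 0) {
    stop_dcar("`output_noise_sd` must be >= 0.", "dcar_invalid_config")
  }
  n <- length(map_series)
  fs <- sampling_rate
  xc <- map_series - mean(map_series)
  f_all <- (seq_len(n) - 1L) * fs / n
  f_fold <- pmin(f_all, fs - f_all)
  H <- freq_response(model, f_fold)
  neg <- f_all > fs / 2
  H[neg] <- Conj(H[neg])
  H[1L] <- Re(H[1L])
  if (n %% 2L == 0L) H[n / 2L + 1L] <- Re(H[n / 2L + 1L])
  y <- Re(stats::fft(stats::fft(xc) * H, inverse = TRUE)) / n +
    model$mcav_setpoint
  if (output_noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(n, 0, output_noise_sd))
  }
  y
}

#' Simulate one paired MAP/MCAv recording
#'
#' Convenience wrapper generating MAP with [simulate_map()] and MCAv with
#' [simulate_mcav()] (the output-noise draw uses a seed derived from
#' `config$seed`, so the whole recording is reproducible from the config
#' alone).
#'
#' @param config A [sim_config()].
#' @param subject_id,condition,intervention Metadata carried on the
#'   returned recording.
#' @return A [hemodynamic_recording()].
#' @export
simulate_recording <- function(config, subject_id = "sim",
                               condition = "baseline",
                               intervention = "normoxia") {
  map <- simulate_map(config)
  mcav <- simulate_mcav(
    map, config$transfer_model, config$output_noise_sd,
    seed = derive_seed(config$seed, 1L), sampling_rate = config$sampling_rate
  )
  hemodynamic_recording(
    map = map, mcav = mcav, sampling_rate = config$sampling_rate,
    subject_id = subject_id, condition = condition, intervention = intervention
  )
}

#' Default blood-gas generator targets
#'
#' Median targets per condition and intervention for PaO2 (kPa), SaO2
#' (fraction), PaCO2 (kPa) and haemoglobin (mM) used by
#' [simulate_blood_gases()]. PaO2/SaO2/PaCO2 targets follow typical
#' normoxic (FiO2 21%), hyperoxic (40%) and hypoxic (12%) values in
#' healthy volunteers before and after endotoxin; the haemoglobin targets
#' are synthetic values back-solved so that the implied arterial oxygen
#' content matches the corresponding CaO2 levels.
#'
#' @return Nested list `targets[[condition]][[intervention]]`.
#' @export
default_gas_targets <- function() {
  list(
    baseline = list(
      normoxia = list(paO2 = 13.2, saO2 = 0.98, paCO2 = 5.7, hb = 8.44),
      hyperoxia = list(paO2 = 28.5, saO2 = 1.00, paCO2 = 5.6, hb = 8.44),
      hypoxia = list(paO2 = 7.5, saO2 = 0.90, paCO2 = 5.7, hb = 8.44)
    ),
    LPS = list(
      normoxia = list(paO2 = 11.6, saO2 = 0.98, paCO2 = 5.0, hb = 8.35),
      hyperoxia = list(paO2 = 26.7, saO2 = 1.00, paCO2 = 5.0, hb = 8.35),
      hypoxia = list(paO2 = 7.1, saO2 = 0.89, paCO2 = 4.8, hb = 8.35)
    )
  )
}

#' Cohort effect configuration
#'
#' Study-level ground truth for a simulated cohort: subjects, the
#' condition effect on low-frequency phase (median 0.58 rad at baseline
#' rising to 0.82 rad after systemic inflammation), between-subject
#' spreads, per-intervention blood-gas targets and oxygen-vasoreactivity
#' slopes, and the recording parameters. Subject-level parameter draws are
#' controlled by `seed` alone, so two realisations of the same config
#' share identical ground truth (see [simulate_cohort()]).
#'
#' @param n_subjects Number of subjects (default 10).
#' @param baseline_lf_phase,lps_lf_phase Cohort median low-frequency phase
#'   (rad) before and after the inflammatory condition (defaults 0.58 and
#'   0.82).
#' @param between_subject_sd SD of the subject-level phase offset in rad
#'   (default 0.19, consistent with the spread of reported low-frequency
#'   phases). The offset is common to both conditions (paired design).
#' @param gain_lf Median low-frequency gain, cm s^-1 mmHg^-1
#'   (default 1.26, unaffected by condition).
#' @param gain_between_subject_sd SD of the subject gain offset
#'   (default 0.15).
#' @param mcav_normoxia Named vector of normoxic MCAv setpoints per
#'   condition (cm/s; defaults baseline 72, LPS 69).
#' @param mcav_between_subject_sd SD of the subject MCAv offset (cm/s,
#'   default 6).
#' @param covr_slopes Signed oxygen-vasoreactivity slopes (% MCAv change
#'   per kPa PaO2 change) per condition and direction; the defaults
#'   (baseline: hyperoxia -0.7, hypoxia -1.1; LPS: -0.2, -2.1) reproduce a
#'   MCAv decrease under hyperoxia and increase under hypoxia.
#' @param covr_between_subject_sd SD of the subject slope offset
#'   (default 0.3 %/kPa).
#' @param gas_targets Nested list of blood-gas targets, see
#'   [default_gas_targets()].
#' @param gas_rel_sd Relative between-subject SD of blood-gas draws
#'   (default 0.02).
#' @param duration,sampling_rate,map_setpoint,background_noise_sd,output_noise_sd
#'   Recording parameters, see [sim_config()].
#' @param interventions Interventions to simulate (default all three).
#' @param seed Integer seed controlling the subject-level ground truth.
#' @return A list of class `cohort_effect_config`.
#' @export
cohort_effect_config <- function(n_subjects = 10,
                                 baseline_lf_phase = 0.58,
                                 lps_lf_phase = 0.82,
                                 between_subject_sd = 0.19,
                                 gain_lf = 1.26,
                                 gain_between_subject_sd = 0.15,
                                 mcav_normoxia = c(baseline = 72, LPS = 69),
                                 mcav_between_subject_sd = 6,
                                 covr_slopes = list(
                                   baseline = c(hyperoxia = -0.7, hypoxia = -1.1),
                                   LPS = c(hyperoxia = -0.2, hypoxia = -2.1)
                                 ),
                                 covr_between_subject_sd = 0.3,
                                 gas_targets = default_gas_targets(),
                                 gas_rel_sd = 0.02,
                                 duration = 1200, sampling_rate = 10,
                                 map_setpoint = 88, background_noise_sd = 1,
                                 output_noise_sd = 0.5,
                                 interventions = c("normoxia", "hyperoxia",
                                                   "hypoxia"),
                                 seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    stop_dcar("`n_subjects` must be >= 1.", "dcar_invalid_config")
  }
  sds <- c(between_subject_sd, gain_between_subject_sd, mcav_between_subject_sd,
           covr_between_subject_sd, gas_rel_sd)
  if (any(sds < 0)) {
    stop_dcar("Between-subject standard deviations must be >= 0.",
              "dcar_invalid_config")
  }
  interventions <- match.arg(interventions,
                             c("normoxia", "hyperoxia", "hypoxia"),
                             several.ok = TRUE)
  if (!"normoxia" %in% interventions) {
    stop_dcar("`interventions` must include the normoxic reference.",
              "dcar_invalid_config")
  }
  structure(
    list(
      n_subjects = n_subjects,
      baseline_lf_phase = baseline_lf_phase, lps_lf_phase = lps_lf_phase,
      between_subject_sd = between_subject_sd,
      gain_lf = gain_lf, gain_between_subject_sd = gain_between_subject_sd,
      mcav_normoxia = mcav_normoxia,
      mcav_between_subject_sd = mcav_between_subject_sd,
      covr_slopes = covr_slopes,
      covr_between_subject_sd = covr_between_subject_sd,
      gas_targets = gas_targets, gas_rel_sd = gas_rel_sd,
      duration = duration, sampling_rate = sampling_rate,
      map_setpoint = map_setpoint,
      background_noise_sd = background_noise_sd,
      output_noise_sd = output_noise_sd,
      interventions = interventions,
      seed = as.integer(seed)
    ),
    class = "cohort_effect_config"
  )
}

#' Simulate one blood-gas panel
#'
#' Draws PaO2, SaO2, PaCO2 and haemoglobin around the configured targets
#' for the requested condition and intervention (relative Gaussian
#' between-subject variation, SaO2 clipped to \[0, 1\]) and derives the
#' arterial oxygen content with [compute_cao2()]. With `gas_rel_sd = 0`
#' the targets are returned exactly.
#'
#' @param effect A [cohort_effect_config()].
#' @param condition `"baseline"` or `"LPS"`.
#' @param intervention `"normoxia"`, `"hyperoxia"` or `"hypoxia"`.
#' @param seed Integer seed for the draw.
#' @return One-row tibble with columns `paO2_kPa`, `saO2_frac`,
#'   `paCO2_kPa`, `hb_mM`, `caO2_mM`.
#' @export
simulate_blood_gases <- function(effect, condition, intervention, seed = 1L) {
  stopifnot(inherits(effect, "cohort_effect_config"))
  condition <- match.arg(condition, c("baseline", "LPS"))
  if (!intervention %in% c("normoxia", "hyperoxia", "hypoxia")) {
    stop_dcar(
      sprintf("Unknown intervention label '%s'.", intervention),
      "dcar_invalid_config"
    )
  }
  tgt <- effect$gas_targets[[condition]][[intervention]]
  draw <- function(value, eps) value * (1 + effect$gas_rel_sd * eps)
  eps <- if (effect$gas_rel_sd > 0) {
    withr::with_seed(seed, rnorm(4))
  } else {
    numeric(4)
  }
  paO2 <- max(draw(tgt$paO2, eps[1]), 0)
  saO2 <- min(max(draw(tgt$saO2, eps[2]), 0), 1)
  paCO2 <- max(draw(tgt$paCO2, eps[3]), 0)
  hb <- max(draw(tgt$hb, eps[4]), 0)
  tibble::tibble(
    paO2_kPa = paO2, saO2_frac = saO2, paCO2_kPa = paCO2, hb_mM = hb,
    caO2_mM = compute_cao2(saO2, hb, paO2)
  )
}

#' Simulate a full synthetic study
#'
#' Generates every subject x condition x intervention cell of the study:
#' a paired MAP/MCAv recording driven by a subject-specific band-plateau
#' transfer template (low-frequency phase = condition median + subject
#' offset) and a blood-gas panel, with per-intervention MCAv setpoints
#' derived from the subject's vasoreactivity slopes and realised PaO2
#' values. The subject-level ground truth (true phases, gains, setpoints,
#' slopes) is returned alongside the data, so estimator recovery tests
#' never have to re-derive it.
#'
#' Seeding is two-level: `effect$seed` fixes the subject-level truth
#' (parameter offsets and blood-gas panels), while `realisation_seed`
#' (defaulting to `effect$seed`) drives the recording noise. Two
#' different realisation seeds therefore give different signal data with
#' identical ground-truth metadata.
#'
#' @param effect A [cohort_effect_config()].
#' @param realisation_seed Integer seed for the noise realisation
#'   (default `effect$seed`).
#' @return A list of class `car_cohort` with elements `recordings` (named
#'   list of [hemodynamic_recording()], names `subject.condition.intervention`),
#'   `panels` (tibble of blood-gas panels), `truth` (tibble of
#'   ground-truth parameters) and `effect`.
#' @export
simulate_cohort <- function(effect, realisation_seed = effect$seed) {
  stopifnot(inherits(effect, "cohort_effect_config"))
  conditions <- c("baseline", "LPS")
  subjects <- sprintf("sub%02d", seq_len(effect$n_subjects))

  # subject-level truth: drawn from effect$seed only
  subj <- withr::with_seed(effect$seed, {
    tibble::tibble(
      subject_id = subjects,
      phase_offset = rnorm(effect$n_subjects, 0, effect$between_subject_sd),
      gain_offset = rnorm(effect$n_subjects, 0, effect$gain_between_subject_sd),
      mcav_offset = rnorm(effect$n_subjects, 0, effect$mcav_between_subject_sd),
      covr_offset_hyper = rnorm(effect$n_subjects, 0, effect$covr_between_subject_sd),
      covr_offset_hypo = rnorm(effect$n_subjects, 0, effect$covr_between_subject_sd)
    )
  })

  recordings <- list()
  panels <- list()
  truth <- list()
  cell <- 0L
  for (s in seq_len(effect$n_subjects)) {
    for (cond in conditions) {
      phase_sc <- (if (cond == "baseline") effect$baseline_lf_phase else
        effect$lps_lf_phase) + subj$phase_offset[s]
      gain_s <- max(effect$gain_lf + subj$gain_offset[s], 0.2)
      mcav_norm_s <- effect$mcav_normoxia[[cond]] + subj$mcav_offset[s]
      covr_s <- c(
        hyperoxia = effect$covr_slopes[[cond]][["hyperoxia"]] +
          subj$covr_offset_hyper[s],
        hypoxia = effect$covr_slopes[[cond]][["hypoxia"]] +
          subj$covr_offset_hypo[s]
      )
      # blood gases first: intervention setpoints depend on realised PaO2
      cell_panels <- list()
      for (iv in effect$interventions) {
        cell <- cell + 1L
        # blood-gas panels are subject-level characteristics: drawn from the
        # effect seed so ground truth is invariant across realisation seeds
        cell_panels[[iv]] <- simulate_blood_gases(
          effect, cond, iv, seed = derive_seed(effect$seed, 2L * cell)
        )
      }
      pa_norm <- cell_panels[["normoxia"]]$paO2_kPa
      for (iv in effect$interventions) {
        setpoint <- if (iv == "normoxia") {
          mcav_norm_s
        } else {
          mcav_norm_s *
            (1 + covr_s[[iv]] * (cell_panels[[iv]]$paO2_kPa - pa_norm) / 100)
        }
        template <- band_transfer_template(gain_lf = gain_s,
                                           phase_lf = phase_sc)
        cfg <- sim_config(
          duration = effect$duration, sampling_rate = effect$sampling_rate,
          map_setpoint = effect$map_setpoint,
          background_noise_sd = effect$background_noise_sd,
          transfer_model = transfer_model(
            "frequency_template", template = template,
            mcav_setpoint = setpoint
          ),
          output_noise_sd = effect$output_noise_sd,
          seed = derive_seed(realisation_seed, 1000L + cell * 3L + match(iv, effect$interventions))
        )
        key <- paste(subjects[s], cond, iv, sep = ".")
        recordings[[key]] <- simulate_recording(
          cfg, subject_id = subjects[s], condition = cond, intervention = iv
        )
        panels[[key]] <- dplyr::mutate(
          cell_panels[[iv]],
          subject_id = subjects[s], condition = cond, intervention = iv,
          .before = 1L
        )
        truth[[key]] <- tibble::tibble(
          subject_id = subjects[s], condition = cond, intervention = iv,
          lf_phase_true = phase_sc, lf_gain_true = gain_s,
          mcav_setpoint = setpoint,
          covr_slope_hyperoxia = covr_s[["hyperoxia"]],
          covr_slope_hypoxia = covr_s[["hypoxia"]]
        )
      }
    }
  }
  structure(
    list(
      recordings = recordings,
      panels = dplyr::bind_rows(panels),
      truth = dplyr::bind_rows(truth),
      effect = effect
    ),
    class = "car_cohort"
  )
}

#' @export
print.car_cohort <- function(x, ...) {
  cat(sprintf(
    "<car_cohort> %d subjects x 2 conditions x %d intervention(s): %d recordings\n",
    x$effect$n_subjects, length(x$effect$interventions), length(x$recordings)
  ))
  invisible(x)
}
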