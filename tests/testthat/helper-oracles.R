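# Independent oracles used across the suite. These deliberately share no
# code with the package: the DFT is an explicit O(N^2) sum, the signed-rank
# null is a full 2^n enumeration, and Holm is spelled out step by step.

# Brute-force one-sided Hann-windowed auto-/cross-spectral densities of one
# segment, with per-segment mean removal, on the same density scale as the
# package (2 / (fs * sum(w^2)), halved at DC and Nyquist).
direct_hann_csd <- function(x, y, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xd <- (x - mean(x)) * w
  yd <- (y - mean(y)) * w
  k <- 0:(n %/% 2)
  ex <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  X <- as.vector(ex %*% xd)
  Y <- as.vector(ex %*% yd)
  scale <- rep(2 / (fs * sum(w^2)), length(k))
  scale[1] <- scale[1] / 2
  if (n %% 2 == 0) scale[length(k)] <- scale[length(k)] / 2
  list(
    frequencies = k * fs / n,
    s_x = Re(X * Conj(X)) * scale,
    s_y = Re(Y * Conj(Y)) * scale,
    s_xy = Conj(X) * Y * scale
  )
}

# Full enumeration of all 2^n sign assignments for the signed-rank test;
# two-sided p doubles the smaller tail, capped at 1.
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# Step-down Holm adjustment written out longhand.
holm_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# A noiseless single-oscillator configuration used by several tests.
pure_tone_config <- function(frequency = 0.1, amplitude = 1, duration = 600,
                             seed = 1L) {
  sim_config(
    duration = duration, sampling_rate = 10, map_setpoint = 88,
    oscillators = tibble::tibble(frequency = frequency, amplitude = amplitude,
                                 phase = 0),
    background_noise_sd = 0,
    transfer_model = transfer_model("unity"),
    output_noise_sd = 0, seed = seed
  )
}

# Broadband MAP configuration (all bins excited) with a chosen output model.
broadband_config <- function(model, duration = 600, output_noise_sd = 0,
                             seed = 1L) {
  sim_config(
    duration = duration, sampling_rate = 10, map_setpoint = 88,
    background_noise_sd = 1, transfer_model = model,
    output_noise_sd = output_noise_sd, seed = seed
  )
}

# Per-recording LF summary through the estimator chain.
lf_summary <- function(rec, threshold = 0.4) {
  est <- welch_cross_spectra(rec$map, rec$mcav)
  ba <- band_average(est, coherence_threshold = threshold)
  ba[ba$band == "LF", ]
}
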