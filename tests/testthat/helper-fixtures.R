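# Shared fixtures: small chirp/scene configurations and independent oracles.

# Compact chirp for fast simulation; 4 mm wavelength pins the analytic
# phase-displacement numbers.
test_chirp <- function(n_fast = 32L, lambda = NULL) {
  chirp_config(n_fast_samples = as.integer(n_fast), wavelength_m = lambda)
}

# Single-scatterer scene: one target carrying the full displacement.
single_target_scene <- function(duration_s = 10, snr_db = Inf,
                                azimuth_deg = 0,
                                resp_amp = 5e-3, resp_rate = 0.25,
                                harmonics = c(0.1, 0.05),
                                heart_amp = 0.3e-3, seed = 1L, ...) {
  scene_config(duration_s = duration_s, snr_db = snr_db,
               heart_azimuth_deg = azimuth_deg,
               respiration_amplitude_m = resp_amp,
               respiration_rate_hz = resp_rate,
               resp_harmonics = harmonics,
               heartbeat_amplitude_m = heart_amp,
               heart_respiration_scale = 1,
               torso_rcs_scale = 0, seed = seed, ...)
}

# Clean SCG kernel train with beats on the sample grid.
kernel_train <- function(fs = 200, duration_s = 62, period_s = 1.0,
                         first_beat_s = 0.5, amplitude = 1) {
  t <- (0:(duration_s * fs - 1)) / fs
  x <- numeric(length(t))
  beats <- seq(first_beat_s, duration_s - 0.6, by = period_s)
  k <- scg_beat_kernel(fs, amplitude)
  for (tb in beats) {
    i0 <- round(tb * fs) + 1L
    idx <- i0:(i0 + length(k$y) - 1L)
    ok <- idx <= length(x)
    x[idx[ok]] <- x[idx[ok]] + k$y[ok]
  }
  list(x = x, t = t, beat_times = beats, ao_times = beats + k$ao_offset_s,
       fs = fs)
}

# Brute-force DTW oracle: full dynamic-programming table, no optimizations.
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- abs(x[i] - y[j]) +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1]
}

# Unwrapped-arctangent phase oracle for a complex trajectory with per-sample
# phase steps below pi.
unwrapped_phase_oracle <- function(y) {
  ph <- Arg(y)
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(0, cumsum(d))
}

# Relative RMSE after mean alignment.
rel_rmse <- function(est, truth) {
  est <- est - mean(est)
  truth <- truth - mean(truth)
  sqrt(mean((est - truth)^2)) / stats::sd(truth)
}

# Fraction of reference beats with a detected event within tol_s.
beat_hit_rate <- function(detected_s, truth_s, tol_s = 0.010) {
  if (!length(detected_s)) return(0)
  hits <- vapply(truth_s, function(tt) any(abs(detected_s - tt) <= tol_s), NA)
  mean(hits)
}
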