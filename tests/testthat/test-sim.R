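# Scene simulator: beat sequence statistics, chest kinematics, IF cube physics.

test_that("zero-variance IBI model emits an exact metronome", {
  b <- generate_ibi_sequence(list(mean_s = 1, sd_s = 0), 10, seed = 5)
  expect_equal(b$beat_times_s, 0:10)
  expect_equal(b$ibi_ms, rep(1000, 10))
})

test_that("beat count and variability match the configured model", {
  # expectation duration / mean = 750 beats
  b <- generate_ibi_sequence(list(mean_s = 0.8, sd_s = 0.05), 600, seed = 2)
  expect_gt(length(b$ibi_ms), 750 * 0.95)
  expect_lt(length(b$ibi_ms), 750 * 1.05)
  # sample SDNN inside the Monte-Carlo 95% interval [47.26, 52.77] ms
  # (frozen from 2000 independent draws of N(1 s, 50 ms) streams over 600 s)
  b2 <- generate_ibi_sequence(list(mean_s = 1, sd_s = 0.05), 600, seed = 3)
  expect_gt(sd(b2$ibi_ms), 47.26)
  expect_lt(sd(b2$ibi_ms), 52.77)
})

test_that("IBI generation is deterministic and validates its inputs", {
  a <- generate_ibi_sequence(list(mean_s = 0.9, sd_s = 0.04), 60, seed = 42)
  b <- generate_ibi_sequence(list(mean_s = 0.9, sd_s = 0.04), 60, seed = 42)
  expect_identical(a, b)
  expect_error(generate_ibi_sequence(list(mean_s = -1), 60), "positive")
  expect_error(generate_ibi_sequence(list(mean_s = 1), -5), "positive")
})

test_that("lag-1 correlated IBI model produces correlated intervals", {
  b <- generate_ibi_sequence(list(mean_s = 1, sd_s = 0.05, ar1 = 0.6), 600,
                             seed = 4)
  x <- b$ibi_ms
  r <- cor(x[-length(x)], x[-1])
  expect_gt(r, 0.4)
  expect_lt(r, 0.8)
})

test_that("chest displacement composes respiration and beat kernels", {
  fs <- 200
  tt <- (0:(20 * fs)) / fs
  # both amplitudes zero -> identically zero
  sc0 <- single_target_scene(resp_amp = 0, heart_amp = 0)
  d0 <- synthesize_chest_displacement(sc0, c(1, 2, 3), tt)
  expect_equal(d0$total_m, numeric(length(tt)))
  # pure 5 mm / 0.25 Hz respiration, no harmonics
  sc1 <- single_target_scene(resp_amp = 5e-3, resp_rate = 0.25,
                             harmonics = c(0, 0), heart_amp = 0)
  d1 <- synthesize_chest_displacement(sc1, numeric(0), tt)
  expect_equal(max(abs(d1$total_m)), 5e-3, tolerance = 1e-3)
  sp <- Mod(fft(d1$total_m))[1:(length(tt) %/% 2)]
  f_axis <- (seq_along(sp) - 1) / (length(tt) / fs)
  expect_equal(f_axis[which.max(sp[-1]) + 1], 0.25, tolerance = 0.02)
})

test_that("beat kernels put energy in the SCG band", {
  fs <- 200
  tt <- (0:(60 * fs)) / fs
  sc <- single_target_scene()
  beats <- generate_ibi_sequence(sc$ibi_model, 60, seed = 1)$beat_times_s
  d <- synthesize_chest_displacement(sc, beats, tt)
  sp <- Mod(fft(d$cardiac_m))^2
  f_axis <- (seq_along(sp) - 1) / (length(tt) / fs)
  in_band <- f_axis >= 7.8125 & f_axis <= 18.75
  expect_gt(sum(sp[in_band]), 0)
  # the AO ground truth is the beat time plus the documented kernel offset
  expect_equal(d$ao_times_s, beats + scg_beat_kernel(fs)$ao_offset_s)
})

test_that("overlapping kernels warn and are summed", {
  fs <- 200
  tt <- (0:(5 * fs)) / fs
  sc <- single_target_scene(resp_amp = 0)
  expect_warning(
    d <- synthesize_chest_displacement(sc, c(1, 1.2), tt),
    "overlapping")
  one <- synthesize_chest_displacement(sc, 1, tt)
  two <- synthesize_chest_displacement(sc, 1.2, tt)
  expect_equal(d$cardiac_m, one$cardiac_m + two$cardiac_m)
})

test_that("static scatterer produces the analytic IF tone frequency", {
  # R = 0.6 m, slope 60 MHz/us -> f_IF = 2 R slope / c = 240.17 kHz
  ch <- test_chirp(n_fast = 64L)
  sc <- single_target_scene(duration_s = 0.2, resp_amp = 0, heart_amp = 0)
  sim <- simulate_scene(sc, ch)
  frame <- sim$cube$samples[1, , 1]
  sp <- Mod(fft(frame))[1:32]
  f_axis <- (0:31) * ch$adc_sample_rate_hz / 64
  f_expected <- 2 * 0.6 * ch$frequency_slope_hz_per_s / 299792458
  expect_lt(abs(f_axis[which.max(sp)] - f_expected),
            ch$adc_sample_rate_hz / 64)
})

test_that("a broadside scatterer reaches all antennas identically", {
  ch <- test_chirp()
  sc <- single_target_scene(duration_s = 1, azimuth_deg = 0)
  sim <- simulate_scene(sc, ch)
  expect_equal(sim$cube$samples[, , 1], sim$cube$samples[, , 8])
})

test_that("simulation is bit-identical under a fixed seed", {
  ch <- test_chirp()
  sc <- scene_config(duration_s = 2, snr_db = 10, seed = 77)
  a <- simulate_scene(sc, ch)
  b <- simulate_scene(sc, ch)
  expect_identical(a$cube$samples, b$cube$samples)
  expect_identical(a$truth$ao_times_s, b$truth$ao_times_s)
})

test_that("noise-free per-antenna power is equal across the array", {
  ch <- test_chirp()
  sc <- single_target_scene(duration_s = 2, azimuth_deg = -25)
  sim <- simulate_scene(sc, ch)
  p <- apply(abs(sim$cube$samples)^2, 3, mean)
  expect_equal(max(p) / min(p), 1, tolerance = 1e-12)
})

test_that("demodulated target-bin phase tracks 4 pi dR / lambda", {
  # 0.1 mm sinusoid at 4 mm wavelength -> 0.314 rad amplitude
  ch <- test_chirp(n_fast = 64L, lambda = 4e-3)
  sc <- single_target_scene(duration_s = 10, resp_amp = 1e-4, resp_rate = 0.5,
                            harmonics = c(0, 0), heart_amp = 0)
  sim <- simulate_scene(sc, ch)
  pr <- range_fft(sim$cube)
  b <- which.max(apply(abs(pr$bins)^2, 2, sum))
  ph <- mdacm_demodulate(pr$bins[, b, 1], fs_hz = 200)$phase_rad
  amp <- (max(ph) - min(ph)) / 2
  expect_equal(amp, 4 * pi * 1e-4 / 4e-3, tolerance = 0.01)
  # full linearity against the ground-truth displacement
  expect_lt(rel_rmse(ph, 4 * pi * sim$truth$displacement_m / 4e-3), 0.01)
})

test_that("scene validation rejects impossible geometry", {
  ch <- test_chirp()
  expect_error(scene_config(heart_azimuth_deg = 120), "must lie in")
  sc <- scene_config(target_range_m = 50, duration_s = 1)
  expect_error(synthesize_if_cube(sc, ch), "unambiguous")
})
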