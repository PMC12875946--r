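# Envelopes, AO fiducial detection, inter-beat intervals, HRV metrics,
# and beat-sequence agreement.

test_that("the analytic envelope of a sinusoid is its amplitude", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  A <- 2.3
  env <- envelopes(A * sin(2 * pi * 5 * t), fs)
  mid <- (fs):(9 * fs)
  expect_lt(max(abs(env$upper[mid] - A)), 0.02 * A)
  expect_lt(max(abs(env$lower[mid] + A)), 0.02 * A)
  z <- envelopes(numeric(400), fs)
  expect_equal(z$upper, numeric(400))
  expect_equal(z$lower, numeric(400))
  # positive scaling of a zero-mean signal scales the envelopes
  x <- sin(2 * pi * 3 * t) * exp(-t / 5)
  e1 <- envelopes(x, fs)
  e4 <- envelopes(4 * x, fs)
  expect_equal(e4$upper, 4 * e1$upper, tolerance = 1e-10)
})

test_that("AO detection recovers nearly every beat of a clean kernel train", {
  kt <- kernel_train(duration_s = 62, period_s = 1.0)
  ev <- detect_ao(kt$x, kt$fs)
  hits <- beat_hit_rate(ev$times_s, kt$ao_times, tol_s = 0.010)
  expect_gte(hits, 58 / length(kt$ao_times))
  expect_lte(length(ev$times_s), length(kt$ao_times) + 2L)
  # spacing invariant after detection
  expect_true(all(diff(ev$indices) >= 0.4 * kt$fs))
})

test_that("a silenced cycle does not fabricate an AO event", {
  kt <- kernel_train(duration_s = 20, period_s = 1.0)
  x <- kt$x
  fs <- kt$fs
  # remove the beat at 10.5 s entirely
  idx <- round(10.5 * fs):round((10.5 + 0.35) * fs)
  x[idx] <- 0
  ev <- detect_ao(x, fs)
  expect_false(any(abs(ev$times_s - (10.5 + 0.115)) < 0.2))
  # neighboring beats are still found
  expect_true(any(abs(ev$times_s - (9.5 + 0.115)) < 0.02))
  expect_true(any(abs(ev$times_s - (11.5 + 0.115)) < 0.02))
})

test_that("cycles whose search window is clipped at the edge are discarded", {
  fs <- 200
  k <- scg_beat_kernel(fs)
  # one beat hard against the signal start: its envelope trough sits inside
  # the clipped window region
  x <- numeric(6 * fs)
  x[seq_along(k$y)] <- k$y
  x2 <- numeric(6 * fs)
  i0 <- round(3 * fs)
  x2[i0 + seq_along(k$y)] <- k$y
  ev_edge <- suppressWarnings(detect_ao(x + x2, fs))
  # interior beat found; edge beat either discarded (counted) or absent
  expect_true(any(abs(ev_edge$times_s - (3 + 0.115)) < 0.02))
})

test_that("degenerate inputs yield empty event sequences", {
  expect_warning(ev <- detect_ao(rep(1.5, 800), 200), "no valid")
  expect_length(ev$indices, 0L)
  expect_error(detect_ao(rnorm(100), 200), "at least 2 s")
})

test_that("AO detection is shift-equivariant and amplitude-invariant", {
  kt <- kernel_train(duration_s = 30, period_s = 1.0)
  ev <- detect_ao(kt$x, kt$fs)
  k <- 40L
  shifted <- c(numeric(k), kt$x[1:(length(kt$x) - k)])
  ev_s <- detect_ao(shifted, kt$fs)
  common <- intersect(ev$indices + k, ev_s$indices)
  expect_gte(length(common), length(ev$indices) - 3L)
  ev_a <- detect_ao(0.37 * kt$x, kt$fs)
  expect_identical(ev_a$indices, ev$indices)
})

test_that("AO indices lie strictly between their cycle's IM and IC troughs", {
  kt <- kernel_train(duration_s = 20, period_s = 1.0)
  ev <- detect_ao(kt$x, kt$fs)
  # with the documented kernel, IM leads AO by 35 ms and IC trails by 35 ms;
  # judge events that belong to a true cycle (envelope edge ringing can add
  # a stray event at the extreme ends of the record)
  interior <- ev$times_s[ev$times_s > 0.5 & ev$times_s < max(kt$beat_times)]
  matched <- interior[vapply(interior, function(tt)
    min(abs(kt$ao_times - tt)) < 0.05, NA)]
  expect_gte(length(matched), length(kt$beat_times) - 3L)
  for (tt in matched) {
    tb <- kt$beat_times[which.min(abs(kt$beat_times + 0.115 - tt))]
    expect_gt(tt, tb + 0.080)
    expect_lt(tt, tb + 0.150)
  }
})

test_that("IBI derivation applies the inclusive validity bounds", {
  expect_equal(ibi_from_events(c(0, 1, 2, 3))$ibi_ms, rep(1000, 3))
  # a 2000 ms interval sits on the inclusive boundary and is kept
  s <- ibi_from_events(c(0, 1, 3, 4))
  expect_equal(s$ibi_ms, c(1000, 2000, 1000))
  expect_equal(s$n_raw, 3L)
  expect_equal(s$n_kept, 3L)
  # 2500 ms is dropped
  s2 <- ibi_from_events(c(0, 1, 3.5, 4.5))
  expect_equal(s2$ibi_ms, c(1000, 1000))
  expect_equal(s2$n_kept, 2L)
  empty <- ibi_from_events(numeric(0))
  expect_length(empty$ibi_ms, 0L)
})

test_that("HRV metrics match hand-evaluated closed forms", {
  m0 <- hrv_metrics(rep(1000, 4))
  expect_equal(m0$sdnn_ms, 0)
  expect_equal(m0$rmssd_ms, 0)
  expect_equal(m0$pnn50_percent, 0)
  # (800, 860, 800, 860): deviations +/-30 -> SDNN 30 (1/N form);
  # successive diffs (60, -60, 60) -> RMSSD 60; 3 of N=4 exceed 50 ms -> 75%
  m <- hrv_metrics(c(800, 860, 800, 860))
  expect_equal(m$sdnn_ms, 30)
  expect_equal(m$rmssd_ms, 60)
  expect_equal(m$pnn50_percent, 75)
  # threshold is strict: |diff| = 49 does not count
  expect_equal(hrv_metrics(c(1000, 1049))$pnn50_percent, 0)
  expect_error(hrv_metrics(1000), "at least two")
})

test_that("SDNN denominator conventions differ by exactly sqrt(N/(N-1))", {
  set.seed(18)
  x <- rnorm(37, 1000, 40)
  mp <- hrv_metrics(x, sdnn_denom = "population")
  ms <- hrv_metrics(x, sdnn_denom = "sample")
  expect_equal(ms$sdnn_ms / mp$sdnn_ms, sqrt(37 / 36))
  # pNN50 denominator option
  y <- c(1000, 1100, 1000, 1100)
  expect_equal(hrv_metrics(y, pnn50_denom = "n")$pnn50_percent, 75)
  expect_equal(hrv_metrics(y, pnn50_denom = "nm1")$pnn50_percent, 100)
})

test_that("agreement with an identical reference is exact", {
  times <- cumsum(c(0, rnorm(60, 1, 0.05)))
  rep0 <- compare_to_reference(times, times)
  expect_equal(rep0$mae_ms, 0)
  expect_equal(rep0$rmse_ms, 0)
  expect_equal(unname(diff(rep0$loa_ms)), 0)
  expect_equal(rep0$sdnn_error_ms, 0)
})

test_that("a constant time offset cancels in the interval comparison", {
  set.seed(19)
  times <- cumsum(c(0, rnorm(60, 1, 0.05)))
  rep1 <- compare_to_reference(times + 0.020, times)
  expect_lt(rep1$mae_ms, 1e-9)
  expect_lt(abs(rep1$bias_ms), 1e-9)
})

test_that("missed beats reduce matches without fabricating intervals", {
  set.seed(20)
  times <- cumsum(c(0, rnorm(60, 1, 0.05)))
  dropped <- times[-c(10, 30)]
  rep2 <- compare_to_reference(dropped, times)
  expect_equal(rep2$n_matched, length(times) - 1 - 4)
  expect_lt(rep2$mae_ms, 1e-9)
})
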