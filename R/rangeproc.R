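# Range processing: fast-time FFT, static clutter removal, target-bin
# selection into the beamformer's snapshot matrix.

#' Fast-time FFT of an IF cube into range profiles
#'
#' Applies a discrete Fourier transform along fast time, per frame and
#' antenna, and maps beat frequency to range by `R = f * c / (2 * slope)`.
#' Complex (I/Q) sampling puts the unambiguous positive-range half in the
#' first `n_fft / 2` bins; only those are kept. The default window is
#' rectangular (none); a Hann window is available.
#'
#' @param cube An `ifdata_cube` from [synthesize_if_cube()] or
#'   [read_if_cube()].
#' @param n_fft FFT length, at least `n_fast_samples` (zero-padded above it).
#' @param window `"rect"` (default) or `"hann"`.
#' @return An object of class `range_profile`: `bins` (complex array
#'   `[frame, range bin, antenna]`), `range_axis_m` (bin centres), `chirp`,
#'   and a `clutter_removed` flag.
#' @export
range_fft <- function(cube, n_fft = NULL, window = c("rect", "hann")) {
  stopifnot(inherits(cube, "ifdata_cube"))
  window <- match.arg(window)
  d <- dim(cube$samples)
  n_frames <- d[1]; n_fast <- d[2]; M <- d[3]
  if (is.null(n_fft)) n_fft <- n_fast
  if (n_fft < n_fast) stop("n_fft must be at least n_fast_samples")
  if (n_fft %% 2 != 0) stop("n_fft must be even")
  w <- switch(window,
              rect = rep(1, n_fast),
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n_fast) - 1) / (n_fast - 1)))
  n_bins <- n_fft %/% 2
  bins <- array(0 + 0i, dim = c(n_frames, n_bins, M))
  pad <- matrix(0 + 0i, nrow = n_fft, ncol = n_frames)
  for (m in seq_len(M)) {
    pad[] <- 0 + 0i
    pad[seq_len(n_fast), ] <- t(cube$samples[, , m]) * w
    ft <- stats::mvfft(pad)
    bins[, , m] <- t(ft[seq_len(n_bins), , drop = FALSE])
  }
  df <- cube$chirp$adc_sample_rate_hz / n_fft
  range_axis <- (seq_len(n_bins) - 1) * df * .c0 /
    (2 * cube$chirp$frequency_slope_hz_per_s)
  structure(list(bins = bins, range_axis_m = range_axis, chirp = cube$chirp,
                 clutter_removed = FALSE),
            class = "range_profile")
}

#' Remove static clutter from a range profile
#'
#' Subtracts, for every (range bin, antenna) pair, the slow-time mean of that
#' bin, suppressing returns from stationary reflectors. Requires at least two
#' frames.
#'
#' @param profile A `range_profile` from [range_fft()].
#' @return The profile with zero slow-time mean per bin and
#'   `clutter_removed = TRUE`.
#' @export
remove_static_clutter <- function(profile) {
  stopifnot(inherits(profile, "range_profile"))
  d <- dim(profile$bins)
  if (d[1] < 2L) stop("static clutter removal requires at least two frames")
  mu <- colMeans(profile$bins)              # [bin, antenna]
  profile$bins <- profile$bins -
    aperm(array(mu, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  profile$clutter_removed <- TRUE
  profile$removed_mean <- mu
  profile
}

#' Extract the target range gate as a snapshot matrix
#'
#' Selects the single range bin with the largest total post-clutter-removal
#' energy (summed over frames and antennas) and returns the complex slow-time
#' sequences of all antennas at that gate -- the snapshot set the beamformer
#' operates on. A single global gate is used (rather than a per-frame argmax)
#' so that the snapshot model, and hence the spatial covariance, refers to one
#' fixed range.
#'
#' The clutter-removed sequences (`X`) drive the covariance estimate and the
#' beamformer; the same gate's sequences with their slow-time mean restored
#' (`X_raw`) are kept alongside, because phase demodulation needs the
#' phasor's true rotation centre -- subtracting the slow-time mean of a
#' moderately swinging arc shifts its centre and distorts the demodulated
#' phase. Static returns from other azimuths are suppressed spatially by the
#' beamformer; [dc_compensate()] remains available for static clutter
#' co-located with the target in both range and angle.
#'
#' @param profile A clutter-removed `range_profile`.
#' @return An object of class `snapshot_matrix`: `X` (complex, antennas x
#'   frames, clutter-removed), `X_raw` (same gate, mean restored),
#'   `target_bin_index` (1-based), `target_range_m`, `fs_slow_hz`, and
#'   `chirp`.
#' @export
select_target_bin <- function(profile) {
  stopifnot(inherits(profile, "range_profile"))
  if (!isTRUE(profile$clutter_removed)) {
    stop("select_target_bin expects a clutter-removed profile; ",
         "call remove_static_clutter() first")
  }
  energy <- apply(abs(profile$bins)^2, 2, sum)
  if (max(energy) <= 0) stop("degenerate all-zero range profile")
  b <- which.max(energy)
  X <- t(profile$bins[, b, ])               # M x N
  X_raw <- X + matrix(profile$removed_mean[b, ], nrow = nrow(X),
                      ncol = ncol(X), byrow = FALSE)
  structure(list(X = X,
                 X_raw = X_raw,
                 target_bin_index = b,
                 target_range_m = profile$range_axis_m[b],
                 fs_slow_hz = profile$chirp$fs_slow_hz,
                 chirp = profile$chirp),
            class = "snapshot_matrix")
}

#' @export
print.snapshot_matrix <- function(x, ...) {
  cat(sprintf("Snapshot matrix: %d antennas x %d frames at bin %d (%.2f m), fs %.0f Hz\n",
              nrow(x$X), ncol(x$X), x$target_bin_index, x$target_range_m,
              x$fs_slow_hz))
  invisible(x)
}
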