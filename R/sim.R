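# Scene simulator: beat timing, chest kinematics, and IF data-cube rendering.

# Derive a deterministic 31-bit sub-seed from a master seed, so the beat
# sequence and the noise draw from independent streams.
.sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% (2^31 - 1))
}

#' Generate a beat-time / inter-beat-interval sequence
#'
#' Draws successive inter-beat intervals (IBIs) from the configured model and
#' accumulates them into beat times covering `[0, duration_s]`. The default
#' model is Gaussian with optional lag-1 autocorrelation `ar1` (an AR(1)
#' process with stationary standard deviation `sd_s`); draws are clamped to
#' the physiological range \[0.4, 2\] s.
#'
#' @param ibi_model List with `mean_s` (> 0), `sd_s` (>= 0), `distribution`
#'   (currently `"gaussian"`), and optional `ar1`.
#' @param duration_s Length of the sequence to cover, seconds.
#' @param seed Integer seed; the draw is deterministic given
#'   `(ibi_model, duration_s, seed)`.
#' @return List with `beat_times_s` (first beat at 0) and `ibi_ms`
#'   (successive differences in milliseconds).
#' @examples
#' b <- generate_ibi_sequence(list(mean_s = 1, sd_s = 0), 10, seed = 1)
#' b$beat_times_s   # 0, 1, 2, ..., 10
#' @export
generate_ibi_sequence <- function(ibi_model, duration_s, seed = 1L) {
  ibi_model <- utils::modifyList(
    list(mean_s = 1.0, sd_s = 0.05, distribution = "gaussian", ar1 = 0),
    ibi_model)
  if (!is.numeric(ibi_model$mean_s) || ibi_model$mean_s <= 0) {
    stop("ibi_model$mean_s must be positive")
  }
  if (!is.numeric(ibi_model$sd_s) || ibi_model$sd_s < 0) {
    stop("ibi_model$sd_s must be non-negative")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive")
  }
  if (!identical(ibi_model$distribution, "gaussian")) {
    stop("unsupported IBI distribution: ", ibi_model$distribution)
  }
  mean_s <- ibi_model$mean_s
  sd_s <- ibi_model$sd_s
  ar1 <- ibi_model$ar1
  n_max <- ceiling(duration_s / 0.4) + 2L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(seed, 1L))
  eps <- stats::rnorm(n_max)
  dev <- numeric(n_max)
  if (sd_s > 0) {
    dev[1] <- sd_s * eps[1]
    if (ar1 != 0) {
      scale <- sd_s * sqrt(1 - ar1^2)
      for (k in 2:n_max) dev[k] <- ar1 * dev[k - 1] + scale * eps[k]
    } else {
      dev <- sd_s * eps
    }
  }
  ibi <- pmin(pmax(mean_s + dev, 0.4), 2.0)
  times <- cumsum(c(0, ibi))
  keep <- times <= duration_s
  times <- times[keep]
  list(beat_times_s = times, ibi_ms = diff(times) * 1000)
}

# Saving/restoring the global RNG state keeps the simulator deterministic
# without clobbering the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-beat SCG displacement kernel
#'
#' Fixed analytic seismocardiogram morphology used by the simulator: a sum of
#' Gaussian lobes placing the canonical fiducials in order -- atrial systole
#' (AS), mitral closure (MC), the deep isovolumetric-contraction trough (IM),
#' the dominant aortic-opening peak (AO), the secondary trough (IC), and the
#' rapid-ejection rebound (RE) with a shallow late tail. The kernel is scaled
#' so its largest absolute excursion equals `amplitude_m`; the AO lobe peaks
#' `ao_offset_s` = 0.115 s after kernel onset, which is the ground-truth
#' fiducial the detector is judged against.
#'
#' @param fs_hz Sampling rate of the returned kernel (Hz).
#' @param amplitude_m Peak absolute displacement of the kernel (m).
#' @return List with `y` (kernel samples), `t_s` (times from onset),
#'   `ao_offset_s`, and `support_s` (total kernel duration, 0.32 s).
#' @export
scg_beat_kernel <- function(fs_hz = 200, amplitude_m = 1) {
  support_s <- 0.32
  t <- seq(0, support_s, by = 1 / fs_hz)
  y <- .scg_kernel_cont(t)
  list(y = amplitude_m * y, t_s = t,
       ao_offset_s = .scg_ao_offset_s, support_s = support_s)
}

# Lobe table: centre (s), amplitude (relative), sigma (s).
.scg_lobes <- cbind(
  center = c(0.010, 0.045, 0.080, 0.115, 0.150, 0.190, 0.250),
  amp    = c(0.15, 0.35, -1.00, 0.90, -0.60, 0.40, -0.15),
  sigma  = c(0.010, 0.010, 0.009, 0.009, 0.011, 0.013, 0.016)
)
.scg_ao_offset_s <- 0.115

# Continuous kernel, normalized to unit maximum absolute excursion.
.scg_kernel_cont <- function(t) {
  y <- numeric(length(t))
  for (i in seq_len(nrow(.scg_lobes))) {
    y <- y + .scg_lobes[i, "amp"] *
      exp(-(t - .scg_lobes[i, "center"])^2 / (2 * .scg_lobes[i, "sigma"]^2))
  }
  # normalization constant: |IM| lobe dominates; evaluate once on a fine grid
  y / .scg_kernel_peak
}

# Normalization constant evaluated once at install time on a fine grid.
.scg_kernel_peak <- local({
  tt <- seq(0, 0.32, by = 1e-4)
  y <- numeric(length(tt))
  for (i in seq_len(nrow(.scg_lobes))) {
    y <- y + .scg_lobes[i, "amp"] *
      exp(-(tt - .scg_lobes[i, "center"])^2 / (2 * .scg_lobes[i, "sigma"]^2))
  }
  max(abs(y))
})

#' Synthesize the chest displacement trace
#'
#' Builds the total chest-wall displacement on the slow-time grid:
#' a respiration waveform (fundamental plus configured 2nd/3rd harmonics) and
#' a train of per-beat SCG kernels ([scg_beat_kernel()]) inserted at the
#' given beat times. Kernels whose support overlaps (IBI shorter than the
#' kernel duration) are summed, with a warning.
#'
#' @param scene A [scene_config()].
#' @param beat_times_s Beat (kernel onset) times in seconds.
#' @param slow_time_s Uniform slow-time grid in seconds.
#' @return List with `respiration_m`, `cardiac_m`, `total_m` (= respiration +
#'   cardiac), `ao_times_s` (ground-truth aortic-opening instants), and
#'   `slow_time_s`.
#' @export
synthesize_chest_displacement <- function(scene, beat_times_s, slow_time_s) {
  stopifnot(inherits(scene, "scene_config"))
  n <- length(slow_time_s)
  if (n < 2L) stop("slow_time_s must have at least two samples")
  dt <- diff(slow_time_s)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("slow_time_s must be uniformly spaced")
  }
  f <- scene$respiration_rate_hz
  a <- scene$respiration_amplitude_m
  h <- scene$resp_harmonics
  respiration <- a * (sin(2 * pi * f * slow_time_s) +
                        h[1] * sin(2 * pi * 2 * f * slow_time_s) +
                        h[2] * sin(2 * pi * 3 * f * slow_time_s))
  cardiac <- numeric(n)
  support <- 0.32
  if (scene$heartbeat_amplitude_m > 0 && length(beat_times_s)) {
    if (any(diff(beat_times_s) < support)) {
      warning("inter-beat interval shorter than the SCG kernel support; ",
              "overlapping kernels are summed")
    }
    fs <- 1 / dt[1]
    for (tb in beat_times_s) {
      i0 <- floor((tb - slow_time_s[1]) * fs) + 1
      idx <- seq.int(max(1L, i0), min(n, i0 + ceiling(support * fs) + 1L))
      if (!length(idx)) next
      tt <- slow_time_s[idx] - tb
      sel <- tt >= 0 & tt <= support
      if (any(sel)) {
        cardiac[idx[sel]] <- cardiac[idx[sel]] +
          scene$heartbeat_amplitude_m * .scg_kernel_cont(tt[sel])
      }
    }
  }
  list(respiration_m = respiration,
       cardiac_m = cardiac,
       total_m = respiration + cardiac,
       ao_times_s = beat_times_s + .scg_ao_offset_s,
       slow_time_s = slow_time_s)
}

#' Render a scene into an IF data cube
#'
#' Simulates the raw intermediate-frequency samples of an FMCW radar watching
#' the scene. Each scatterer at instantaneous range `R_t` contributes, frame
#' by frame, a fast-time complex tone of frequency `2 * slope * R_t / c` with
#' phase `4 * pi * R_t / lambda`, and antenna `m` carries the narrowband
#' inter-element phase `exp(-1i * 2 * pi * m * d * sin(theta) / lambda)`.
#' The torso and any clutter scatterers move with respiration only; the heart
#' scatterer carries the cardiac micro-motion plus an attenuated respiration
#' share. Complex white Gaussian noise is added so that the heart scatterer's
#' post-range-FFT bin SNR equals `scene$snr_db`.
#'
#' @param scene A [scene_config()].
#' @param chirp A [chirp_config()].
#' @param displacement Optional output of [synthesize_chest_displacement()];
#'   generated internally (with the scene's IBI model and seed) when `NULL`.
#' @return List with `cube` (class `ifdata_cube`: complex array
#'   `[frame, fast sample, antenna]` plus metadata) and `truth` (class
#'   `ground_truth`: beat and AO times, IBIs, the heart-scatterer
#'   displacement trace, and the heart azimuth).
#' @export
synthesize_if_cube <- function(scene, chirp = chirp_config(),
                               displacement = NULL) {
  stopifnot(inherits(scene, "scene_config"), inherits(chirp, "chirp_config"))
  r_max <- max_unambiguous_range(chirp)
  ranges <- c(scene$target_range_m,
              vapply(scene$clutter_scatterers, function(s) s$range_m, 0))
  if (any(ranges >= r_max)) {
    stop(sprintf("scatterer range beyond the unambiguous range %.2f m", r_max))
  }
  az <- c(scene$heart_azimuth_deg, scene$torso_azimuth_deg,
          vapply(scene$clutter_scatterers, function(s) s$azimuth_deg, 0))
  if (any(abs(az) > 90)) stop("scatterer azimuth outside the array field of view")

  fs <- chirp$fs_slow_hz
  n_frames <- as.integer(round(scene$duration_s * fs)) + 1L
  slow_t <- (seq_len(n_frames) - 1) / fs
  if (is.null(displacement)) {
    beats <- generate_ibi_sequence(scene$ibi_model, scene$duration_s,
                                   seed = scene$seed)
    displacement <- synthesize_chest_displacement(scene, beats$beat_times_s,
                                                  slow_t)
  } else {
    if (length(displacement$total_m) != n_frames) {
      stop("displacement is not on the cube's slow-time grid")
    }
    beats <- list(beat_times_s = displacement$ao_times_s - .scg_ao_offset_s,
                  ibi_ms = diff(displacement$ao_times_s) * 1000)
  }

  heart_disp <- scene$heart_respiration_scale * displacement$respiration_m +
    displacement$cardiac_m
  torso_disp <- displacement$respiration_m

  n_fast <- chirp$n_fast_samples
  M <- chirp$n_virtual_antennas
  t_fast <- (seq_len(n_fast) - 1) / chirp$adc_sample_rate_hz
  lambda <- chirp$wavelength_m
  slope <- chirp$frequency_slope_hz_per_s
  dl <- chirp$element_spacing_m / lambda

  cube <- array(0 + 0i, dim = c(n_frames, n_fast, M))
  add_scatterer <- function(range_t, theta_deg, amp) {
    if (amp == 0) return(invisible())
    f_if <- 2 * slope * range_t / .c0
    ph0 <- 4 * pi * range_t / lambda
    base <- exp(1i * (outer(2 * pi * f_if, t_fast) + ph0))
    steer <- exp(-1i * 2 * pi * (0:(M - 1)) * dl * sin(theta_deg * pi / 180))
    for (m in seq_len(M)) {
      cube[, , m] <<- cube[, , m] + (amp * steer[m]) * base
    }
    invisible()
  }

  add_scatterer(scene$target_range_m + heart_disp, scene$heart_azimuth_deg, 1)
  add_scatterer(scene$target_range_m + torso_disp, scene$torso_azimuth_deg,
                scene$torso_rcs_scale)
  for (cl in scene$clutter_scatterers) {
    add_scatterer(rep(cl$range_m, n_frames), cl$azimuth_deg, cl$rcs_scale)
  }

  if (is.finite(scene$snr_db)) {
    # Bin SNR after an n_fast-point rectangular FFT for a unit-amplitude tone:
    # peak power n_fast^2 * A^2, bin noise power n_fast * sigma^2.
    sigma2 <- n_fast / 10^(scene$snr_db / 10)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(.sub_seed(scene$seed, 2L))
    ntot <- n_frames * n_fast * M
    noise <- sqrt(sigma2 / 2) * (stats::rnorm(ntot) + 1i * stats::rnorm(ntot))
    cube <- cube + array(noise, dim = dim(cube))
  }

  out_cube <- structure(
    list(samples = cube, chirp = chirp, provenance = "simulated"),
    class = "ifdata_cube")
  if (scene$heartbeat_amplitude_m == 0) {
    # no cardiac micro-motion rendered: there are no true beats to recover
    beats <- list(beat_times_s = numeric(0), ibi_ms = numeric(0))
  }
  truth <- structure(
    list(beat_times_s = beats$beat_times_s,
         ao_times_s = beats$beat_times_s + .scg_ao_offset_s,
         ibi_ms = beats$ibi_ms,
         displacement_m = heart_disp,
         respiration_m = displacement$respiration_m,
         slow_time_s = slow_t,
         heart_azimuth_deg = scene$heart_azimuth_deg),
    class = "ground_truth")
  list(cube = out_cube, truth = truth)
}

#' Simulate a complete scene
#'
#' Convenience wrapper: draws the beat sequence, builds the chest
#' displacement, and renders the IF cube.
#'
#' @inheritParams synthesize_if_cube
#' @return As [synthesize_if_cube()].
#' @examples
#' sim <- simulate_scene(scene_config(duration_s = 2, snr_db = Inf),
#'                       chirp_config(n_fast_samples = 32L))
#' dim(sim$cube$samples)
#' @export
simulate_scene <- function(scene, chirp = chirp_config()) {
  synthesize_if_cube(scene, chirp)
}

#' @export
print.ifdata_cube <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("IF data cube (%s): %d frames x %d fast samples x %d antennas\n",
              x$provenance, d[1], d[2], d[3]))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d beats, heart azimuth %+.1f deg\n",
              length(x$beat_times_s), x$heart_azimuth_deg))
  invisible(x)
}
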