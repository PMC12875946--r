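#' Chirp and array configuration
#'
#' Describes one FMCW chirp and the virtual receive array. Defaults follow a
#' 77 GHz automotive-band radar operated for vital-sign sensing: 60 MHz/us
#' frequency slope, 60 us ramp, 5 Msps ADC, 5 ms frame period (so the
#' slow-time -- frame-to-frame -- sampling rate is 200 Hz), and a
#' time-division-multiplexed 2T4R antenna pair synthesizing an 8-element
#' virtual uniform linear array at half-wavelength spacing.
#'
#' The effective sweep bandwidth is `frequency_slope_hz_per_s` times the ADC
#' observation window `n_fast_samples / adc_sample_rate_hz`; the carrier
#' wavelength is `c / start_frequency_hz` unless `wavelength_m` is given
#' explicitly (useful to pin a round 4 mm wavelength in analytic checks).
#'
#' @param start_frequency_hz Chirp start (carrier) frequency in Hz.
#' @param frequency_slope_hz_per_s Chirp frequency slope in Hz/s.
#' @param ramp_end_time_s Chirp ramp duration in seconds.
#' @param adc_sample_rate_hz Fast-time (ADC) sampling rate in samples/s.
#' @param n_fast_samples ADC samples per chirp.
#' @param frame_period_s Frame (chirp repetition) period in seconds; its
#'   reciprocal is the slow-time sampling rate.
#' @param n_virtual_antennas Number of virtual array elements (>= 2).
#' @param element_spacing_m Inter-element spacing in metres; default half the
#'   carrier wavelength.
#' @param wavelength_m Optional carrier wavelength override in metres.
#' @return An object of class `chirp_config`.
#' @examples
#' cfg <- chirp_config()
#' cfg$fs_slow_hz      # 200
#' cfg$wavelength_m    # ~3.9 mm at 77 GHz
#' @export
chirp_config <- function(start_frequency_hz = 77e9,
                         frequency_slope_hz_per_s = 60e12,
                         ramp_end_time_s = 60e-6,
                         adc_sample_rate_hz = 5e6,
                         n_fast_samples = 128L,
                         frame_period_s = 5e-3,
                         n_virtual_antennas = 8L,
                         element_spacing_m = NULL,
                         wavelength_m = NULL) {
  .assert_scalar_num(start_frequency_hz, "start_frequency_hz", lo = 1e6)
  .assert_scalar_num(frequency_slope_hz_per_s, "frequency_slope_hz_per_s", lo = 1)
  .assert_scalar_num(ramp_end_time_s, "ramp_end_time_s", lo = 1e-9)
  .assert_scalar_num(adc_sample_rate_hz, "adc_sample_rate_hz", lo = 1)
  .assert_scalar_num(n_fast_samples, "n_fast_samples", lo = 2)
  .assert_scalar_num(frame_period_s, "frame_period_s", lo = 1e-6)
  .assert_scalar_num(n_virtual_antennas, "n_virtual_antennas", lo = 2)
  if (frame_period_s <= ramp_end_time_s) {
    stop("frame_period_s must exceed ramp_end_time_s")
  }
  adc_window_s <- n_fast_samples / adc_sample_rate_hz
  if (adc_window_s > ramp_end_time_s) {
    stop("ADC window (n_fast_samples / adc_sample_rate_hz) exceeds the ramp duration")
  }
  if (is.null(wavelength_m)) wavelength_m <- .c0 / start_frequency_hz
  .assert_scalar_num(wavelength_m, "wavelength_m", lo = 1e-6)
  if (is.null(element_spacing_m)) element_spacing_m <- wavelength_m / 2
  .assert_scalar_num(element_spacing_m, "element_spacing_m", lo = 1e-9)
  cfg <- list(
    start_frequency_hz = start_frequency_hz,
    frequency_slope_hz_per_s = frequency_slope_hz_per_s,
    ramp_end_time_s = ramp_end_time_s,
    adc_sample_rate_hz = adc_sample_rate_hz,
    n_fast_samples = as.integer(n_fast_samples),
    frame_period_s = frame_period_s,
    n_virtual_antennas = as.integer(n_virtual_antennas),
    element_spacing_m = element_spacing_m,
    wavelength_m = wavelength_m,
    bandwidth_hz = frequency_slope_hz_per_s * adc_window_s,
    fs_slow_hz = 1 / frame_period_s
  )
  class(cfg) <- "chirp_config"
  cfg
}

#' @export
print.chirp_config <- function(x, ...) {
  cat("FMCW chirp configuration\n")
  cat(sprintf("  carrier %.2f GHz (lambda %.3f mm), slope %.1f MHz/us\n",
              x$start_frequency_hz / 1e9, x$wavelength_m * 1e3,
              x$frequency_slope_hz_per_s / 1e12))
  cat(sprintf("  %d fast samples @ %.1f Msps (B_eff %.2f GHz)\n",
              x$n_fast_samples, x$adc_sample_rate_hz / 1e6, x$bandwidth_hz / 1e9))
  cat(sprintf("  frame period %.1f ms (slow-time %.0f Hz), %d virtual antennas, d = %.3f mm\n",
              x$frame_period_s * 1e3, x$fs_slow_hz, x$n_virtual_antennas,
              x$element_spacing_m * 1e3))
  invisible(x)
}

#' Maximum unambiguous range of a chirp configuration
#'
#' Range mapped to the highest retained beat frequency (half the complex ADC
#' rate): `R_max = (fs_adc / 2) * c / (2 * slope)`.
#'
#' @param chirp A [chirp_config()].
#' @return Range in metres.
#' @export
max_unambiguous_range <- function(chirp) {
  stopifnot(inherits(chirp, "chirp_config"))
  (chirp$adc_sample_rate_hz / 2) * .c0 / (2 * chirp$frequency_slope_hz_per_s)
}

#' Scene description for the radar simulator
#'
#' Encodes the geometry and kinematics of a supine subject under a
#' downward-looking radar: a torso scatterer dominated by respiration
#' (chest-wall displacements of a few millimetres at 0.1-0.5 Hz) and a heart
#' scatterer at its own azimuth carrying the cardiac micro-motion (a few
#' tenths of a millimetre per beat) plus an attenuated share of respiration.
#' Optional static clutter scatterers and additive complex white noise model
#' the environment.
#'
#' Respiration is a sinusoid at `respiration_rate_hz` with relative second and
#' third harmonic amplitudes `resp_harmonics` (defaults 10% and 5%), so the
#' third respiratory harmonic genuinely overlaps the conventional heartbeat
#' band -- the separation problem the wavelet-packet stage addresses.
#'
#' @param target_range_m Radial distance of the chest from the radar (m).
#' @param heart_azimuth_deg Azimuth of the heart scatterer, degrees in
#'   (-90, 90).
#' @param torso_azimuth_deg Azimuth of the respiration-dominated torso
#'   scatterer.
#' @param respiration_amplitude_m Fundamental respiration displacement
#'   amplitude (m), typically 3-12 mm.
#' @param respiration_rate_hz Respiration rate (Hz), typically 0.1-0.5.
#' @param resp_harmonics Length-2 numeric: relative amplitudes of the 2nd and
#'   3rd respiration harmonics.
#' @param heartbeat_amplitude_m Peak cardiac micro-motion amplitude (m),
#'   typically 0.1-0.5 mm.
#' @param heart_respiration_scale Fraction of the respiration displacement
#'   present at the heart scatterer.
#' @param torso_rcs_scale Reflected amplitude of the torso scatterer relative
#'   to the heart scatterer (set 0 to remove the torso entirely).
#' @param ibi_model List with `mean_s`, `sd_s`, `distribution` ("gaussian"),
#'   and optional lag-1 correlation `ar1`; governs the simulated inter-beat
#'   intervals.
#' @param clutter_scatterers List of static scatterers, each a list with
#'   `range_m`, `azimuth_deg`, `rcs_scale`.
#' @param snr_db Signal-to-noise ratio in dB, defined for the heart scatterer
#'   at its range bin after the (rectangular-window) range FFT.
#' @param duration_s Scene duration in seconds.
#' @param seed Master seed; sub-streams are derived for the beat sequence and
#'   the noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(target_range_m = 0.6,
                         heart_azimuth_deg = -10,
                         torso_azimuth_deg = 15,
                         respiration_amplitude_m = 5e-3,
                         respiration_rate_hz = 0.25,
                         resp_harmonics = c(0.10, 0.05),
                         heartbeat_amplitude_m = 0.3e-3,
                         heart_respiration_scale = 0.2,
                         torso_rcs_scale = 3,
                         ibi_model = list(mean_s = 1.0, sd_s = 0.05,
                                          distribution = "gaussian", ar1 = 0),
                         clutter_scatterers = list(),
                         snr_db = 20,
                         duration_s = 60,
                         seed = 1L) {
  .assert_scalar_num(target_range_m, "target_range_m", lo = 1e-3)
  .assert_scalar_num(heart_azimuth_deg, "heart_azimuth_deg", lo = -90, hi = 90)
  .assert_scalar_num(torso_azimuth_deg, "torso_azimuth_deg", lo = -90, hi = 90)
  .assert_scalar_num(respiration_amplitude_m, "respiration_amplitude_m", lo = 0)
  .assert_scalar_num(respiration_rate_hz, "respiration_rate_hz", lo = 0)
  stopifnot(is.numeric(resp_harmonics), length(resp_harmonics) == 2)
  .assert_scalar_num(heartbeat_amplitude_m, "heartbeat_amplitude_m", lo = 0)
  .assert_scalar_num(heart_respiration_scale, "heart_respiration_scale", lo = 0)
  .assert_scalar_num(torso_rcs_scale, "torso_rcs_scale", lo = 0)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop("'snr_db' must be a numeric scalar (Inf for a noise-free scene)")
  }
  .assert_scalar_num(duration_s, "duration_s", lo = 1e-3)
  if (!is.list(ibi_model) || is.null(ibi_model$mean_s)) {
    stop("ibi_model must be a list with at least 'mean_s'")
  }
  ibi_model <- utils::modifyList(
    list(mean_s = 1.0, sd_s = 0.05, distribution = "gaussian", ar1 = 0),
    ibi_model)
  .assert_scalar_num(ibi_model$mean_s, "ibi_model$mean_s", lo = 0.4, hi = 2.0)
  .assert_scalar_num(ibi_model$sd_s, "ibi_model$sd_s", lo = 0)
  .assert_scalar_num(ibi_model$ar1, "ibi_model$ar1", lo = -0.99, hi = 0.99)
  for (cl in clutter_scatterers) {
    .assert_scalar_num(cl$range_m, "clutter range_m", lo = 1e-3)
    .assert_scalar_num(cl$azimuth_deg, "clutter azimuth_deg", lo = -90, hi = 90)
    .assert_scalar_num(cl$rcs_scale, "clutter rcs_scale", lo = 0)
  }
  sc <- list(
    target_range_m = target_range_m,
    heart_azimuth_deg = heart_azimuth_deg,
    torso_azimuth_deg = torso_azimuth_deg,
    respiration_amplitude_m = respiration_amplitude_m,
    respiration_rate_hz = respiration_rate_hz,
    resp_harmonics = as.numeric(resp_harmonics),
    heartbeat_amplitude_m = heartbeat_amplitude_m,
    heart_respiration_scale = heart_respiration_scale,
    torso_rcs_scale = torso_rcs_scale,
    ibi_model = ibi_model,
    clutter_scatterers = clutter_scatterers,
    snr_db = snr_db,
    duration_s = duration_s,
    seed = as.integer(seed)
  )
  class(sc) <- "scene_config"
  sc
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Radar scene\n")
  cat(sprintf("  chest at %.2f m; heart azimuth %+.1f deg, torso azimuth %+.1f deg\n",
              x$target_range_m, x$heart_azimuth_deg, x$torso_azimuth_deg))
  cat(sprintf("  respiration %.1f mm @ %.2f Hz; heartbeat %.2f mm; IBI %0.f +/- %.0f ms\n",
              x$respiration_amplitude_m * 1e3, x$respiration_rate_hz,
              x$heartbeat_amplitude_m * 1e3, x$ibi_model$mean_s * 1e3,
              x$ibi_model$sd_s * 1e3))
  cat(sprintf("  SNR %.1f dB, duration %.0f s, %d clutter scatterer(s), seed %d\n",
              x$snr_db, x$duration_s, length(x$clutter_scatterers), x$seed))
  invisible(x)
}
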