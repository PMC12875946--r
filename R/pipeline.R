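# End-to-end runner and file interchange (cube binary + JSON sidecar, CSV
# signal/event tables, JSON reports).

#' Pipeline configuration
#'
#' Collects the tunable constants of every stage with the standard values as
#' defaults: range FFT window, 20 s azimuth-search window on a 1-degree
#' \[-60, 60\] grid, level-6 db45 wavelet packets with leaves 6-12, AO
#' detector spacings (0.6 / 0.15 / 0.1 of `fs`), and the 400-2000 ms IBI
#' validity bounds.
#'
#' @param chirp A [chirp_config()].
#' @param n_fft Range FFT length (`NULL`: number of fast-time samples).
#' @param window Fast-time window, `"rect"` or `"hann"`.
#' @param search_grid_deg Azimuth grid (degrees).
#' @param search_window_s Azimuth-search window (s).
#' @param loading Covariance diagonal loading.
#' @param template `scg_template` or `NULL` for the packaged default.
#' @param wavelet,wpt_level,bands Wavelet-packet settings.
#' @param ao_delta,ao_delta1,ao_delta2,ao_mask_radius_s AO detector
#'   parameters, see [detect_ao()].
#' @param ibi_min_ms,ibi_max_ms IBI validity bounds (ms).
#' @param sdnn_denom,pnn50_denom HRV conventions, see [hrv_metrics()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(chirp = chirp_config(),
                            n_fft = NULL,
                            window = "rect",
                            search_grid_deg = seq(-60, 60, by = 1),
                            search_window_s = 20,
                            loading = 0.1,
                            template = NULL,
                            wavelet = "db45",
                            wpt_level = 6,
                            bands = 6:12,
                            ao_delta = 0.6,
                            ao_delta1 = 0.15,
                            ao_delta2 = 0.1,
                            ao_mask_radius_s = 0.025,
                            ibi_min_ms = 400,
                            ibi_max_ms = 2000,
                            sdnn_denom = "population",
                            pnn50_denom = "n") {
  stopifnot(inherits(chirp, "chirp_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full radar-to-HRV pipeline
#'
#' Executes the processing chain on an IF data cube (or simulates one first
#' from a scene): range FFT, static clutter removal, target-gate selection,
#' 20 s SQI azimuth search with frozen Capon weights, DACM demodulation,
#' wavelet-packet SCG reconstruction, AO detection, and HRV metrics. When
#' ground truth is available (simulated input) the result also carries the
#' beat-timing agreement report.
#'
#' @param x A `scene_config`, an `ifdata_cube`, or the list returned by
#'   [simulate_scene()].
#' @param config A [pipeline_config()]; its chirp is used when `x` is a
#'   scene.
#' @return List of class `pipeline_result` with `sqi_profile`, `vitals`,
#'   `scg`, `ao`, `ibi`, `hrv`, optional `truth` and `agreement`, and a
#'   `manifest` (config digest, stage timings, warnings, package version).
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  warns <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  note <- function(nm, t0) timings[[nm]] <<- round(tic() - t0, 3)

  truth <- NULL
  if (inherits(x, "scene_config")) {
    t0 <- tic()
    sim <- synthesize_if_cube(x, config$chirp)
    cube <- sim$cube
    truth <- sim$truth
    note("simulate", t0)
  } else if (inherits(x, "ifdata_cube")) {
    cube <- x
  } else if (is.list(x) && inherits(x$cube, "ifdata_cube")) {
    cube <- x$cube
    truth <- x$truth
  } else {
    stop("x must be a scene_config, an ifdata_cube, or a simulate_scene() result")
  }

  t0 <- tic()
  prof <- range_fft(cube, n_fft = config$n_fft, window = config$window)
  prof <- remove_static_clutter(prof)
  snaps <- select_target_bin(prof)
  note("rangeproc", t0)

  fs <- snaps$fs_slow_hz
  t0 <- tic()
  tpl <- if (is.null(config$template)) scg_template(fs_hz = fs) else config$template
  prof_sqi <- withCallingHandlers(
    search_heart_azimuth(snaps, template = tpl,
                         grid_deg = config$search_grid_deg,
                         window_s = config$search_window_s,
                         loading = config$loading,
                         wavelet = config$wavelet,
                         bands = config$bands),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  note("azimuth_search", t0)

  t0 <- tic()
  y <- beamform_output(prof_sqi$weights_opt, snaps$X_raw)
  vitals <- mdacm_demodulate(y, fs_hz = fs,
                             wavelength_m = cube$chirp$wavelength_m)
  note("demodulate", t0)

  t0 <- tic()
  dec <- wpt_decompose(vitals$phase_rad, level = config$wpt_level,
                       wavelet = config$wavelet, fs_hz = fs)
  scg <- reconstruct_scg(dec, bands = config$bands)
  note("scg_extraction", t0)

  t0 <- tic()
  ao <- withCallingHandlers(
    detect_ao(scg, delta = config$ao_delta, delta1 = config$ao_delta1,
              delta2 = config$ao_delta2,
              mask_radius_s = config$ao_mask_radius_s),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ibi <- ibi_from_events(ao, min_ms = config$ibi_min_ms,
                         max_ms = config$ibi_max_ms)
  hrv <- if (ibi$n_kept >= 2) {
    hrv_metrics(ibi, sdnn_denom = config$sdnn_denom,
                pnn50_denom = config$pnn50_denom)
  } else {
    warns <- c(warns, "insufficient beats for HRV metrics")
    NULL
  }
  note("ao_hrv", t0)

  agreement <- NULL
  if (!is.null(truth) && length(ao$times_s) >= 3 &&
      length(truth$ao_times_s) >= 3) {
    agreement <- tryCatch(compare_to_reference(ao, truth$ao_times_s),
                          error = function(e) NULL)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("radarscg")),
    config_digest = .object_digest(unclass(config)),
    frozen_azimuth_deg = prof_sqi$best_angle_deg,
    target_bin_index = snaps$target_bin_index,
    target_range_m = snaps$target_range_m,
    stage_timings_s = as.list(timings),
    warnings = warns
  )
  structure(list(sqi_profile = prof_sqi, snapshots = snaps, vitals = vitals,
                 scg = scg, ao = ao, ibi = ibi, hrv = hrv, truth = truth,
                 agreement = agreement, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Radar SCG/HRV pipeline result\n")
  cat(sprintf("  frozen azimuth %+g deg at range %.2f m (bin %d)\n",
              x$manifest$frozen_azimuth_deg, x$manifest$target_range_m,
              x$manifest$target_bin_index))
  cat(sprintf("  %d AO events, %d/%d valid IBIs\n",
              length(x$ao$indices), x$ibi$n_kept, x$ibi$n_raw))
  if (!is.null(x$hrv)) print(x$hrv) else cat("  HRV: insufficient beats\n")
  if (!is.null(x$agreement)) {
    cat(sprintf("  vs ground truth: IBI MAE %.2f ms, MRE %.3f%%\n",
                x$agreement$mae_ms, x$agreement$mre_percent))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# File interchange

#' Write / read an IF data cube
#'
#' The cube is stored as one binary file of little-endian complex64 values
#' (interleaved float32 real/imaginary) in `[frame, fast sample, antenna]`
#' C order, next to a JSON sidecar `<path>.json` carrying the chirp
#' configuration, array shape, and provenance. [read_if_cube()] reverses the
#' layout and validates the sidecar.
#'
#' @param cube An `ifdata_cube`.
#' @param path Path of the binary payload; the sidecar is `<path>.json`.
#' @return `write_if_cube`: `path`, invisibly. `read_if_cube`: an
#'   `ifdata_cube`.
#' @export
write_if_cube <- function(cube, path) {
  stopifnot(inherits(cube, "ifdata_cube"))
  d <- dim(cube$samples)
  # C order [frame, fast, antenna]: antenna fastest-varying
  perm <- aperm(cube$samples, c(3, 2, 1))
  inter <- numeric(2 * length(perm))
  inter[c(TRUE, FALSE)] <- Re(perm)
  inter[c(FALSE, TRUE)] <- Im(perm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(inter, con, size = 4, endian = "little")
  sidecar <- list(
    format = "radarscg-ifcube-v1",
    dtype = "complex64-le",
    order = "c",
    shape = list(n_frames = d[1], n_fast_samples = d[2],
                 n_virtual_antennas = d[3]),
    chirp = cube$chirp[setdiff(names(cube$chirp), character(0))],
    provenance = cube$provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_if_cube
#' @export
read_if_cube <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar '", sidecar_path, "': expected a JSON file with ",
         "keys format, dtype, order, shape {n_frames, n_fast_samples, ",
         "n_virtual_antennas}, chirp, provenance")
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  req <- c("format", "dtype", "shape", "chirp")
  if (!all(req %in% names(sc))) {
    stop("sidecar is missing required keys: ",
         paste(setdiff(req, names(sc)), collapse = ", "))
  }
  d <- c(sc$shape$n_frames, sc$shape$n_fast_samples, sc$shape$n_virtual_antennas)
  n <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  inter <- readBin(con, what = "numeric", n = 2 * n, size = 4,
                   endian = "little")
  if (length(inter) != 2 * n) stop("cube payload shorter than the sidecar shape")
  z <- complex(real = inter[c(TRUE, FALSE)], imaginary = inter[c(FALSE, TRUE)])
  samples <- aperm(array(z, dim = rev(d)), c(3, 2, 1))
  chirp <- chirp_config(
    start_frequency_hz = sc$chirp$start_frequency_hz,
    frequency_slope_hz_per_s = sc$chirp$frequency_slope_hz_per_s,
    ramp_end_time_s = sc$chirp$ramp_end_time_s,
    adc_sample_rate_hz = sc$chirp$adc_sample_rate_hz,
    n_fast_samples = sc$chirp$n_fast_samples,
    frame_period_s = sc$chirp$frame_period_s,
    n_virtual_antennas = sc$chirp$n_virtual_antennas,
    element_spacing_m = sc$chirp$element_spacing_m,
    wavelength_m = sc$chirp$wavelength_m)
  structure(list(samples = samples, chirp = chirp,
                 provenance = if (is.null(sc$provenance)) "imported" else sc$provenance),
            class = "ifdata_cube")
}

#' Write / read a sampled signal as CSV
#'
#' Two-column CSV with header `time_s,value` (0-based sample indices map to
#' `time_s = index / fs`). Both comma- and semicolon-delimited dialects are
#' read via `dialect`.
#'
#' @param x Numeric signal (or `vital_sign_signal` / `scg_signal`).
#' @param path File path.
#' @param fs_hz Sampling rate used for the time column.
#' @param value_name Column name of the payload.
#' @param dialect `"comma"` or `"semicolon"`.
#' @return `write_signal_csv`: `path` invisibly; `read_signal_csv`: list
#'   with `value`, `time_s`, `fs_hz`.
#' @export
write_signal_csv <- function(x, path, fs_hz = 200, value_name = "value") {
  if (inherits(x, "vital_sign_signal")) { fs_hz <- x$fs_hz; x <- x$phase_rad }
  if (inherits(x, "scg_signal")) { fs_hz <- x$fs_hz; x <- x$samples }
  df <- data.frame(time_s = (seq_along(x) - 1) / fs_hz, value = as.numeric(x))
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, dialect = c("comma", "semicolon")) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "comma") utils::read.csv(path) else utils::read.csv2(path)
  if (ncol(df) < 2L || !("time_s" %in% names(df))) {
    stop("expected a CSV with columns time_s,<value>")
  }
  tv <- df$time_s
  fs <- if (length(tv) > 1) 1 / stats::median(diff(tv)) else NA_real_
  list(value = df[[setdiff(names(df), "time_s")[1]]], time_s = tv, fs_hz = fs)
}

#' Write / read AO events as CSV
#'
#' Columns `index` (0-based sample position) and `time_s`.
#'
#' @param events An `ao_events` object.
#' @param path File path.
#' @param fs_hz Sampling rate used when reading back.
#' @return `write_events_csv`: `path` invisibly; `read_events_csv`: an
#'   `ao_events` object.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "ao_events"))
  utils::write.csv(data.frame(index = events$indices - 1L,
                              time_s = events$times_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, fs_hz = 200) {
  df <- utils::read.csv(path)
  if (!all(c("index", "time_s") %in% names(df))) {
    stop("expected a CSV with columns index,time_s")
  }
  structure(list(indices = as.integer(df$index) + 1L, times_s = df$time_s,
                 fs_hz = fs_hz, n_discarded_cycles = NA_integer_),
            class = "ao_events")
}

#' Read an SCG template from CSV
#'
#' Accepts the [write_signal_csv()] layout; the signal is z-normalized.
#'
#' @param path File path.
#' @param dialect CSV dialect, see [read_signal_csv()].
#' @return An `scg_template`.
#' @export
read_template_csv <- function(path, dialect = "comma") {
  sig <- read_signal_csv(path, dialect = dialect)
  structure(list(samples = znormalize(sig$value), fs_hz = sig$fs_hz,
                 provenance = paste0("file:", basename(path))),
            class = "scg_template")
}

#' Write an HRV or agreement report as JSON
#'
#' @param x An `hrv_metrics`, `ibi_agreement`, or plain list.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
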