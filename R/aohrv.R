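# AO fiducial detection on the SCG and time-domain HRV metrics.

#' Hilbert envelope pair of an SCG signal
#'
#' Upper and lower envelopes as the signal mean plus/minus the magnitude of
#' the analytic signal of the mean-removed SCG, giving the symmetric pair the
#' AO detector segments cardiac cycles with.
#'
#' @param scg Numeric SCG signal or an `scg_signal`.
#' @param fs_hz Sampling rate (Hz); taken from the object if available.
#' @return List with `upper`, `lower` (same length as the input) and `fs_hz`.
#' @export
envelopes <- function(scg, fs_hz = 200) {
  if (inherits(scg, "scg_signal")) {
    fs_hz <- scg$fs_hz
    scg <- scg$samples
  }
  m <- mean(scg)
  e <- Mod(.analytic_signal(scg - m))
  list(upper = m + e, lower = m - e, fs_hz = fs_hz)
}

#' Detect aortic-opening (AO) fiducials on an SCG signal
#'
#' Envelope-guided neighborhood search. Per cardiac cycle:
#' \enumerate{
#'   \item Find peaks of the upper envelope and troughs of the lower envelope
#'     with minimum separation `delta * fs` samples, and pair them
#'     positionally (i-th peak with i-th trough, truncated to the common
#'     count).
#'   \item Discard pairs whose peak/trough positions differ by
#'     `delta1 * fs` samples or more (noisy cycle segments).
#'   \item In the window of half-width `delta2 * fs` samples around the
#'     trough, locate the deepest minimum (the IM trough), mask its
#'     neighborhood, and locate the second minimum (the IC trough).
#'   \item The AO fiducial is the maximum of the raw SCG strictly between the
#'     IM and IC candidates.
#' }
#' The mask applied in step 3 covers `mask_radius_s` around the first
#' minimum (default 25 ms) so the second search returns the second-deepest
#' *local* minimum rather than the immediate neighbor of the first on a
#' band-limited signal; `mask_radius_s = 0` masks the single argmin sample
#' only. Cycles whose search window is clipped below 0.15 s, or whose IM/IC
#' candidates leave no interior samples, are discarded and counted.
#'
#' @param scg Numeric SCG signal or an `scg_signal`.
#' @param fs_hz Sampling rate (Hz).
#' @param delta Minimum envelope peak spacing, in seconds times `fs` (0.6).
#' @param delta1 Maximum peak/trough x-offset, seconds times `fs` (0.15).
#' @param delta2 Search half-window, seconds times `fs` (0.1).
#' @param mask_radius_s Half-width of the mask around the first minimum
#'   before the second-minimum search, in seconds.
#' @return Object of class `ao_events`: `indices` (1-based sample
#'   positions), `times_s` (`(indices - 1) / fs`), `fs_hz`, and
#'   `n_discarded_cycles`. Empty (with a warning) when no cycle qualifies.
#' @export
detect_ao <- function(scg, fs_hz = 200, delta = 0.6, delta1 = 0.15,
                      delta2 = 0.1, mask_radius_s = 0.025) {
  if (inherits(scg, "scg_signal")) {
    fs_hz <- scg$fs_hz
    scg <- scg$samples
  }
  scg <- as.numeric(scg)
  L <- length(scg)
  if (L < 2 * fs_hz) stop("need at least 2 s of SCG signal")
  env <- envelopes(scg, fs_hz)
  min_space <- as.integer(round(delta * fs_hz))
  x1 <- .find_peaks(env$upper, min_spacing = min_space)
  x2 <- .find_peaks(-env$lower, min_spacing = min_space)
  n_pairs <- min(length(x1), length(x2))
  n_disc <- 0L
  ao <- integer(0)
  if (n_pairs > 0) {
    x1 <- x1[seq_len(n_pairs)]
    x2 <- x2[seq_len(n_pairs)]
    dwin <- as.integer(round(delta2 * fs_hz))
    mask_r <- as.integer(round(mask_radius_s * fs_hz))
    for (i in seq_len(n_pairs)) {
      if (abs(x1[i] - x2[i]) >= delta1 * fs_hz) {
        n_disc <- n_disc + 1L
        next
      }
      a <- max(1L, x2[i] - dwin)
      b <- min(L, x2[i] + dwin)
      if ((b - a + 1L) < 0.15 * fs_hz) {       # window clipped too hard
        n_disc <- n_disc + 1L
        next
      }
      seg <- scg[a:b]
      i1 <- which.min(seg)
      x21 <- a + i1 - 1L
      masked <- seg
      masked[max(1L, i1 - mask_r):min(length(seg), i1 + mask_r)] <- Inf
      if (all(!is.finite(masked))) {
        n_disc <- n_disc + 1L
        next
      }
      i2 <- which.min(masked)
      x22 <- a + i2 - 1L
      lo <- min(x21, x22)
      hi <- max(x21, x22)
      if (hi - lo < 2L) {                      # empty open interval
        n_disc <- n_disc + 1L
        next
      }
      inner <- (lo + 1L):(hi - 1L)
      ao <- c(ao, inner[which.max(scg[inner])])
    }
  }
  ao <- sort(unique(ao))
  if (!length(ao)) warning("no valid cardiac cycles found")
  structure(list(indices = ao, times_s = (ao - 1) / fs_hz, fs_hz = fs_hz,
                 n_discarded_cycles = n_disc),
            class = "ao_events")
}

#' @export
print.ao_events <- function(x, ...) {
  cat(sprintf("AO events: %d fiducials at %.0f Hz (%d cycle(s) discarded)\n",
              length(x$indices), x$fs_hz, x$n_discarded_cycles))
  invisible(x)
}

#' Inter-beat intervals from AO events
#'
#' Successive differences of the AO times in milliseconds, with a validity
#' filter keeping intervals inside `[min_ms, max_ms]` (inclusive; defaults
#' 400-2000 ms). The filter removes the double-length intervals injected by
#' discarded cycles as well as physiologically impossible values.
#'
#' @param events An `ao_events` object, or a numeric vector of beat times in
#'   seconds.
#' @param min_ms,max_ms Inclusive validity bounds in milliseconds.
#' @return Object of class `ibi_series`: `ibi_ms` (kept intervals), `n_raw`,
#'   `n_kept`.
#' @examples
#' ibi_from_events(c(0, 1, 2, 3))$ibi_ms   # 1000 1000 1000
#' @export
ibi_from_events <- function(events, min_ms = 400, max_ms = 2000) {
  times <- if (inherits(events, "ao_events")) events$times_s else as.numeric(events)
  raw <- diff(times) * 1000
  keep <- raw >= min_ms & raw <= max_ms
  structure(list(ibi_ms = raw[keep], n_raw = length(raw),
                 n_kept = sum(keep)),
            class = "ibi_series")
}

#' Time-domain HRV metrics
#'
#' SDNN, RMSSD, and pNN50 of an inter-beat-interval series:
#' \deqn{SDNN = \sqrt{\tfrac{1}{N}\sum_i (IBI_i - \overline{IBI})^2}, \quad
#'       RMSSD = \sqrt{\tfrac{1}{N-1}\sum_{i=2}^{N} (IBI_i - IBI_{i-1})^2},}
#' and pNN50 the percentage of successive differences strictly exceeding
#' 50 ms. SDNN defaults to the population (1/N) form; the sample (1/(N-1))
#' form is available and differs exactly by `sqrt(N / (N - 1))`. pNN50
#' defaults to the `N` denominator; the conventional `N - 1` (number of
#' successive differences) is available.
#'
#' @param ibi An `ibi_series` or numeric vector of intervals in ms (N >= 2).
#' @param sdnn_denom `"population"` (1/N, default) or `"sample"` (1/(N-1)).
#' @param pnn50_denom `"n"` (default) or `"nm1"`.
#' @return Object of class `hrv_metrics`: `sdnn_ms`, `rmssd_ms`,
#'   `pnn50_percent`, `n_intervals`.
#' @examples
#' hrv_metrics(c(800, 860, 800, 860))   # SDNN 30, RMSSD 60, pNN50 75
#' @export
hrv_metrics <- function(ibi, sdnn_denom = c("population", "sample"),
                        pnn50_denom = c("n", "nm1")) {
  sdnn_denom <- match.arg(sdnn_denom)
  pnn50_denom <- match.arg(pnn50_denom)
  x <- if (inherits(ibi, "ibi_series")) ibi$ibi_ms else as.numeric(ibi)
  N <- length(x)
  if (N < 2L) stop("need at least two inter-beat intervals")
  sdnn <- if (sdnn_denom == "population") {
    sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd(x)
  }
  dx <- diff(x)
  rmssd <- sqrt(sum(dx^2) / (N - 1))
  denom <- if (pnn50_denom == "n") N else N - 1L
  pnn50 <- 100 * sum(abs(dx) > 50) / denom
  structure(list(sdnn_ms = sdnn, rmssd_ms = rmssd, pnn50_percent = pnn50,
                 n_intervals = N),
            class = "hrv_metrics")
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf("HRV (n = %d): SDNN %.2f ms, RMSSD %.2f ms, pNN50 %.2f%%\n",
              x$n_intervals, x$sdnn_ms, x$rmssd_ms, x$pnn50_percent))
  invisible(x)
}

#' Agreement between a measured beat sequence and a reference
#'
#' Matches measured AO times to reference beat times (nearest neighbor
#' within `max_offset_s`, one-to-one), forms the inter-beat intervals of
#' consecutively matched beats on both sides, and summarizes their agreement:
#' mean absolute error (MAE, ms), mean relative error (MRE, %), RMSE,
#' Bland-Altman bias and 95% limits of agreement (bias +/- 1.96 sd of the
#' paired differences), and the absolute SDNN/RMSSD/pNN50 errors between the
#' two interval series.
#'
#' @param test `ao_events` or numeric beat times (s) of the method under
#'   evaluation.
#' @param reference `ao_events` or numeric reference beat times (s).
#' @param max_offset_s Maximum match distance (s).
#' @return Object of class `ibi_agreement`: matched interval pairs and the
#'   error/agreement summary.
#' @export
compare_to_reference <- function(test, reference, max_offset_s = 0.5) {
  tt <- if (inherits(test, "ao_events")) test$times_s else as.numeric(test)
  rt <- if (inherits(reference, "ao_events")) reference$times_s else as.numeric(reference)
  if (length(tt) < 3L || length(rt) < 3L) {
    stop("need at least three beats on each side")
  }
  # one-to-one nearest matching: for each reference beat take the closest
  # unclaimed test beat within the window
  match_idx <- rep(NA_integer_, length(rt))
  used <- logical(length(tt))
  for (j in seq_along(rt)) {
    d <- abs(tt - rt[j])
    d[used] <- Inf
    k <- which.min(d)
    if (is.finite(d[k]) && d[k] <= max_offset_s) {
      match_idx[j] <- k
      used[k] <- TRUE
    }
  }
  ok <- which(!is.na(match_idx))
  if (length(ok) < 3L) stop("fewer than three matched beats")
  # intervals between consecutively matched reference beats (consecutive on
  # both sides, so a missed beat does not fabricate a double interval)
  pairs_ref <- numeric(0)
  pairs_test <- numeric(0)
  for (i in seq_len(length(ok) - 1L)) {
    j1 <- ok[i]; j2 <- ok[i + 1L]
    if (j2 - j1 == 1L && match_idx[j2] - match_idx[j1] == 1L) {
      pairs_ref <- c(pairs_ref, (rt[j2] - rt[j1]) * 1000)
      pairs_test <- c(pairs_test, (tt[match_idx[j2]] - tt[match_idx[j1]]) * 1000)
    }
  }
  if (length(pairs_ref) < 2L) stop("fewer than two matched interval pairs")
  d <- pairs_test - pairs_ref
  bias <- mean(d)
  sd_d <- stats::sd(d)
  hrv_t <- hrv_metrics(pairs_test)
  hrv_r <- hrv_metrics(pairs_ref)
  structure(list(
    ibi_test_ms = pairs_test,
    ibi_ref_ms = pairs_ref,
    n_matched = length(pairs_ref),
    mae_ms = mean(abs(d)),
    mre_percent = mean(abs(d) / pairs_ref) * 100,
    rmse_ms = sqrt(mean(d^2)),
    bias_ms = bias,
    loa_ms = c(lower = bias - 1.96 * sd_d, upper = bias + 1.96 * sd_d),
    sdnn_error_ms = abs(hrv_t$sdnn_ms - hrv_r$sdnn_ms),
    rmssd_error_ms = abs(hrv_t$rmssd_ms - hrv_r$rmssd_ms),
    pnn50_error_percent = abs(hrv_t$pnn50_percent - hrv_r$pnn50_percent)
  ), class = "ibi_agreement")
}

#' @export
print.ibi_agreement <- function(x, ...) {
  cat(sprintf("IBI agreement over %d matched intervals\n", x$n_matched))
  cat(sprintf("  MAE %.2f ms, MRE %.3f%%, RMSE %.2f ms\n",
              x$mae_ms, x$mre_percent, x$rmse_ms))
  cat(sprintf("  Bland-Altman bias %.2f ms, 95%% LoA [%.2f, %.2f] ms\n",
              x$bias_ms, x$loa_ms[1], x$loa_ms[2]))
  cat(sprintf("  |dSDNN| %.2f ms, |dRMSSD| %.2f ms, |dpNN50| %.2f%%\n",
              x$sdnn_error_ms, x$rmssd_error_ms, x$pnn50_error_percent))
  invisible(x)
}
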