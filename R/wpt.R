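# Wavelet packet decomposition and band reconstruction of the SCG.

# Orthonormal scaling filters available to the transform. "db45" is the
# production choice (45 vanishing moments, 90 taps: narrow transition bands
# so the level-6 leaves behave like sharp uniform sub-band filters); "haar"
# is kept for small exact-arithmetic checks.
.wpt_filters <- function(wavelet) {
  h <- switch(wavelet,
              db45 = .db45_dec_lo,
              haar = c(1, 1) / sqrt(2),
              stop("unknown wavelet '", wavelet, "'; available: db45, haar"))
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)   # quadrature mirror highpass
  list(h = h, g = g)
}

#' Frequency band of a level-`level` wavelet packet leaf
#'
#' Under frequency (sequency) ordering, leaf `i` of a full wavelet packet
#' tree at depth `level` occupies
#' `((i - 1) * (fs / 2) / 2^level, i * (fs / 2) / 2^level)` Hz.
#'
#' @param i Leaf index, 1-based, in `1..2^level`.
#' @param fs_hz Sampling rate (Hz).
#' @param level Decomposition depth.
#' @return Numeric `c(lo_hz, hi_hz)`.
#' @examples
#' band_frequency_range(1)   # 0 .. 1.5625 Hz at fs = 200, level 6
#' band_frequency_range(6)   # lower edge 7.8125 Hz
#' @export
band_frequency_range <- function(i, fs_hz = 200, level = 6) {
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > 2^level || i != round(i)) {
    stop(sprintf("leaf index must be an integer in 1..%d", 2^level))
  }
  c(lo_hz = (i - 1) * (fs_hz / 2) / 2^level,
    hi_hz = i * (fs_hz / 2) / 2^level)
}

#' Full wavelet packet decomposition
#'
#' Decomposes a signal into the `2^level` leaves of a full wavelet packet
#' tree using a periodized orthonormal filter bank, and orders the leaves by
#' frequency (sequency) so that leaf `i` occupies the band reported by
#' [band_frequency_range()]. The transform is orthogonal: energy is
#' conserved exactly and [wpt_reconstruct()] inverts it to round-off.
#'
#' Signals are zero-padded to the next multiple of `2^level` (the padding is
#' removed on reconstruction). Periodization wraps the signal circularly;
#' with the 90-tap db45 filter a warning is issued for inputs shorter than
#' 10 s at 200 Hz, where wrap-around effects become material.
#'
#' @param x Numeric signal (or a `vital_sign_signal`, whose phase is used).
#' @param level Decomposition depth (default 6: 64 uniform sub-bands).
#' @param wavelet `"db45"` (default) or `"haar"`.
#' @param fs_hz Sampling rate carried along for band bookkeeping.
#' @return Object of class `wpt_decomposition`: `coefficients` (list of
#'   `2^level` leaf coefficient vectors, frequency-ordered), `level`,
#'   `wavelet`, `fs_hz`, `n` (original length), `n_pad`.
#' @export
wpt_decompose <- function(x, level = 6, wavelet = "db45", fs_hz = 200) {
  if (inherits(x, "vital_sign_signal")) {
    fs_hz <- x$fs_hz
    x <- x$phase_rad
  }
  x <- as.numeric(x)
  filt <- .wpt_filters(wavelet)
  if (level < 1 || level != round(level)) stop("level must be a positive integer")
  n <- length(x)
  block <- 2^level
  if (n < block) stop("signal shorter than 2^level samples")
  if (wavelet == "db45" && n < 10 * fs_hz) {
    warning("input shorter than 10 s; db45 wavelet-packet bands lose ",
            "selectivity on very short windows")
  }
  n_pad <- ceiling(n / block) * block
  if (n_pad > n) x <- c(x, numeric(n_pad - n))
  # nodes carried as list of (coeffs, freq_index); children of a node with
  # frequency index f: lowpass -> 2f, highpass -> 2f+1 when f is even, and
  # swapped when f is odd (the sequency-ordering rule for QMF cascades).
  nodes <- list(list(coef = x, f = 0L))
  for (l in seq_len(level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      nd <- nodes[[j]]
      ad <- .wpt_analysis_step_cpp(nd$coef, filt$h, filt$g)
      if (nd$f %% 2L == 0L) {
        nxt[[2 * j - 1]] <- list(coef = ad$a, f = 2L * nd$f)
        nxt[[2 * j]] <- list(coef = ad$d, f = 2L * nd$f + 1L)
      } else {
        nxt[[2 * j - 1]] <- list(coef = ad$a, f = 2L * nd$f + 1L)
        nxt[[2 * j]] <- list(coef = ad$d, f = 2L * nd$f)
      }
    }
    nodes <- nxt
  }
  freq_of_natural <- vapply(nodes, function(nd) nd$f, 0L)
  coefs <- vector("list", length(nodes))
  for (j in seq_along(nodes)) coefs[[freq_of_natural[j] + 1L]] <- nodes[[j]]$coef
  structure(list(coefficients = coefs, level = level, wavelet = wavelet,
                 fs_hz = fs_hz, n = n, n_pad = n_pad,
                 freq_of_natural = freq_of_natural),
            class = "wpt_decomposition")
}

#' Inverse wavelet packet transform over selected leaves
#'
#' Reconstructs the time-domain signal from a subset of leaves (all others
#' zeroed). With all leaves kept this inverts [wpt_decompose()] exactly.
#'
#' @param decomp A `wpt_decomposition`.
#' @param bands Integer leaf indices (1-based, frequency-ordered) to keep;
#'   `NULL` keeps all.
#' @return Numeric signal of the original length.
#' @export
wpt_reconstruct <- function(decomp, bands = NULL) {
  stopifnot(inherits(decomp, "wpt_decomposition"))
  n_leaves <- 2^decomp$level
  if (is.null(bands)) bands <- seq_len(n_leaves)
  bands <- as.integer(bands)
  if (any(bands < 1L | bands > n_leaves)) {
    stop(sprintf("band indices must lie in 1..%d", n_leaves))
  }
  filt <- .wpt_filters(decomp$wavelet)
  keep <- logical(n_leaves)
  keep[bands] <- TRUE
  # rebuild in natural (tree) order, zeroing dropped leaves
  nodes <- vector("list", n_leaves)
  for (j in seq_len(n_leaves)) {
    f <- decomp$freq_of_natural[j]
    cf <- decomp$coefficients[[f + 1L]]
    nodes[[j]] <- if (keep[f + 1L]) cf else numeric(length(cf))
  }
  for (l in seq_len(decomp$level)) {
    nxt <- vector("list", length(nodes) / 2L)
    for (j in seq_along(nxt)) {
      nxt[[j]] <- .wpt_synthesis_step_cpp(nodes[[2 * j - 1]], nodes[[2 * j]],
                                          filt$h, filt$g)
    }
    nodes <- nxt
  }
  nodes[[1]][seq_len(decomp$n)]
}

#' Leaf energy fractions
#'
#' Fraction of total coefficient energy in each frequency-ordered leaf; the
#' wavelet-packet energy histogram used to justify the SCG band choice.
#'
#' @param decomp A `wpt_decomposition`.
#' @return Numeric vector of `2^level` non-negative fractions summing to 1.
#' @export
band_energy_fractions <- function(decomp) {
  stopifnot(inherits(decomp, "wpt_decomposition"))
  e <- vapply(decomp$coefficients, function(cf) sum(cf^2), 0)
  tot <- sum(e)
  if (tot <= 0) stop("zero signal: energy fractions are undefined")
  e / tot
}

#' Reconstruct the SCG from its wavelet-packet band
#'
#' Keeps the level-6 leaves spanning the seismocardiogram band -- by default
#' leaves 6 through 12, i.e. 7.8125 to 18.750 Hz at 200 Hz sampling -- and
#' inverts the transform.
#'
#' @param decomp A `wpt_decomposition` (level 6 for the standard band map).
#' @param bands Leaf indices to keep (default `6:12`).
#' @return Object of class `scg_signal`: `samples`, `fs_hz`, `band_indices`,
#'   and the band edges in Hz.
#' @export
reconstruct_scg <- function(decomp, bands = 6:12) {
  samples <- wpt_reconstruct(decomp, bands = bands)
  lo <- band_frequency_range(min(bands), decomp$fs_hz, decomp$level)[1]
  hi <- band_frequency_range(max(bands), decomp$fs_hz, decomp$level)[2]
  structure(list(samples = samples, fs_hz = decomp$fs_hz,
                 band_indices = bands,
                 band_lo_hz = unname(lo), band_hi_hz = unname(hi)),
            class = "scg_signal")
}

#' @export
print.scg_signal <- function(x, ...) {
  cat(sprintf("SCG signal: %d samples at %.0f Hz, band %.4f-%.3f Hz (leaves %s)\n",
              length(x$samples), x$fs_hz, x$band_lo_hz, x$band_hi_hz,
              paste(range(x$band_indices), collapse = "-")))
  invisible(x)
}

#' Band-pass filter baseline
#'
#' Zero-phase Butterworth band-pass (order 4, forward-backward via
#' `signal::filtfilt`), the conventional alternative to the wavelet-packet
#' extraction. Defaults to the 0.7-3 Hz heartbeat band; use 0.1-0.5 Hz for
#' respiration.
#'
#' @param x Numeric signal.
#' @param lo_hz,hi_hz Pass-band edges in Hz.
#' @param fs_hz Sampling rate (Hz).
#' @param order Butterworth order (per pass).
#' @return Filtered signal of the same length.
#' @export
bpf_baseline <- function(x, lo_hz = 0.7, hi_hz = 3, fs_hz = 200, order = 4) {
  stopifnot(lo_hz > 0, hi_hz > lo_hz, hi_hz < fs_hz / 2)
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}
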