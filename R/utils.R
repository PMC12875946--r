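# Internal helpers shared across modules.

.assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must lie in [%g, %g], got %g", name, lo, hi, x),
         call. = FALSE)
  }
  invisible(x)
}

# Analytic signal via the frequency-domain Hilbert construction: double the
# positive frequencies, zero the negative ones, keep DC (and Nyquist for even
# length) untouched.
.analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Local maxima with a minimum-spacing constraint, in the spirit of MATLAB
# findpeaks(..., 'MinPeakDistance'): candidate peaks are strict local maxima;
# they are accepted in order of decreasing height, and any candidate closer
# than `min_spacing` samples to an already accepted peak is dropped.
.find_peaks <- function(x, min_spacing = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  core <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(core) == 0L) return(integer(0))
  ord <- core[order(x[core], decreasing = TRUE)]
  accepted <- integer(0)
  for (idx in ord) {
    if (!length(accepted) || all(abs(accepted - idx) >= min_spacing)) {
      accepted <- c(accepted, idx)
    }
  }
  sort(accepted)
}

# Stable content hash used by the run manifest: md5 of the serialized object,
# serialization version pinned so hashes are comparable across sessions.
.object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
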