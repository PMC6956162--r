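#' Analytic signal via the frequency-domain Hilbert construction
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length; `Mod()` is the envelope and
#'   `Arg()` the instantaneous phase in (-pi, pi].
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# zero-phase Butterworth bandpass (forward-backward 3rd order)
bandpass_zp <- function(x, lo, hi, fs, order = 3) {
  ny <- fs / 2
  if (hi >= ny) stop("band upper edge ", hi, " Hz at or above Nyquist (", ny, " Hz)")
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  # demean first: forward-backward IIR filtering of a large DC offset
  # leaves slow edge transients in the lowest bands
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

lowpass_zp <- function(x, hi, fs, order = 4) {
  bf <- signal::butter(order, hi / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Downsample a recording
#'
#' Zero-phase anti-alias low-pass filtering followed by cubic-spline
#' resampling onto the target grid. Sample count of the result is
#' `round(duration_s * target_fs)`.
#'
#' @param rec a `recording`.
#' @param target_fs target sampling rate in Hz; must not exceed `rec$fs`.
#' @return A downsampled `recording`.
#' @export
downsample <- function(rec, target_fs) {
  validate_recording(rec)
  if (target_fs > rec$fs) stop("downsample(): upsampling requested (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  n_new <- round(rec$duration_s * target_fs)
  t_old <- (seq_len(ncol(rec$data)) - 1) / rec$fs
  t_new <- (seq_len(n_new) - 1) / target_fs
  cutoff <- 0.9 * target_fs / 2
  out <- t(apply(rec$data, 1, function(x) {
    xf <- lowpass_zp(x, cutoff, rec$fs)
    stats::spline(t_old, xf, xout = t_new)$y
  }))
  new_recording(out, fs = target_fs, channel_names = rec$channel_names,
                system = rec$system)
}

#' Filterbank decomposition with Hilbert envelope and phase
#'
#' Applies the eight-band zero-phase Butterworth filterbank (3rd order,
#' forward-backward) to every channel and computes the Hilbert amplitude
#' envelope and instantaneous phase per band.
#'
#' @param rec a `recording`; `fs/2` must exceed the top band edge (45 Hz).
#' @param bands band definition table, defaults to [band_table()].
#' @return An object of class `banded_signals`: lists `filtered`, `env`,
#'   `phase`, each of length `nrow(bands)` holding samples x channels
#'   matrices, plus `fs`, `bands`, `channel_names`.
#' @export
filterbank <- function(rec, bands = band_table()) {
  validate_recording(rec)
  if (rec$fs / 2 <= max(bands$hi))
    stop("sampling rate too low for the top band (needs fs > ",
         2 * max(bands$hi), " Hz)")
  C <- nrow(rec$data)
  filtered <- env <- phase <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    fb <- matrix(0, ncol(rec$data), C)
    eb <- pb <- fb
    for (ch in seq_len(C)) {
      y <- bandpass_zp(rec$data[ch, ], bands$lo[b], bands$hi[b], rec$fs)
      a <- analytic_signal(y)
      fb[, ch] <- y
      eb[, ch] <- Mod(a)
      pb[, ch] <- Arg(a)
    }
    filtered[[b]] <- fb; env[[b]] <- eb; phase[[b]] <- pb
  }
  names(filtered) <- names(env) <- names(phase) <- bands$band
  structure(list(filtered = filtered, env = env, phase = phase,
                 fs = rec$fs, bands = bands,
                 channel_names = rec$channel_names),
            class = "banded_signals")
}

#' @export
print.banded_signals <- function(x, ...) {
  cat(sprintf("<banded_signals> %d bands x %d channels x %d samples @ %g Hz\n",
              nrow(x$bands), length(x$channel_names),
              nrow(x$filtered[[1]]), x$fs))
  invisible(x)
}

#' Sliding-window scheme
#'
#' Two-second windows (two delta cycles) advanced by `step_s`. The number of
#' segments is `T = floor(samples / step_samples)`; windows overrunning the
#' end are truncated at the last sample. The default 0.2-s step yields
#' exactly 900 segments for a 180-s recording at either 170 or 150 Hz.
#'
#' @param n_samples number of samples (or a `recording`, in which case `fs`
#'   is taken from it).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 2).
#' @param step_s step in seconds (default 0.2).
#' @return Object of class `window_scheme` with `starts`, `ends` (1-based,
#'   inclusive), `n_windows`, `window_samples`, `step_samples`.
#' @export
#' @examples
#' make_windows(30600, 170)$n_windows  # 900
make_windows <- function(n_samples, fs, window_s = 2, step_s = 0.2) {
  if (inherits(n_samples, "recording")) {
    fs <- n_samples$fs
    n_samples <- ncol(n_samples$data)
  }
  win <- round(window_s * fs)
  step <- round(step_s * fs)
  if (n_samples < win)
    stop("recording shorter than one window (", window_s, " s)")
  n_win <- floor(n_samples / step)
  starts <- (seq_len(n_win) - 1L) * step + 1L
  ends <- pmin(starts + win - 1L, n_samples)
  structure(list(starts = starts, ends = ends, n_windows = n_win,
                 window_samples = win, step_samples = step,
                 window_s = window_s, step_s = step_s, fs = fs,
                 n_samples = n_samples),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> T = %d windows of %d samples, step %d (%g s @ %g Hz)\n",
              x$n_windows, x$window_samples, x$step_samples, x$step_s, x$fs))
  invisible(x)
}
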