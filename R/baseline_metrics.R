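# Static comparison measures: relative power, imaginary coherence and
# multiscale (sample) entropy.

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Welch auto/cross spectra: list(freq, S) where S[[i]][[j]] is the averaged
# cross-spectrum of channels i and j over 50%-overlapping tapered segments.
welch_spectra <- function(x, fs, seg_s = 2, overlap = 0.5) {
  x <- as.matrix(x)                      # samples x channels
  nseg <- round(seg_s * fs)
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, nrow(x) - nseg + 1, by = step)
  if (!length(starts)) stop("signal shorter than one Welch segment")
  w <- hann(nseg)
  nfft <- nseg
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  C <- ncol(x)
  acc <- vector("list", C * C)
  dim(acc) <- c(C, C)
  X <- array(0i, c(length(freq), length(starts), C))
  for (ch in seq_len(C)) for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + nseg - 1), ch]
    seg <- (seg - mean(seg)) * w
    X[, s, ch] <- stats::fft(seg)[seq_along(freq)]
  }
  S <- array(0i, c(length(freq), C, C))
  for (i in seq_len(C)) for (j in i:C) {
    cs <- rowMeans(X[, , i, drop = FALSE][, , 1] *
                   Conj(X[, , j, drop = FALSE][, , 1]))
    S[, i, j] <- cs
    S[, j, i] <- Conj(cs)
  }
  list(freq = freq, S = S)
}

#' Welch power spectral density
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 2, 50% overlap,
#'   Hann-tapered).
#' @return List with `freq` and `psd`.
#' @export
welch_psd <- function(x, fs, seg_s = 2) {
  sp <- welch_spectra(matrix(x, ncol = 1), fs, seg_s)
  list(freq = sp$freq, psd = Re(sp$S[, 1, 1]))
}

#' Relative band power
#'
#' Welch spectral estimate (2-s segments, 50% overlap); per channel, the
#' power in each of the eight bands divided by the total power in
#' 0.5-45 Hz.
#'
#' @param rec a `recording` of at least 4 s.
#' @param bands band table (default [band_table()]).
#' @return Matrix bands x channels of relative powers.
#' @export
relative_power <- function(rec, bands = band_table()) {
  validate_recording(rec)
  if (rec$duration_s < 4) stop("relative_power needs at least 4 s of data")
  sp <- welch_spectra(t(rec$data), rec$fs)
  total_sel <- sp$freq >= min(bands$lo) & sp$freq < max(bands$hi)
  out <- matrix(0, nrow(bands), nrow(rec$data),
                dimnames = list(bands$band, rec$channel_names))
  for (ch in seq_len(nrow(rec$data))) {
    psd <- Re(sp$S[, ch, ch])
    tot <- sum(psd[total_sel])
    for (b in seq_len(nrow(bands)))
      out[b, ch] <- sum(psd[sp$freq >= bands$lo[b] &
                            sp$freq < bands$hi[b]]) / tot
  }
  out
}

#' Imaginary part of coherence
#'
#' `|Im(S_xy / sqrt(S_xx S_yy))|` averaged over the frequency bins of a
#' band; insensitive to zero-lag coupling.
#'
#' @param rec a `recording` (>= 4 s).
#' @param pair integer `c(i, j)` channel pair.
#' @param band `c(lo, hi)` Hz or a band name; default the full 0.5-45 Hz.
#' @return Scalar in `[0, 1]`.
#' @export
imaginary_coherence <- function(rec, pair, band = NULL) {
  validate_recording(rec)
  sp <- welch_spectra(t(rec$data[pair, , drop = FALSE]), rec$fs)
  if (is.character(band)) {
    bt <- band_table()
    i <- match(band, bt$band)
    band <- c(bt$lo[i], bt$hi[i])
  }
  if (is.null(band)) band <- c(0.5, 45)
  sel <- sp$freq >= band[1] & sp$freq < band[2]
  coh <- sp$S[sel, 1, 2] /
    sqrt(Re(sp$S[sel, 1, 1]) * Re(sp$S[sel, 2, 2]))
  mean(abs(Im(coh)))
}

#' Multiscale entropy
#'
#' Coarse-grains the signal by non-overlapping means at each scale and
#' computes sample entropy (embedding `m`, tolerance `r` times the SD of
#' the original signal) on each coarse-grained series.
#'
#' @param x numeric vector of length >= 100 x max(scales).
#' @param m embedding dimension (default 2).
#' @param r tolerance as a fraction of the original signal's SD
#'   (default 0.2).
#' @param scales integer scales (default 1:10).
#' @return Named numeric vector of sample entropies per scale.
#' @export
multiscale_entropy <- function(x, m = 2, r = 0.2, scales = 1:10) {
  if (length(x) < 100 * max(scales))
    stop("signal too short: need at least 100 samples per coarse-grained point")
  s0 <- stats::sd(x)
  out <- stats::setNames(numeric(length(scales)), paste0("scale", scales))
  if (s0 == 0) return(out)  # constant signal: zero entropy at all scales
  tol <- r * s0
  for (i in seq_along(scales)) {
    sc <- scales[i]
    n <- floor(length(x) / sc)
    cg <- colMeans(matrix(x[seq_len(n * sc)], sc, n))
    se <- pracma::sample_entropy(cg, edim = m, r = tol, tau = 1)
    out[i] <- if (is.finite(se)) se else 0
  }
  out
}

#' Lobe-averaged baseline feature vector
#'
#' Static comparison features in the same shape the classifier consumes:
#' per lobe-hemisphere group, the group-averaged relative power per band
#' and the group-averaged multiscale entropy per scale.
#'
#' @param rec a `recording`.
#' @param layout a `lobar_layout` covering the recording's channels.
#' @param scales entropy scales (default 1:5).
#' @return Named numeric feature vector.
#' @export
baseline_feature_vector <- function(rec, layout, scales = 1:5) {
  rp <- relative_power(rec)
  groups <- sort(unique(layout$map$group[layout$map$channel %in%
                                           rec$channel_names]))
  grp_of <- stats::setNames(layout$map$group, layout$map$channel)
  out <- numeric(0)
  for (g in groups) {
    ch <- which(grp_of[rec$channel_names] == g)
    out <- c(out, stats::setNames(rowMeans(rp[, ch, drop = FALSE]),
                                  paste0("RP_", g, "_", rownames(rp))))
  }
  for (g in groups) {
    ch <- which(grp_of[rec$channel_names] == g)
    mse <- rowMeans(sapply(ch, function(c1)
      multiscale_entropy(rec$data[c1, ], scales = scales)))
    out <- c(out, stats::setNames(mse, paste0("MSE_", g, "_scale", scales)))
  }
  out
}
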