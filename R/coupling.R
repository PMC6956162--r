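#' Amplitude envelope correlation
#'
#' Product-moment correlation of two Hilbert amplitude envelopes. The
#' coupling strength used downstream is `abs(aec(...))`.
#'
#' @param env_a,env_b numeric envelope vectors of equal length (>= 8).
#' @return Correlation in `[-1, 1]`; `NA` (flagged missing) if either
#'   envelope has zero variance.
#' @export
#' @examples
#' aec(1:10, 21 - (1:10))  # -1
aec <- function(env_a, env_b) {
  if (length(env_a) != length(env_b) || length(env_a) < 8)
    stop("envelopes must have equal length >= 8")
  if (stats::sd(env_a) == 0 || stats::sd(env_b) == 0) return(NA_real_)
  stats::cor(env_a, env_b)
}

#' Imaginary phase-locking value
#'
#' `|Im(mean(exp(i (phase_a - phase_b))))|`: the magnitude of the imaginary
#' part of the mean phase-difference phasor. Insensitive to zero-lag
#' coupling (a constant zero phase difference gives 0; a constant `pi/2`
#' lag gives 1).
#'
#' @param phase_a,phase_b instantaneous-phase vectors (radians), equal
#'   length >= 8.
#' @return Strength in `[0, 1]`.
#' @export
iplv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b) || length(phase_a) < 8)
    stop("phase series must have equal length >= 8")
  abs(Im(mean(exp(1i * (phase_a - phase_b)))))
}

#' Directed phase lag index
#'
#' Mean of the Heaviside step of the wrapped phase difference
#' `phase_a - phase_b` (`H(0) = 0.5`): the probability that signal a's
#' phase leads signal b's. 0.5 means no consistent lead; the associated
#' strength is `2 * |dpli - 0.5|`.
#'
#' @param phase_a,phase_b instantaneous-phase vectors, equal length >= 8.
#' @return Value in `[0, 1]`.
#' @seealso [dpli_strength()]
#' @export
dpli <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b) || length(phase_a) < 8)
    stop("phase series must have equal length >= 8")
  d <- Arg(exp(1i * (phase_a - phase_b)))  # wrapped to (-pi, pi]
  mean(d > 0) + 0.5 * mean(d == 0)
}

#' @rdname dpli
#' @param value a dPLI value.
#' @export
dpli_strength <- function(value) 2 * abs(value - 0.5)

#' Phase of a band-filtered amplitude envelope
#'
#' Re-filters a high-band Hilbert envelope within a low band and extracts
#' its instantaneous phase; the building block of the phase-amplitude
#' coupling estimator.
#'
#' @param env high-band amplitude envelope.
#' @param band `c(lo, hi)` in Hz or a band name (the low band).
#' @param fs sampling rate in Hz.
#' @return Phase vector in (-pi, pi].
#' @export
env_phase <- function(env, band, fs) {
  if (is.character(band)) {
    bt <- band_table()
    i <- match(band, bt$band)
    if (is.na(i)) stop("unknown band name: ", band)
    band <- c(bt$lo[i], bt$hi[i])
  }
  Arg(analytic_signal(bandpass_zp(env - mean(env), band[1], band[2], fs)))
}

#' Phase-amplitude coupling strength
#'
#' Phase-locking between a low-band phase and the low-band-filtered phase
#' of a high-band amplitude envelope (cross-frequency iPLV).
#'
#' @param phase_low low-band instantaneous phase of the modulating signal.
#' @param env_high high-band amplitude envelope of the modulated signal.
#' @param low_band the low band (`c(lo, hi)` Hz or name) used to re-filter
#'   the envelope.
#' @param fs sampling rate in Hz.
#' @return Strength in `[0, 1]`.
#' @export
pac <- function(phase_low, env_high, low_band, fs) {
  if (length(phase_low) != length(env_high))
    stop("phase and envelope must have equal length")
  iplv(phase_low, env_phase(env_high, low_band, fs))
}

#' Neural-gas vector quantisation
#'
#' Learns `k` prototypes minimising quantisation error by soft rank-based
#' updates: at each step, every prototype moves toward the presented vector
#' with step size `eps(t) * exp(-rank / lambda(t))`, where both the
#' neighbourhood range `lambda` and the learning rate `eps` decay
#' exponentially. The single-prototype case is the exact minimiser (the
#' mean).
#'
#' @param x numeric matrix, one state vector per row (must contain at least
#'   `k` distinct rows).
#' @param k codebook size.
#' @param seed integer seed (fixed seed gives identical codebooks).
#' @param n_iter number of presentation steps.
#' @return A `k` x `ncol(x)` prototype matrix.
#' @export
neural_gas_codebook <- function(x, k, seed = 1, n_iter = 20000L) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k)
    stop("fewer distinct state vectors (", nrow(unique(x)), ") than k = ", k)
  if (k == 1L) return(matrix(colMeans(x), 1))
  set.seed(seed)
  w <- x[sample(nrow(x), k), , drop = FALSE]
  lambda0 <- k / 2; lambdaF <- 0.01
  eps0 <- 0.5; epsF <- 0.005
  order_idx <- sample(nrow(x), n_iter, replace = TRUE)
  for (t in seq_len(n_iter)) {
    v <- x[order_idx[t], ]
    frac <- (t - 1) / n_iter
    lambda <- lambda0 * (lambdaF / lambda0)^frac
    eps <- eps0 * (epsF / eps0)^frac
    d2 <- rowSums(sweep(w, 2, v)^2)
    rk <- rank(d2, ties.method = "first") - 1
    h <- eps * exp(-rk / lambda)
    w <- w + h * sweep(-w, 2, v, "+")
  }
  w
}

# nearest-prototype assignment (rows of x -> 1..k)
vq_assign <- function(x, codebook) {
  cross <- x %*% t(codebook)
  d2 <- outer(rowSums(x^2), rowSums(codebook^2), "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}

# delay-embed a vector: rows (x_t, x_{t+lag}, ..., x_{t+(dim-1)lag})
delay_embed <- function(x, dim = 3L, lag = 1L) {
  n <- length(x) - (dim - 1L) * lag
  sapply(seq_len(dim), function(j) x[(1:n) + (j - 1L) * lag])
}

#' Symbolise band-limited signals with a shared neural-gas codebook
#'
#' Each channel x band signal is z-scored, delay-embedded (dimension
#' `dim`, lag 1 sample), and every embedded state vector is assigned to its
#' nearest prototype of a single codebook trained on a subsample of all
#' state vectors of the recording (one common alphabet across all sensor
#' pairs and bands).
#'
#' @param banded a `banded_signals` object.
#' @param k codebook size (default 8).
#' @param dim embedding dimension (default 3).
#' @param seed integer seed.
#' @param train_max maximum number of state vectors used to train the
#'   codebook.
#' @return List with `sym` (list per band of (samples - dim + 1) x channels
#'   integer matrices), `codebook`, `k`.
#' @export
symbolize <- function(banded, k = 8L, dim = 3L, seed = 1, train_max = 4000L) {
  stopifnot(inherits(banded, "banded_signals"))
  C <- length(banded$channel_names)
  nb <- length(banded$filtered)
  emb <- vector("list", nb * C)
  for (b in seq_len(nb)) for (ch in seq_len(C)) {
    z <- as.numeric(scale(banded$filtered[[b]][, ch]))
    if (any(is.na(z))) z <- rep(0, length(z))  # constant channel
    emb[[(b - 1) * C + ch]] <- delay_embed(z, dim)
  }
  pool <- do.call(rbind, emb)
  set.seed(seed)
  if (nrow(pool) > train_max)
    pool <- pool[sample(nrow(pool), train_max), , drop = FALSE]
  cb <- neural_gas_codebook(pool, k, seed = seed)
  sym <- vector("list", nb)
  for (b in seq_len(nb)) {
    m <- matrix(0L, nrow(emb[[(b - 1) * C + 1]]), C)
    for (ch in seq_len(C)) m[, ch] <- vq_assign(emb[[(b - 1) * C + ch]], cb)
    sym[[b]] <- m
  }
  names(sym) <- names(banded$filtered)
  list(sym = sym, codebook = cb, k = k)
}

# symbolic transfer entropy a -> b at one delay, normalised by log(k)
te_symbolic <- function(sym_a, sym_b, k, delay) {
  n <- length(sym_b) - delay
  if (n < 4) return(0)
  y <- sym_b[(1 + delay):(n + delay)]
  y0 <- sym_b[1:n]
  x0 <- sym_a[1:n]
  iyy0 <- y + k * (y0 - 1L)                  # joint (y, y0) index, 1..k^2
  c3 <- tabulate(iyy0 + k * k * (x0 - 1L), k^3)
  c_yy0 <- tabulate(iyy0, k * k)
  c_y0x0 <- tabulate(y0 + k * (x0 - 1L), k * k)
  c_y0 <- tabulate(y0, k)
  nz <- which(c3 > 0L)
  if (!length(nz)) return(0)
  iyy0_nz <- (nz - 1L) %% (k * k) + 1L
  iy0 <- ((nz - 1L) %/% k) %% k + 1L
  ix0 <- (nz - 1L) %/% (k * k) + 1L
  te <- sum(c3[nz] / n *
              log(c3[nz] * c_y0[iy0] /
                    (c_y0x0[(ix0 - 1L) * k + iy0] * c_yy0[iyy0_nz])))
  max(te, 0) / log(k)
}

#' Delay symbolic transfer entropy
#'
#' Transfer entropy between two symbol series (shared alphabet `1..k`),
#' scanned over a grid of delays in both directions. Strength is the
#' normalised net information flow `|TE_ab - TE_ba| / max(TE_ab, TE_ba)`
#' with each directional TE maximised over the delay grid.
#'
#' @param sym_a,sym_b integer symbol series from a common codebook.
#' @param k alphabet size.
#' @param delays integer delay grid in samples (default `1:10`).
#' @return List with `strength` in `[0, 1]`, `direction` (+1 for a->b, -1
#'   for b->a, 0 degenerate), `delay` (best delay of the dominant
#'   direction), `te_ab`, `te_ba`, and `degenerate` (constant input flag).
#' @export
dste <- function(sym_a, sym_b, k, delays = 1:10) {
  if (length(sym_a) != length(sym_b))
    stop("symbol series must have equal length")
  if (length(unique(sym_a)) == 1L || length(unique(sym_b)) == 1L)
    return(list(strength = 0, direction = 0L, delay = NA_integer_,
                te_ab = 0, te_ba = 0, degenerate = TRUE))
  te_ab <- vapply(delays, function(d) te_symbolic(sym_a, sym_b, k, d), 0)
  te_ba <- vapply(delays, function(d) te_symbolic(sym_b, sym_a, k, d), 0)
  best_ab <- which.max(te_ab); best_ba <- which.max(te_ba)
  mx <- max(te_ab[best_ab], te_ba[best_ba])
  strength <- if (mx > 0) abs(te_ab[best_ab] - te_ba[best_ba]) / mx else 0
  dir <- if (te_ab[best_ab] >= te_ba[best_ba]) 1L else -1L
  list(strength = strength, direction = dir,
       delay = delays[if (dir == 1L) best_ab else best_ba],
       te_ab = te_ab[best_ab], te_ba = te_ba[best_ba], degenerate = FALSE)
}
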