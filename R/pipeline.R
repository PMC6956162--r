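# Internal engine shared by estimate_all() and run_dicm().
#
# All five estimators are evaluated on whole-recording analytic series
# (envelope, phase phasor, envelope-phase phasor per cross-band code,
# neural-gas symbols), so a circular time-shift surrogate is just a shifted
# index into the same series. Per window, strengths for the observed data
# and all surrogates are computed in one vectorised pass per candidate;
# phasor products are expanded into real arithmetic (BLAS crossprod) and
# shifted series matrices are cached across the candidates of a window.

precompute_coupling <- function(banded, estimators, dste_k = 8L,
                                dste_dim = 3L, seed = 1) {
  C <- length(banded$channel_names)
  N <- nrow(banded$filtered[[1]])
  fc <- freq_codes()
  env <- banded$env
  ZR <- lapply(banded$phase, cos)
  ZI <- lapply(banded$phase, sin)
  ZepR <- ZepI <- NULL
  if (any(c("pac", "dpli") %in% estimators)) {
    cross <- fc[fc$type == "cross", ]
    ZepR <- ZepI <- vector("list", 36)
    bt <- banded$bands
    for (r in seq_len(nrow(cross))) {
      l <- cross$band_low[r]; h <- cross$band_high[r]
      mR <- mI <- matrix(0, N, C)
      for (ch in seq_len(C)) {
        ph <- env_phase(env[[h]][, ch], c(bt$lo[l], bt$hi[l]), banded$fs)
        mR[, ch] <- cos(ph); mI[, ch] <- sin(ph)
      }
      ZepR[[cross$code[r]]] <- mR
      ZepI[[cross$code[r]]] <- mI
    }
  }
  symb <- NULL
  if ("dste" %in% estimators)
    symb <- symbolize(banded, k = dste_k, dim = dste_dim, seed = seed)
  list(env = env, ZR = ZR, ZI = ZI, ZepR = ZepR, ZepI = ZepI, symb = symb,
       fc = fc, N = N, Ns = N - dste_dim + 1L, C = C, fs = banded$fs)
}

candidate_table <- function(estimators) {
  et <- estimator_table()
  do.call(rbind, lapply(estimators, function(nm) {
    data.frame(est = nm, est_id = et$id[et$name == nm],
               code = admissible_codes(nm), stringsAsFactors = FALSE)
  }))
}

# correlation of x with each column of Y (NA on zero variance)
col_cor <- function(x, Y) {
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  sx <- sqrt(sum(xc^2)); sy <- sqrt(colSums(Yc^2))
  r <- as.numeric(crossprod(xc, Yc)) / (sx * sy)
  r[!is.finite(r)] <- NA_real_
  r
}

# |Im(mean(exp(i(phi_fixed - phi_shift))))| from phasor components
iplv_cols <- function(fR, fI, MR, MI) {
  abs(as.numeric(crossprod(fI, MR) - crossprod(fR, MI))) / length(fR)
}

# 2 * |dPLI - 0.5| from phasor components; the phase difference is
# positive iff Im > 0 or (Im == 0 and Re < 0), zero iff Im == 0 and Re > 0.
dpli_cols <- function(fR, fI, MR, MI) {
  ImD <- fI * MR - fR * MI
  ReD <- fR * MR + fI * MI
  v <- colMeans(ImD > 0 | (ImD == 0 & ReD < 0)) +
    0.5 * colMeans(ImD == 0 & ReD > 0)
  2 * abs(v - 0.5)
}

# strengths of every candidate for pair (a, b) in one window.
# IDX:  window-sample index matrix [len x (1 + n_surr)], col 1 = observed;
# IDXs: same for the (shorter) symbol series.
# Returns a matrix [n_candidates x (1 + n_surr)].
window_strengths <- function(pc, cand, a, b, IDX, IDXs, dste_delays) {
  nS <- ncol(IDX)
  len <- nrow(IDX)
  out <- matrix(NA_real_, nrow(cand), nS)
  idx <- IDX[, 1]
  cache <- new.env(parent = emptyenv())
  shifted <- function(kind, key, ch) {
    id <- paste0(kind, key, "_", ch)
    m <- cache[[id]]
    if (is.null(m)) {
      v <- switch(kind,
                  env = pc$env[[key]][, ch],
                  zr = pc$ZR[[key]][, ch],
                  zi = pc$ZI[[key]][, ch],
                  epr = pc$ZepR[[key]][, ch],
                  epi = pc$ZepI[[key]][, ch])
      m <- matrix(v[IDX], len, nS)
      cache[[id]] <- m
    }
    m
  }
  for (r in seq_len(nrow(cand))) {
    code <- cand$code[r]
    l <- pc$fc$band_low[code]; h <- pc$fc$band_high[code]
    est <- cand$est[r]
    if (est == "aec") {
      if (l == h) {
        out[r, ] <- abs(col_cor(pc$env[[l]][idx, a], shifted("env", l, b)))
      } else {
        r1 <- col_cor(pc$env[[l]][idx, a], shifted("env", h, b))
        r2 <- col_cor(pc$env[[h]][idx, a], shifted("env", l, b))
        out[r, ] <- pmax(abs(r1), abs(r2), na.rm = TRUE)
        out[r, is.na(r1) & is.na(r2)] <- NA_real_
      }
    } else if (est == "iplv") {
      out[r, ] <- iplv_cols(pc$ZR[[l]][idx, a], pc$ZI[[l]][idx, a],
                            shifted("zr", l, b), shifted("zi", l, b))
    } else if (est == "pac") {
      s1 <- iplv_cols(pc$ZR[[l]][idx, a], pc$ZI[[l]][idx, a],
                      shifted("epr", code, b), shifted("epi", code, b))
      s2 <- iplv_cols(pc$ZepR[[code]][idx, a], pc$ZepI[[code]][idx, a],
                      shifted("zr", l, b), shifted("zi", l, b))
      out[r, ] <- pmax(s1, s2)
    } else if (est == "dpli") {
      if (l == h) {
        out[r, ] <- dpli_cols(pc$ZR[[l]][idx, a], pc$ZI[[l]][idx, a],
                              shifted("zr", l, b), shifted("zi", l, b))
      } else {
        s1 <- dpli_cols(pc$ZR[[l]][idx, a], pc$ZI[[l]][idx, a],
                        shifted("epr", code, b), shifted("epi", code, b))
        s2 <- dpli_cols(pc$ZepR[[code]][idx, a], pc$ZepI[[code]][idx, a],
                        shifted("zr", l, b), shifted("zi", l, b))
        out[r, ] <- pmax(s1, s2)
      }
    } else if (est == "dste") {
      out[r, ] <- dste_window(pc, a, b, l, h, IDXs, dste_delays)
    }
  }
  out
}

# dSTE candidate: net strength maximised over the delay grid (and, for
# cross codes, over both orientations) for the observed window and every
# surrogate alike, so the statistics are exchangeable under the null.
dste_window <- function(pc, a, b, l, h, IDXs, delays) {
  k <- pc$symb$k
  idx <- IDXs[, 1]
  nS <- ncol(IDXs)
  degen <- function(v) length(unique(v)) == 1L
  net <- if (l == h) {
    sa <- pc$symb$sym[[l]][idx, a]
    if (degen(sa) || degen(pc$symb$sym[[l]][idx, b]))
      return(rep(NA_real_, nS))
    SB <- matrix(pc$symb$sym[[l]][, b][IDXs], length(idx))
    dste_net_batch(sa, SB, k, as.integer(delays))
  } else {
    sa_l <- pc$symb$sym[[l]][idx, a]
    sa_h <- pc$symb$sym[[h]][idx, a]
    if ((degen(sa_l) && degen(sa_h)) ||
        (degen(pc$symb$sym[[h]][idx, b]) && degen(pc$symb$sym[[l]][idx, b])))
      return(rep(NA_real_, nS))
    SBh <- matrix(pc$symb$sym[[h]][, b][IDXs], length(idx))
    SBl <- matrix(pc$symb$sym[[l]][, b][IDXs], length(idx))
    pmax(dste_net_batch(sa_l, SBh, k, as.integer(delays)),
         dste_net_batch(sa_h, SBl, k, as.integer(delays)))
  }
  net
}

all_pairs <- function(C) {
  p <- utils::combn(C, 2)
  data.frame(a = p[1, ], b = p[2, ])
}

#' Raw per-window coupling strengths for all candidates
#'
#' Evaluates every admissible (estimator, frequency code) candidate for
#' every channel pair and sliding window, without surrogate testing: AEC,
#' dPLI and dSTE over all 36 codes, same-frequency iPLV over the 8
#' within-band codes, PAC over the 28 cross-band codes.
#'
#' @param banded a `banded_signals` object (see [filterbank()]).
#' @param scheme a `window_scheme`; defaults to the 2-s / 0.2-s scheme.
#' @param pairs data frame with columns `a`, `b` (channel indices); default
#'   all pairs.
#' @param estimators subset of `c("aec", "iplv", "pac", "dste", "dpli")`.
#' @param dste_k,dste_dim,dste_delays dSTE symbolisation and delay-scan
#'   parameters.
#' @param seed seed for the neural-gas codebook.
#' @return List with `strengths` (array candidates x windows x pairs),
#'   `candidates` (the candidate table), `pairs`, `scheme`.
#' @export
estimate_all <- function(banded, scheme = NULL, pairs = NULL,
                         estimators = c("aec", "iplv", "pac", "dste", "dpli"),
                         dste_k = 8L, dste_dim = 3L, dste_delays = 1:10,
                         seed = 1) {
  stopifnot(inherits(banded, "banded_signals"))
  if (is.null(scheme))
    scheme <- make_windows(nrow(banded$filtered[[1]]), banded$fs)
  if (is.null(pairs)) pairs <- all_pairs(length(banded$channel_names))
  pc <- precompute_coupling(banded, estimators, dste_k, dste_dim, seed)
  cand <- candidate_table(estimators)
  strengths <- array(NA_real_,
                     c(nrow(cand), scheme$n_windows, nrow(pairs)))
  for (t in seq_len(scheme$n_windows)) {
    idx <- scheme$starts[t]:scheme$ends[t]
    IDX <- matrix(idx, ncol = 1)
    IDXs <- matrix(pmin(idx, pc$Ns), ncol = 1)
    for (p in seq_len(nrow(pairs)))
      strengths[, t, p] <- window_strengths(pc, cand, pairs$a[p], pairs$b[p],
                                            IDX, IDXs, dste_delays)[, 1]
  }
  list(strengths = strengths, candidates = cand, pairs = pairs,
       scheme = scheme)
}
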