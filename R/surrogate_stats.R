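#' Circular-shift surrogate distribution for a coupling statistic
#'
#' Builds an empirical null by circularly shifting one member of the pair
#' by a random offset of at least `fs` samples and recomputing the
#' statistic. The shift preserves each signal's spectrum and envelope
#' statistics while destroying any cross-signal coupling.
#'
#' @param x,y the two (whole-series) signals of the pair; `y` is shifted.
#' @param stat_fn function `(x, y) -> scalar` computing the coupling
#'   statistic.
#' @param n_surr number of surrogates (>= 1).
#' @param fs sampling rate in Hz; the minimum shift.
#' @param seed integer seed.
#' @return Numeric vector of `n_surr` surrogate statistic values.
#' @export
make_surrogates <- function(x, y, stat_fn, n_surr, fs, seed = 1) {
  if (n_surr < 1) stop("n_surr must be >= 1")
  n <- length(y)
  min_shift <- round(fs)
  if (n <= 2 * min_shift)
    stop("series shorter than twice the minimum shift (", 2 * min_shift,
         " samples)")
  set.seed(seed)
  offs <- sample(min_shift:(n - min_shift), n_surr, replace = TRUE)
  vapply(offs, function(o) stat_fn(x, shift_vec(y, o)), 0)
}

#' Empirical surrogate p-value
#'
#' The proportion of surrogate statistic values at or above the observed
#' value (exact-test tie handling: a bounded statistic that saturates at
#' its maximum, as dPLI does, must not be declared significant merely for
#' tying the surrogates). Zero is attainable when the observed value
#' strictly exceeds every surrogate, and is handled correctly by the
#' Benjamini-Hochberg step-up.
#'
#' @param observed observed statistic.
#' @param surrogates numeric vector of surrogate values (non-empty).
#' @return p in `[0, 1]`.
#' @export
surrogate_pvalue <- function(observed, surrogates) {
  if (!length(surrogates)) stop("empty surrogate distribution")
  mean(surrogates >= observed)
}

#' Benjamini-Hochberg retention mask
#'
#' Step-up FDR control at level `q` across a set of candidate p-values
#' (applied per sensor pair and window, across the frequency candidates of
#' one estimator, in the pipeline).
#'
#' @param pvals numeric p-values (NAs allowed; never retained).
#' @param q FDR level (default 0.01).
#' @return Logical mask of retained candidates (empty input gives an empty
#'   mask).
#' @export
fdr_filter <- function(pvals, q = 0.01) {
  if (!length(pvals)) return(logical(0))
  adj <- stats::p.adjust(pvals, method = "BH")
  !is.na(adj) & adj <= q
}

#' Select the dominant coupling mode(s) among significant candidates
#'
#' Given the FDR-surviving candidates of one sensor pair and window (across
#' estimators), keeps the representative dominant intrinsic coupling mode:
#' with a single contributing estimator, its maximum-strength candidate;
#' with several, candidates are re-thresholded at `alpha_multi` (default
#' 0.01 / 4 = 0.0025) and up to two records with the smallest p-values
#' (ties broken by larger strength) are kept. If several estimators are
#' significant but none passes `alpha_multi`, the single maximum-strength
#' candidate is kept.
#'
#' @param candidates data frame with columns `est_id`, `code`, `strength`,
#'   `p` (FDR-significant candidates only; possibly zero rows).
#' @param alpha_multi multi-estimator threshold.
#' @return Data frame of 0, 1 or 2 records ordered by ascending p.
#' @export
select_dicm <- function(candidates, alpha_multi = 0.0025) {
  empty <- candidates[0, c("est_id", "code", "strength", "p")]
  if (!nrow(candidates)) return(empty)
  # best candidate per estimator: max strength, ties -> smallest p
  best <- do.call(rbind, lapply(split(candidates, candidates$est_id),
                                function(d) {
    d <- d[order(-d$strength, d$p), , drop = FALSE]
    d[1, , drop = FALSE]
  }))
  if (nrow(best) == 1L)
    return(best[, c("est_id", "code", "strength", "p")])
  pass <- best[best$p < alpha_multi, , drop = FALSE]
  keep <- if (nrow(pass) >= 2L) {
    pass[order(pass$p, -pass$strength), , drop = FALSE][1:2, , drop = FALSE]
  } else if (nrow(pass) == 1L) {
    pass
  } else {
    best[order(-best$strength, best$p), , drop = FALSE][1, , drop = FALSE]
  }
  keep <- keep[order(keep$p, -keep$strength), , drop = FALSE]
  keep[, c("est_id", "code", "strength", "p")]
}

#' Construct a dominant-coupling tensor
#'
#' Container for per-window, per-pair dominant intrinsic coupling mode
#' records: up to two records per cell, each an (estimator id 1-5,
#' frequency code 0-36, strength, p) tuple; code 0 marks "no significant
#' coupling". Slot 1 holds the smaller-p record.
#'
#' @param est,code,strength,p arrays of dimension `c(2, T, P)`.
#' @param pairs data frame with channel indices `a`, `b` (P rows).
#' @param channel_names channel names.
#' @param meta optional list of pipeline metadata.
#' @return Object of class `dicm_tensor`.
#' @export
dicm_tensor <- function(est, code, strength, p, pairs, channel_names,
                        meta = list()) {
  stopifnot(length(dim(code)) == 3L, dim(code)[1] == 2L,
            dim(code)[3] == nrow(pairs))
  structure(list(est = est, code = code, strength = strength, p = p,
                 pairs = pairs, n_windows = dim(code)[2],
                 channel_names = channel_names, meta = meta),
            class = "dicm_tensor")
}

#' @export
print.dicm_tensor <- function(x, ...) {
  occ <- mean(x$code[1, , ] > 0)
  cat(sprintf("<dicm_tensor> T = %d windows x %d pairs (%d channels); %.1f%% of cells coupled\n",
              x$n_windows, nrow(x$pairs), length(x$channel_names), 100 * occ))
  invisible(x)
}

#' Run the dominant-intrinsic-coupling-mode pipeline
#'
#' For every channel pair and 2-s sliding window, evaluates all admissible
#' (estimator, frequency code) candidates, builds circular-shift surrogate
#' nulls (offsets of at least one second, shared across the candidates of a
#' window), converts them to empirical p-values, applies Benjamini-Hochberg
#' FDR per estimator across its frequency candidates, and selects the
#' dominant mode(s) with [select_dicm()].
#'
#' @param x a `recording` or a `banded_signals` object.
#' @param scheme optional `window_scheme` (default 2 s / 0.2 s).
#' @param estimators subset of `c("aec", "iplv", "pac", "dste", "dpli")`.
#' @param n_surr surrogates per candidate (default 1000; 10000 reproduces
#'   the reference profile, 200 is the desk-test scale).
#' @param q FDR level (default 0.01).
#' @param alpha_multi multi-estimator threshold (default 0.0025).
#' @param pairs optional data frame of channel pairs (`a`, `b`).
#' @param seed integer seed (surrogate offsets and symbolisation).
#' @param dste_k,dste_dim,dste_delays dSTE parameters.
#' @return A [dicm_tensor()] whose `meta` records the pipeline parameters
#'   and the overall candidate-test counts (`n_tests`, `n_retained`) of the
#'   FDR stage.
#' @export
run_dicm <- function(x, scheme = NULL,
                     estimators = c("aec", "iplv", "pac", "dste", "dpli"),
                     n_surr = 1000L, q = 0.01, alpha_multi = 0.0025,
                     pairs = NULL, seed = 1,
                     dste_k = 8L, dste_dim = 3L, dste_delays = 1:10) {
  banded <- if (inherits(x, "recording")) filterbank(x) else x
  stopifnot(inherits(banded, "banded_signals"))
  if (is.null(scheme))
    scheme <- make_windows(nrow(banded$filtered[[1]]), banded$fs)
  C <- length(banded$channel_names)
  if (is.null(pairs)) pairs <- all_pairs(C)
  pc <- precompute_coupling(banded, estimators, dste_k, dste_dim, seed)
  cand <- candidate_table(estimators)
  N <- pc$N
  min_shift <- round(banded$fs)
  if (N <= 2 * min_shift)
    stop("recording shorter than twice the minimum surrogate shift")
  set.seed(seed)
  T <- scheme$n_windows
  P <- nrow(pairs)
  est_a <- code_a <- str_a <- p_a <- array(NA_real_, c(2, T, P))
  code_a[] <- 0
  est_a[] <- 0
  n_tests <- 0L; n_retained <- 0L
  est_groups <- split(seq_len(nrow(cand)), cand$est)
  for (t in seq_len(T)) {
    idx <- scheme$starts[t]:scheme$ends[t]
    offs <- sample(min_shift:(N - min_shift), n_surr, replace = TRUE)
    IDX <- cbind(idx, outer(idx - 1L, offs, "+") %% N + 1L)
    idx_s <- pmin(idx, pc$Ns)
    IDXs <- cbind(idx_s, outer(idx_s - 1L, offs, "+") %% pc$Ns + 1L)
    for (pi in seq_len(P)) {
      M <- window_strengths(pc, cand, pairs$a[pi], pairs$b[pi], IDX, IDXs,
                            dste_delays)
      obs <- M[, 1]
      pv <- rowMeans(M[, -1, drop = FALSE] >= obs)
      pv[is.na(obs)] <- NA_real_
      sig <- rep(FALSE, nrow(cand))
      for (g in est_groups) {
        ok <- !is.na(pv[g])
        n_tests <- n_tests + sum(ok)
        m <- fdr_filter(pv[g], q)
        sig[g] <- m
        n_retained <- n_retained + sum(m)
      }
      if (any(sig)) {
        sel <- select_dicm(data.frame(est_id = cand$est_id[sig],
                                      code = cand$code[sig],
                                      strength = obs[sig], p = pv[sig]),
                           alpha_multi)
        for (r in seq_len(nrow(sel))) {
          est_a[r, t, pi] <- sel$est_id[r]
          code_a[r, t, pi] <- sel$code[r]
          str_a[r, t, pi] <- sel$strength[r]
          p_a[r, t, pi] <- sel$p[r]
        }
      }
    }
  }
  dicm_tensor(est_a, code_a, str_a, p_a, pairs, banded$channel_names,
              meta = list(estimators = estimators, n_surr = n_surr, q = q,
                          alpha_multi = alpha_multi, seed = seed,
                          n_tests = n_tests, n_retained = n_retained,
                          scheme = scheme))
}
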