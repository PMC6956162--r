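# shared fixtures and small oracles used across test files

# four-channel toy layout: frontal + temporal, one sensor per hemisphere
toy_layout <- function() {
  load_layout(data.frame(
    channel = paste0("ch", 1:4),
    lobe = c("frontal", "frontal", "temporal", "temporal"),
    hemisphere = c("L", "R", "L", "R"),
    stringsAsFactors = FALSE))
}

# linearly advancing phase ramp (n samples, arbitrary rate)
phase_ramp <- function(n, cycles = 10) seq(0, 2 * pi * cycles, length.out = n)

# raw-periodogram relative band power (independent of the package's Welch
# estimator)
periodogram_relpower <- function(x, fs, lo, hi) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sel <- f <= fs / 2
  sum(p[sel & f >= lo & f < hi]) / sum(p[sel])
}

# brute-force minimum-distance spanning tree by exhaustive edge-subset
# enumeration (d = 1/w); returns total distance of the optimum
brute_mst_distance <- function(w) {
  n <- nrow(w)
  edges <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  stopifnot(nrow(edges) >= n - 1)
  combs <- utils::combn(nrow(edges), n - 1)
  best <- Inf
  for (k in seq_len(ncol(combs))) {
    sel <- edges[combs[, k], , drop = FALSE]
    # spanning + acyclic check via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(sel))) {
      ra <- find(sel[r, 1]); rb <- find(sel[r, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    d <- sum(1 / w[sel])
    if (d < best) best <- d
  }
  best
}

# build a minimal dicm_tensor from a windows x pairs label matrix
# (labels as list(est, code)) and a strength matrix
toy_tensor <- function(est_mat, code_mat, strength_mat = NULL,
                       channel_names = paste0("ch", 1:4),
                       pairs = NULL) {
  T <- nrow(code_mat); P <- ncol(code_mat)
  if (is.null(pairs)) {
    stopifnot(P == choose(length(channel_names), 2))
    cmb <- utils::combn(length(channel_names), 2)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  if (is.null(strength_mat)) strength_mat <- matrix(0.5, T, P)
  est <- code <- strength <- p <- array(0, c(2, T, P))
  strength[] <- NA_real_; p[] <- NA_real_
  est[1, , ] <- est_mat
  code[1, , ] <- code_mat
  strength[1, , ] <- strength_mat
  p[1, , ] <- ifelse(code_mat > 0, 0, NA_real_)
  dicm_tensor(est, code, strength, p, pairs, channel_names)
}
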