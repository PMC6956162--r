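#' Band-limited Gaussian noise
#'
#' White Gaussian noise passed through the zero-phase Butterworth bandpass
#' used by the filterbank, scaled to unit variance. At least 90% of the
#' spectral power of the result lies inside the requested band.
#'
#' @param band numeric `c(lo, hi)` in Hz or a band name from [band_table()].
#' @param fs sampling rate (Hz); `hi` must be below `fs/2`.
#' @param duration_s duration in seconds (> 0).
#' @param seed optional integer seed (deterministic output when fixed).
#' @return Numeric vector of `round(duration_s * fs)` samples, zero mean,
#'   unit variance.
#' @export
gen_band_noise <- function(band, fs, duration_s, seed = NULL) {
  if (is.character(band)) {
    bt <- band_table()
    i <- match(band, bt$band)
    if (is.na(i)) stop("unknown band name: ", band)
    band <- c(bt$lo[i], bt$hi[i])
  }
  if (duration_s <= 0) stop("duration_s must be positive")
  if (band[2] >= fs / 2)
    stop("band upper edge ", band[2], " Hz at or above Nyquist (", fs / 2, " Hz)")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  x <- bandpass_zp(stats::rnorm(n), band[1], band[2], fs)
  as.numeric(scale(x))
}

# phase-diffusing oscillator at the band's centre frequency: constant
# envelope (so planted modulation depth is preserved exactly) with a
# phase random walk giving a ~1 Hz Lorentzian linewidth, so circular-shift
# surrogates decorrelate while the in-window phase stays coherent.
# Returns the instantaneous phase; the signal is sqrt(2)*cos(phase).
osc_phase <- function(n, fs, lo, hi, linewidth = 1) {
  f <- (lo + hi) / 2
  sigma <- sqrt(2 * pi * linewidth)
  stats::runif(1, 0, 2 * pi) + 2 * pi * f * (seq_len(n) - 1) / fs +
    cumsum(stats::rnorm(n, 0, sigma / sqrt(fs)))
}

#' Define a planted-coupling plan
#'
#' A coupling plan is a list of entries, each planting one coupling mode on
#' one channel pair:
#' \describe{
#'   \item{AEC}{amplitude-envelope coupling: the second channel keeps its
#'     own band phase but its envelope becomes a `strength`-weighted
#'     mixture with the first channel's envelope.}
#'   \item{iPLV}{phase-only coupling: the second channel keeps its own
#'     amplitude envelope while its phase becomes a phasor mixture of the
#'     first channel's constant-lagged phase (weight `strength`) and its
#'     own phase.}
#'   \item{PAC}{the low-band phase of the first channel multiplies the
#'     high-band carrier of the second via
#'     `1 - depth + depth * (1 + cos(phase)) / 2` with `depth = strength`.}
#'   \item{dSTE}{delayed copy injection (within band) or delayed
#'     phase-modulation (cross band) with `delay` samples.}
#'   \item{dPLI}{delayed copy of the first channel's band component, giving
#'     a consistent positive phase lag.}
#' }
#'
#' @param pair integer pair `c(i, j)` of channel indices.
#' @param mode one of `"aec"`, `"iplv"`, `"pac"`, `"dste"`, `"dpli"`.
#' @param band_low band name or index (the only band for within-band modes).
#' @param band_high high band for PAC / cross-band dSTE; `NULL` otherwise.
#' @param strength coupling strength / modulation depth in `[0, 1]`.
#' @param lag phase lag in radians for iPLV (default `pi / 2`).
#' @param delay delay in samples for dSTE / dPLI (default 3).
#' @param active optional sample range `c(from, to)` within which the entry
#'   is active; `NULL` = whole recording.
#' @return A one-entry `coupling_plan`; combine entries with [c()].
#' @export
plan_entry <- function(pair, mode = c("aec", "iplv", "pac", "dste", "dpli"),
                       band_low, band_high = NULL, strength = 0.8,
                       lag = pi / 2, delay = 3, active = NULL) {
  mode <- match.arg(mode)
  bt <- band_table()$band
  to_idx <- function(b) {
    if (is.character(b)) b <- match(b, bt)
    if (is.na(b) || b < 1 || b > 8) stop("invalid band in plan entry")
    as.integer(b)
  }
  band_low <- to_idx(band_low)
  if (!is.null(band_high)) {
    band_high <- to_idx(band_high)
    if (band_low >= band_high)
      stop("plan entry: low band must precede high band")
  }
  if (mode == "pac" && is.null(band_high))
    stop("PAC entries need band_high")
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]")
  e <- list(pair = as.integer(pair), mode = mode, band_low = band_low,
            band_high = band_high, strength = strength, lag = lag,
            delay = as.integer(delay), active = active)
  structure(list(e), class = "coupling_plan")
}

#' @export
c.coupling_plan <- function(...) {
  structure(unlist(lapply(list(...), unclass), recursive = FALSE),
            class = "coupling_plan")
}

# which (channel, band) components an entry rewrites
entry_targets <- function(e) {
  b_target <- if (is.null(e$band_high)) e$band_low else e$band_high
  if (e$mode %in% c("pac", "dste") && !is.null(e$band_high))
    list(c(e$pair[1], e$band_low), c(e$pair[2], b_target))
  else
    list(c(e$pair[2], b_target))
}

validate_plan <- function(plan, n_channels, n_samples) {
  if (is.null(plan)) return(invisible(NULL))
  if (!inherits(plan, "coupling_plan")) stop("plan must be a coupling_plan")
  seen <- list()
  for (e in plan) {
    if (any(e$pair < 1 | e$pair > n_channels) || e$pair[1] == e$pair[2])
      stop("plan entry pair out of range")
    rng <- if (is.null(e$active)) c(1L, n_samples) else as.integer(e$active)
    if (rng[1] < 1 || rng[2] > n_samples || rng[1] > rng[2])
      stop("plan entry active range outside recording")
    for (tg in entry_targets(e)) {
      key_new <- list(tg = tg, rng = rng)
      for (old in seen) {
        if (all(old$tg == tg) && rng[1] <= old$rng[2] && old$rng[1] <= rng[2])
          stop("contradictory plan entries target channel ", tg[1],
               ", band ", tg[2], " in overlapping ranges")
      }
      seen[[length(seen) + 1L]] <- key_new
    }
  }
  invisible(NULL)
}

shift_vec <- function(x, d) {
  n <- length(x)
  x[((seq_len(n) - 1 - d) %% n) + 1]
}

#' Generate a synthetic multichannel recording with planted coupling
#'
#' Each channel is a 1/f-weighted mixture of the eight filterbank bands
#' (independent band-limited noise). Plan entries then rewrite individual
#' (channel, band) components to plant amplitude-envelope coupling,
#' constant-lag phase coupling, phase-amplitude modulation or delayed
#' directed coupling (see [plan_entry()]).
#'
#' @param n_channels number of channels.
#' @param fs sampling rate in Hz (> 90 so that the gamma band is resolvable).
#' @param duration_s duration in seconds.
#' @param plan a `coupling_plan` or `NULL` (independent channels).
#' @param seed integer seed; fixed seed gives bit-identical recordings.
#' @param channel_names,system forwarded to [new_recording()].
#' @return A `recording`.
#' @export
gen_recording <- function(n_channels, fs, duration_s, plan = NULL, seed = 1,
                          channel_names = NULL, system = "synthetic") {
  set.seed(seed)
  n <- round(duration_s * fs)
  bt <- band_table()
  validate_plan(plan, n_channels, n)
  # background components: comp[[b]] is samples x channels, unit variance
  comp <- lapply(seq_len(8), function(b)
    sapply(seq_len(n_channels), function(ch)
      gen_band_noise(c(bt$lo[b], bt$hi[b]), fs, duration_s)))
  for (b in seq_len(8)) comp[[b]] <- matrix(comp[[b]], n, n_channels)

  if (!is.null(plan)) for (e in plan) {
    i <- e$pair[1]; j <- e$pair[2]; s <- e$strength
    rng <- if (is.null(e$active)) seq_len(n) else seq(e$active[1], e$active[2])
    bl <- e$band_low
    bh <- if (is.null(e$band_high)) bl else e$band_high
    if (e$mode == "aec") {
      # envelope mixing: channel j keeps its own band phase but its
      # amplitude envelope becomes a weighted mixture with channel i's,
      # so windowed envelope correlation tracks the requested strength
      # without introducing phase coupling
      ai <- analytic_signal(comp[[bl]][rng, i])
      aj <- analytic_signal(comp[[bl]][rng, j])
      env_mix <- s * Mod(ai) + (1 - s) * Mod(aj)
      comp[[bl]][rng, j] <- as.numeric(scale(env_mix * cos(Arg(aj))))
    } else if (e$mode == "iplv") {
      # phase-only coupling: channel j keeps its own amplitude envelope,
      # its phase becomes a phasor mixture of channel i's lagged phase and
      # an independent phase, so AEC stays at the null level
      ai <- analytic_signal(comp[[bl]][rng, i])
      aj <- analytic_signal(comp[[bl]][rng, j])
      zmix <- s * exp(1i * (Arg(ai) - e$lag)) + (1 - s) * exp(1i * Arg(aj))
      comp[[bl]][rng, j] <- as.numeric(scale(Mod(aj) * cos(Arg(zmix))))
    } else if (e$mode == "dpli") {
      lagged <- shift_vec(comp[[bl]][rng, i], e$delay)
      indep <- gen_band_noise(c(bt$lo[bl], bt$hi[bl]), fs, length(rng) / fs)
      comp[[bl]][rng, j] <- as.numeric(scale(s * lagged + (1 - s) * indep))
    } else if (e$mode == "pac") {
      # standard narrowband PAC synthesis: the modulating channel's low
      # band becomes a phase-diffusing oscillator whose phase multiplies a
      # constant-envelope high-band carrier on the modulated channel, at a
      # non-zero lag (default pi/2) because the downstream estimator is
      # imaginary-part based and deliberately blind to zero-lag coupling
      phi <- osc_phase(length(rng), fs, bt$lo[bl], bt$hi[bl])
      comp[[bl]][rng, i] <- sqrt(2) * cos(phi)
      carrier <- sqrt(2) * cos(osc_phase(length(rng), fs, bt$lo[bh], bt$hi[bh]))
      comp[[bh]][rng, j] <- carrier *
        (1 - s + s * (1 + cos(phi - e$lag)) / 2)
    } else if (e$mode == "dste") {
      if (is.null(e$band_high)) {
        lagged <- shift_vec(comp[[bl]][rng, i], e$delay)
        indep <- gen_band_noise(c(bt$lo[bl], bt$hi[bl]), fs, length(rng) / fs)
        comp[[bl]][rng, j] <- as.numeric(scale(s * lagged + (1 - s) * indep))
      } else {
        phi <- osc_phase(length(rng), fs, bt$lo[bl], bt$hi[bl])
        comp[[bl]][rng, i] <- sqrt(2) * cos(phi)
        phi_d <- shift_vec(phi - e$lag, e$delay)
        carrier <- sqrt(2) * cos(osc_phase(length(rng), fs, bt$lo[bh], bt$hi[bh]))
        comp[[bh]][rng, j] <- carrier *
          (1 - s + s * (1 + cos(phi_d)) / 2)
      }
    }
  }
  w <- 1 / sqrt((bt$lo + bt$hi) / 2)  # 1/f-ish band weighting
  data <- matrix(0, n_channels, n)
  for (b in seq_len(8)) data <- data + w[b] * t(comp[[b]])
  new_recording(data, fs = fs, channel_names = channel_names, system = system)
}

#' Generate a recording whose coupling regime switches over time
#'
#' The recording alternates between the supplied coupling plans every
#' `dwell_s` seconds (cycling through `modes`), driving label changes in the
#' downstream dominant-coupling tensor and hence a nonzero flexibility
#' index on the planted pairs.
#'
#' @param n_channels,fs,duration_s,seed as in [gen_recording()].
#' @param modes list of `coupling_plan`s (entries must not set `active`).
#' @param dwell_s dwell time per regime in seconds; must be at least one
#'   analysis window (2 s).
#' @return A `recording`.
#' @export
gen_switching_recording <- function(n_channels, fs, duration_s, modes,
                                    dwell_s, seed = 1) {
  if (dwell_s < 2) stop("dwell_s shorter than the 2-s analysis window")
  n <- round(duration_s * fs)
  dwell <- round(dwell_s * fs)
  starts <- seq(1L, n, by = dwell)
  combined <- NULL
  for (k in seq_along(starts)) {
    plan_k <- modes[[(k - 1L) %% length(modes) + 1L]]
    to <- min(starts[k] + dwell - 1L, n)
    for (e in plan_k) {
      e$active <- c(starts[k], to)
      entry <- structure(list(e), class = "coupling_plan")
      combined <- if (is.null(combined)) entry else c(combined, entry)
    }
  }
  gen_recording(n_channels, fs, duration_s, plan = combined, seed = seed)
}

#' Generate a synthetic cohort with a quadratic flexibility-age curve
#'
#' Fast path used for model-fitting and group-comparison tests: ages are
#' sampled uniformly within six age bins (8-12, 13-17, 18-27, 28-37, 38-50,
#' 51-60 years, allocated proportionally to the reference cohort sizes
#' 24/26/43/43/28/14) and the flexibility index follows
#' `FI = a * age^2 + b * age + c + N(0, sd^2)`, clamped to `[0, 1]`.
#'
#' @param n cohort size (>= 1).
#' @param fi_curve numeric `c(a, b, c)` of the quadratic; the default peaks
#'   around age 40.
#' @param noise_sd residual standard deviation.
#' @param group group label for every participant.
#' @param group_offset additive FI offset (e.g. a clinical deficit).
#' @param age_sampler optional function `n -> ages` replacing the binned
#'   sampler.
#' @param seed integer seed.
#' @return A data frame (`id`, `age`, `group`, `FI`).
#' @export
gen_cohort <- function(n = 178, fi_curve = c(a = -2e-4, b = 0.016, c = 0.1),
                       noise_sd = 0.02, group = "HP", group_offset = 0,
                       age_sampler = NULL, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  if (is.null(age_sampler)) {
    bins <- cbind(lo = c(8, 13, 18, 28, 38, 51), hi = c(12, 17, 27, 37, 50, 60))
    prop <- c(24, 26, 43, 43, 28, 14) / 178
    counts <- floor(n * prop)
    while (sum(counts) < n) {
      k <- which.max(n * prop - counts)
      counts[k] <- counts[k] + 1L
    }
    ages <- unlist(lapply(seq_len(6), function(k)
      stats::runif(counts[k], bins[k, 1], bins[k, 2])))
    ages <- sample(ages)
  } else {
    ages <- age_sampler(n)
  }
  fi <- fi_curve[1] * ages^2 + fi_curve[2] * ages + fi_curve[3] +
    group_offset + stats::rnorm(n, 0, noise_sd)
  data.frame(id = sprintf("S%03d", seq_len(n)), age = ages, group = group,
             FI = pmin(pmax(fi, 0), 1), stringsAsFactors = FALSE)
}

#' Synthetic group-separated feature vectors
#'
#' Generates `n_features`-dimensional feature vectors for `n_groups` groups
#' whose group means are `shift` standard deviations apart (per coordinate,
#' in expectation), with unit within-group noise. Used to exercise the
#' multi-class SVM path at a controlled separability.
#'
#' @param n_per_group participants per group.
#' @param n_groups number of groups (default 6).
#' @param n_features feature dimension (default 22, matching the MSS/FO set).
#' @param shift between-group mean shift in within-group SDs.
#' @param seed integer seed.
#' @return List with `x` (matrix) and `group` (factor).
#' @export
gen_group_features <- function(n_per_group, n_groups = 6, n_features = 22,
                               shift = 2, seed = 1) {
  set.seed(seed)
  mu <- matrix(stats::rnorm(n_groups * n_features, sd = shift),
               n_groups, n_features)
  x <- do.call(rbind, lapply(seq_len(n_groups), function(g)
    sweep(matrix(stats::rnorm(n_per_group * n_features), n_per_group),
          2, mu[g, ], "+")))
  list(x = x, group = factor(rep(seq_len(n_groups), each = n_per_group)))
}
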