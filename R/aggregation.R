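# Lobar integration of the dominant-coupling tensor: dominance calls,
# mean subgraph strength (MSS), fractional occupancy (FO) and the
# flexibility index (FI).

# indices (into dicm$pairs) of the sensor pairs of one subnetwork row
subnet_pairs <- function(dicm, layout, lobe1, lobe2, scope, hemi1 = NA) {
  chn <- dicm$channel_names
  nm_a <- chn[dicm$pairs$a]
  nm_b <- chn[dicm$pairs$b]
  between <- function(s1, s2) {
    which((nm_a %in% s1 & nm_b %in% s2) | (nm_a %in% s2 & nm_b %in% s1))
  }
  if (lobe1 == lobe2) {
    if (scope == "cross") {
      between(layout_channels(layout, lobe1, "L"),
              layout_channels(layout, lobe1, "R"))
    } else {  # within: pairs internal to each hemisphere's sensors
      L <- layout_channels(layout, lobe1, "L")
      R <- layout_channels(layout, lobe1, "R")
      c(which(nm_a %in% L & nm_b %in% L), which(nm_a %in% R & nm_b %in% R))
    }
  } else {
    s1 <- if (is.na(hemi1)) layout_channels(layout, lobe1)
          else layout_channels(layout, lobe1, hemi1)
    if (scope == "both") {
      between(s1, layout_channels(layout, lobe2))
    } else if (scope == "cross") {
      if (!is.na(hemi1)) {
        opp <- if (hemi1 == "L") "R" else "L"
        between(layout_channels(layout, lobe1, hemi1),
                layout_channels(layout, lobe2, opp))
      } else {
        c(between(layout_channels(layout, lobe1, "L"),
                  layout_channels(layout, lobe2, "R")),
          between(layout_channels(layout, lobe1, "R"),
                  layout_channels(layout, lobe2, "L")))
      }
    } else {  # within-hemisphere lobe pair
      c(between(layout_channels(layout, lobe1, "L"),
                layout_channels(layout, lobe2, "L")),
        between(layout_channels(layout, lobe1, "R"),
                layout_channels(layout, lobe2, "R")))
    }
  }
}

# per-window fraction of subnetwork pairs labelled with (est_id, code)
mode_match_fraction <- function(dicm, pair_idx, est_id, code) {
  if (!length(pair_idx)) return(numeric(0))
  lab_est <- dicm$est[1, , pair_idx, drop = FALSE]
  lab_code <- dicm$code[1, , pair_idx, drop = FALSE]
  match <- (lab_est == est_id) & (lab_code == code)
  apply(match, 2, mean)
}

#' Dominance summary per lobe-group pair and coupling mode
#'
#' A coupling mode (estimator id, frequency code) is the characteristic
#' interaction of a pair of lobe-hemisphere groups when it labels more
#' than 75% of the sensor pairs between the groups (per window) in at
#' least 50% of all temporal segments.
#'
#' @param dicm a `dicm_tensor`.
#' @param layout a `lobar_layout` covering the tensor's channels.
#' @return Data frame, one row per (group pair, observed mode):
#'   `group1`, `group2`, `est_id`, `code`, `sensor_fraction` (mean over
#'   windows of the matching-pair fraction), `n_dom` (windows with
#'   fraction > 0.75), `n_ts`, `segment_fraction`, `dominant`.
#' @export
dominance <- function(dicm, layout) {
  stopifnot(inherits(dicm, "dicm_tensor"))
  chn <- dicm$channel_names
  groups <- sort(unique(layout$map$group[layout$map$channel %in% chn]))
  nm_a <- chn[dicm$pairs$a]
  nm_b <- chn[dicm$pairs$b]
  grp_of <- stats::setNames(layout$map$group, layout$map$channel)
  out <- list()
  for (g1i in seq_along(groups)) for (g2i in g1i:length(groups)) {
    g1 <- groups[g1i]; g2 <- groups[g2i]
    idx <- which((grp_of[nm_a] == g1 & grp_of[nm_b] == g2) |
                 (grp_of[nm_a] == g2 & grp_of[nm_b] == g1))
    if (!length(idx)) next
    lab_est <- dicm$est[1, , idx, drop = FALSE]
    lab_code <- dicm$code[1, , idx, drop = FALSE]
    modes <- unique(data.frame(est_id = as.vector(lab_est),
                               code = as.vector(lab_code)))
    modes <- modes[modes$code > 0, , drop = FALSE]
    for (r in seq_len(nrow(modes))) {
      frac <- mode_match_fraction(dicm, idx, modes$est_id[r], modes$code[r])
      n_dom <- sum(frac > 0.75)
      out[[length(out) + 1L]] <- data.frame(
        group1 = g1, group2 = g2,
        est_id = modes$est_id[r], code = modes$code[r],
        sensor_fraction = mean(frac), n_dom = n_dom,
        n_ts = dicm$n_windows,
        segment_fraction = n_dom / dicm$n_windows,
        dominant = n_dom / dicm$n_windows >= 0.5,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group1 = character(0), group2 = character(0),
                      est_id = integer(0), code = integer(0),
                      sensor_fraction = numeric(0), n_dom = integer(0),
                      n_ts = integer(0), segment_fraction = numeric(0),
                      dominant = logical(0)))
  do.call(rbind, out)
}

#' Mean subgraph strength of a coupling mode over a lobar subnetwork
#'
#' Over the dominant temporal segments (windows where the mode labels
#' > 75% of the subnetwork's sensor pairs), the per-window sum of coupling
#' strengths of the matching pairs is divided by the number of sensor
#' pairs, then averaged over those segments. Lies in `[0, 1]`. With no
#' dominant segment the value is 0 with attribute `flag = TRUE`.
#'
#' @param dicm a `dicm_tensor`.
#' @param layout a `lobar_layout`.
#' @param lobe1,lobe2 lobe names (equal for a single-lobe topography).
#' @param scope `"cross"`, `"within"` or `"both"` (hemisphere scope).
#' @param est_id,code the coupling mode.
#' @param hemi1 optional hemisphere restriction of `lobe1`.
#' @return Numeric MSS value.
#' @export
mss <- function(dicm, layout, lobe1, lobe2 = lobe1, scope = "cross",
                est_id, code, hemi1 = NA) {
  idx <- subnet_pairs(dicm, layout, lobe1, lobe2, scope, hemi1)
  mss_on_pairs(dicm, idx, est_id, code)
}

mss_on_pairs <- function(dicm, pair_idx, est_id, code) {
  if (!length(pair_idx)) return(structure(0, flag = TRUE))
  frac <- mode_match_fraction(dicm, pair_idx, est_id, code)
  dom <- which(frac > 0.75)
  if (!length(dom)) return(structure(0, flag = TRUE))
  lab_est <- dicm$est[1, , pair_idx, drop = FALSE]
  lab_code <- dicm$code[1, , pair_idx, drop = FALSE]
  str <- dicm$strength[1, , pair_idx, drop = FALSE]
  match <- (lab_est == est_id) & (lab_code == code)
  str[!match | is.na(str)] <- 0
  per_window <- apply(str, 2, sum) / length(pair_idx)
  structure(mean(per_window[dom]), flag = FALSE)
}

#' Fractional occupancy of a coupling mode over a lobar subnetwork
#'
#' The fraction of temporal segments in which the mode is dominant
#' (labels > 75% of the subnetwork's sensor pairs): `N_Dom / N_TS`.
#'
#' @inheritParams mss
#' @return Numeric FO value in `[0, 1]`.
#' @export
fo <- function(dicm, layout, lobe1, lobe2 = lobe1, scope = "cross",
               est_id, code, hemi1 = NA) {
  idx <- subnet_pairs(dicm, layout, lobe1, lobe2, scope, hemi1)
  fo_on_pairs(dicm, idx, est_id, code)
}

fo_on_pairs <- function(dicm, pair_idx, est_id, code) {
  if (!length(pair_idx)) return(structure(0, flag = TRUE))
  frac <- mode_match_fraction(dicm, pair_idx, est_id, code)
  structure(sum(frac > 0.75) / dicm$n_windows, flag = FALSE)
}

#' Flexibility index
#'
#' The rate of dominant-coupling-mode label changes between consecutive
#' temporal segments, per sensor pair, averaged over the whole sensor
#' network. Labels are (estimator id, frequency code) with code 0 for
#' "no coupling"; transitions into or out of code 0 count as changes.
#'
#' @param dicm a `dicm_tensor` with at least two windows.
#' @return Object of class `flexibility_result`: `fi_global` in `[0, 1]`
#'   and `fi_pairs` (per-pair change rates).
#' @export
flexibility <- function(dicm) {
  stopifnot(inherits(dicm, "dicm_tensor"))
  T <- dicm$n_windows
  if (T < 2) stop("flexibility requires at least 2 windows")
  lab <- dicm$est[1, , , drop = FALSE] * 100 + dicm$code[1, , , drop = FALSE]
  lab <- array(lab, dim(lab)[2:3])  # T x P
  if (is.null(dim(lab))) lab <- matrix(lab, ncol = nrow(dicm$pairs))
  changes <- lab[-1, , drop = FALSE] != lab[-T, , drop = FALSE]
  fi_pairs <- colSums(changes) / (T - 1)
  structure(list(fi_global = mean(fi_pairs), fi_pairs = fi_pairs,
                 n_windows = T),
            class = "flexibility_result")
}

#' @export
print.flexibility_result <- function(x, ...) {
  cat(sprintf("<flexibility_result> FI_global = %.4f over %d pairs, T = %d\n",
              x$fi_global, length(x$fi_pairs), x$n_windows))
  invisible(x)
}

#' Subnetwork feature vector (12 MSS + 10 FO)
#'
#' Evaluates the ranked subnetwork configuration ([load_table1_spec()]) on
#' a dominant-coupling tensor: one MSS value per row and an FO value for
#' the rows that define one. Rows whose lobes are absent from the layout
#' (or that never reach a dominant segment) contribute 0 and are flagged.
#'
#' @param dicm a `dicm_tensor`.
#' @param layout a `lobar_layout`.
#' @param spec a subnetwork specification (default [load_table1_spec()]).
#' @return Named numeric vector of length 22 (`MSS1..MSS12` then `FO<row>`
#'   for the FO-bearing rows), with a logical `flags` attribute marking
#'   missing-dominance entries.
#' @export
feature_vector <- function(dicm, layout, spec = load_table1_spec()) {
  present <- unique(layout$map$lobe[layout$map$channel %in% dicm$channel_names])
  mss_v <- numeric(nrow(spec))
  fo_v <- numeric(sum(spec$has_FO))
  flags <- logical(nrow(spec))
  fo_i <- 0L
  fo_names <- character(sum(spec$has_FO))
  for (r in seq_len(nrow(spec))) {
    row <- spec[r, ]
    if (!(row$lobe1 %in% present) || !(row$lobe2 %in% present)) {
      idx <- integer(0)
    } else {
      idx <- subnet_pairs(dicm, layout, row$lobe1, row$lobe2, row$scope,
                          row$hemi1)
    }
    m <- mss_on_pairs(dicm, idx, row$est_id, row$code)
    mss_v[r] <- as.numeric(m)
    flags[r] <- isTRUE(attr(m, "flag"))
    if (row$has_FO) {
      fo_i <- fo_i + 1L
      fo_v[fo_i] <- as.numeric(fo_on_pairs(dicm, idx, row$est_id, row$code))
      fo_names[fo_i] <- paste0("FO", row$row)
    }
  }
  out <- c(stats::setNames(mss_v, paste0("MSS", spec$row)),
           stats::setNames(fo_v, fo_names))
  attr(out, "flags") <- flags
  out
}
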