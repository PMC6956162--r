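#' The eight-band filterbank
#'
#' Canonical frequency bands used throughout the pipeline:
#' delta (0.5--4), theta (4--8), alpha1 (8--10), alpha2 (10--13),
#' beta1 (13--15), beta2 (15--19), beta3 (20--29) and gamma (30--45) Hz.
#' Band edges are half-open `[lo, hi)`.
#'
#' @return A data frame with columns `band` (name), `lo` and `hi` (Hz).
#' @export
#' @examples
#' band_table()
band_table <- function() {
  data.frame(
    band = c("delta", "theta", "alpha1", "alpha2",
             "beta1", "beta2", "beta3", "gamma"),
    lo = c(0.5, 4, 8, 10, 13, 15, 20, 30),
    hi = c(4, 8, 10, 13, 15, 19, 29, 45),
    stringsAsFactors = FALSE
  )
}

#' Frequency-code table
#'
#' Integer codes identifying the frequency content of a coupling record.
#' Codes 1--8 are the within-band codes (delta..gamma in `band_table()`
#' order); codes 9--36 are the 28 ordered low < high cross-band pairs in
#' lexicographic order. Code 0 is reserved for "no significant coupling".
#'
#' @return Data frame with columns `code`, `type` ("within"/"cross"),
#'   `band_low`, `band_high` (band indices 1--8) and `label`.
#' @export
#' @examples
#' fc <- freq_codes()
#' sum(fc$type == "cross")  # 28
freq_codes <- function() {
  bt <- band_table()$band
  within <- data.frame(
    code = 1:8, type = "within", band_low = 1:8, band_high = 1:8,
    label = bt, stringsAsFactors = FALSE
  )
  pairs <- utils::combn(8, 2)
  cross <- data.frame(
    code = 9:36, type = "cross",
    band_low = pairs[1, ], band_high = pairs[2, ],
    label = paste0(bt[pairs[1, ]], "->", bt[pairs[2, ]]),
    stringsAsFactors = FALSE
  )
  rbind(within, cross)
}

#' Look up the code of a cross-band pair
#'
#' @param low,high band indices (1--8) or names; `low` must precede `high`.
#' @return Integer code in 9--36.
#' @export
cross_code <- function(low, high) {
  bt <- band_table()$band
  if (is.character(low)) low <- match(low, bt)
  if (is.character(high)) high <- match(high, bt)
  stopifnot(!is.na(low), !is.na(high))
  if (low >= high) stop("cross_code(): 'low' band must precede 'high' band")
  fc <- freq_codes()
  fc$code[fc$type == "cross" & fc$band_low == low & fc$band_high == high]
}

#' Look up the within-band code of a band
#' @param band band index (1--8) or name.
#' @return Integer code in 1--8.
#' @export
within_code <- function(band) {
  bt <- band_table()$band
  if (is.character(band)) band <- match(band, bt)
  stopifnot(!is.na(band), band >= 1, band <= 8)
  as.integer(band)
}

#' Coupling-estimator table
#'
#' The five estimators and their integer ids: 1 AEC, 2 same-frequency iPLV,
#' 3 PAC, 4 dSTE, 5 dPLI, together with the frequency codes each admits.
#'
#' @return Data frame with columns `id`, `name`, `within`, `cross`.
#' @export
estimator_table <- function() {
  data.frame(
    id = 1:5,
    name = c("aec", "iplv", "pac", "dste", "dpli"),
    within = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    cross = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# codes admissible for one estimator name
admissible_codes <- function(name) {
  et <- estimator_table()
  row <- et[et$name == name, ]
  if (nrow(row) != 1L) stop("unknown estimator: ", name)
  fc <- freq_codes()
  codes <- integer(0)
  if (row$within) codes <- c(codes, fc$code[fc$type == "within"])
  if (row$cross) codes <- c(codes, fc$code[fc$type == "cross"])
  codes
}
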