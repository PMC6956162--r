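#' Construct a recording
#'
#' A recording is a channels x samples real matrix plus its sampling rate and
#' channel metadata. All pipeline stages consume this container.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per channel. Defaults to
#'   `ch1..chC`.
#' @param system free-form system label (e.g. `"magnes248"`, `"ctf275"`).
#' @return An object of class `recording` with elements `data`, `fs`,
#'   `channel_names`, `system`, `duration_s`.
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(400), 2), fs = 100)
#' rec
new_recording <- function(data, fs, channel_names = NULL, system = "generic") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  rec <- structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         system = system, duration_s = ncol(data) / fs),
    class = "recording"
  )
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop("invalid recording: fs must be a single positive number")
  if (length(rec$channel_names) != nrow(rec$data))
    stop("invalid recording: one channel name per row required")
  if (anyDuplicated(rec$channel_names))
    stop("invalid recording: duplicated channel names")
  if (any(!is.finite(rec$data)))
    stop("invalid recording: data contain NaN/Inf or missing values")
  if (ncol(rec$data) != round(rec$duration_s * rec$fs))
    stop("invalid recording: samples inconsistent with duration_s * fs")
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples, fs = %g Hz (%.1f s), system = %s\n",
              nrow(x$data), ncol(x$data), x$fs, x$duration_s, x$system))
  invisible(x)
}

#' Write a recording to disk
#'
#' The native text container is TSV (channels as columns, header row of
#' channel names) with a JSON sidecar `<path>.json` holding `fs` and
#' `system`. An HDF5 container (datasets `/data` channels x samples, `/fs`,
#' `/channel_names`, `/system`) is also supported when the `rhdf5` package
#' is available.
#'
#' @param rec a `recording`.
#' @param path output path.
#' @param format `"tsv"` or `"hdf5"`; `"auto"` picks by file extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "tsv", "hdf5")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path)
  validate_recording(rec)
  if (format == "tsv") {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_names
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    jsonlite::write_json(list(fs = rec$fs, system = rec$system),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 support requires the 'rhdf5' package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(rec$data, path, "data")
    rhdf5::h5write(rec$fs, path, "fs")
    rhdf5::h5write(rec$channel_names, path, "channel_names")
    rhdf5::h5write(rec$system, path, "system")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         "h5" = , "hdf5" = "hdf5",
         "tsv" = , "txt" = "tsv",
         "fif" = "fif",
         stop("cannot infer recording format from extension: .", ext))
}

#' Read a recording
#'
#' @param path file path.
#' @param format `"tsv"`, `"hdf5"`, `"fif"` or `"auto"` (by extension). FIF
#'   reading delegates channel extraction to the system Python's `mne`.
#' @return A validated [new_recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "tsv", "hdf5", "fif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- format_from_ext(path)
  if (format == "tsv") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("format error: TSV recording requires a JSON sidecar declaring fs (",
           sidecar, " missing)")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("format error: sidecar does not declare fs")
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    new_recording(t(as.matrix(df)), fs = meta$fs,
                  channel_names = names(df),
                  system = if (is.null(meta$system)) "generic" else meta$system)
  } else if (format == "hdf5") {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("HDF5 support requires the 'rhdf5' package")
    contents <- rhdf5::h5ls(path)$name
    if (!("fs" %in% contents))
      stop("format error: HDF5 recording does not declare fs")
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    new_recording(rhdf5::h5read(path, "data"),
                  fs = as.numeric(rhdf5::h5read(path, "fs")),
                  channel_names = as.character(rhdf5::h5read(path, "channel_names")),
                  system = if ("system" %in% contents)
                    as.character(rhdf5::h5read(path, "system")) else "generic")
  } else {
    read_fif_via_mne(path)
  }
}

# Delegate FIF parsing to the system Python's mne, converting to the TSV
# container in a temporary directory.
read_fif_via_mne <- function(path) {
  py <- Sys.which("python")
  if (py == "") stop("FIF reading requires a system 'python' with mne")
  out <- file.path(tempdir(), paste0("fif2tsv_", basename(path), ".tsv"))
  script <- paste(
    "import sys, json, mne, numpy as np",
    "raw = mne.io.read_raw_fif(sys.argv[1], preload=True, verbose='ERROR')",
    "data = raw.get_data()",
    "names = raw.ch_names",
    "with open(sys.argv[2], 'w') as f:",
    "    f.write('\\t'.join(names) + '\\n')",
    "    np.savetxt(f, data.T, delimiter='\\t')",
    "json.dump({'fs': raw.info['sfreq'], 'system': 'fif'},",
    "          open(sys.argv[2] + '.json', 'w'))",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(path), shQuote(out)))
  if (status != 0L) stop("mne failed to read FIF file: ", path)
  read_recording(out, format = "tsv")
}

#' Load a sensor-to-lobe layout
#'
#' A lobar layout maps every channel to one of five lobes
#' (frontal, temporal, parietal, parieto-occipital, occipital) in one
#' hemisphere (L/R). The packaged 248/275-sensor maps are approximate,
#' name-based partitions (the reference assignments are not published) and
#' can be replaced by any user map.
#'
#' @param map a data frame with columns `channel`, `lobe`, `hemisphere`, or
#'   the path of a TSV file with those columns.
#' @param channels optional character vector of channel names that must all
#'   be covered by the map (e.g. `rec$channel_names`).
#' @return An object of class `lobar_layout`: the map plus a `group` column
#'   (`lobe.hemisphere`) and a `counts` table of sensors per group.
#' @export
#' @examples
#' toy <- data.frame(channel = paste0("ch", 1:4),
#'                   lobe = c("frontal", "frontal", "temporal", "temporal"),
#'                   hemisphere = c("L", "R", "L", "R"))
#' load_layout(toy)
load_layout <- function(map, channels = NULL) {
  if (is.character(map) && length(map) == 1L)
    map <- utils::read.table(map, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  req <- c("channel", "lobe", "hemisphere")
  if (!all(req %in% names(map)))
    stop("layout map needs columns: ", paste(req, collapse = ", "))
  lobes <- c("frontal", "temporal", "parietal", "parieto-occipital", "occipital")
  bad <- setdiff(unique(map$lobe), lobes)
  if (length(bad))
    stop("unknown lobe label(s): ", paste(bad, collapse = ", "))
  if (!all(map$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  if (anyDuplicated(map$channel))
    stop("layout maps a channel more than once: ",
         paste(unique(map$channel[duplicated(map$channel)]), collapse = ", "))
  if (!is.null(channels)) {
    missing <- setdiff(channels, map$channel)
    if (length(missing))
      stop("layout does not map channel(s): ", paste(missing, collapse = ", "))
    map <- map[map$channel %in% channels, , drop = FALSE]
  }
  # both hemispheres non-empty for each lobe present
  for (lb in unique(map$lobe)) {
    hemis <- unique(map$hemisphere[map$lobe == lb])
    if (length(hemis) < 2L)
      stop("lobe '", lb, "' present in only one hemisphere")
  }
  map$group <- paste(map$lobe, map$hemisphere, sep = ".")
  structure(list(map = map, counts = table(map$group)),
            class = "lobar_layout")
}

#' @export
print.lobar_layout <- function(x, ...) {
  cat(sprintf("<lobar_layout> %d channels in %d lobe-hemisphere groups\n",
              nrow(x$map), length(x$counts)))
  print(x$counts)
  invisible(x)
}

# channels of one (lobe, hemisphere) group; hemi NULL = both
layout_channels <- function(layout, lobe, hemi = NULL) {
  m <- layout$map
  sel <- m$lobe == lobe
  if (!is.null(hemi)) sel <- sel & m$hemisphere == hemi
  m$channel[sel]
}

#' Packaged approximate sensor layouts
#'
#' @param system `"magnes248"` (248 axial gradiometers, names `A1..A248`) or
#'   `"ctf275"` (275 channels, CTF-style prefixed names).
#' @return A [load_layout()] object.
#' @export
default_layout <- function(system = c("magnes248", "ctf275")) {
  system <- match.arg(system)
  path <- system.file("extdata", paste0("layout_", system, ".tsv"),
                      package = "dicmflex", mustWork = TRUE)
  load_layout(path)
}

#' The ranked subnetwork configuration used for age-related features
#'
#' Twelve lobar subnetworks, each defined by a topography (one lobe or a
#' lobe pair), a hemisphere scope, a coupling estimator and a frequency
#' code. Each contributes one mean-subgraph-strength (MSS) feature; the ten
#' rows flagged `has_FO` also contribute a fractional-occupancy (FO)
#' feature, for 22 features in total. Band subscripts of the source ranking
#' that do not match the 8-band filterbank are mapped to the nearest bands
#' (beta -> beta2, gamma1/gamma2 -> gamma); the mapping is fixed here.
#'
#' @return Data frame of 12 rows with columns `row`, `lobe1`, `lobe2`,
#'   `hemi1`, `scope` (`cross`, `within`, `both`), `estimator`, `est_id`,
#'   `code`, `band_label`, `has_FO`.
#' @export
#' @examples
#' spec <- load_table1_spec()
#' nrow(spec)        # 12
#' sum(spec$has_FO)  # 10
load_table1_spec <- function() {
  et <- estimator_table()
  row <- function(lobe1, lobe2, hemi1, scope, est, code, label, has_FO) {
    data.frame(lobe1 = lobe1, lobe2 = lobe2, hemi1 = hemi1, scope = scope,
               estimator = est, est_id = et$id[et$name == est],
               code = code, band_label = label, has_FO = has_FO,
               stringsAsFactors = FALSE)
  }
  spec <- rbind(
    row("frontal", "frontal", NA, "cross", "aec", within_code("delta"),
        "delta envelope", TRUE),
    row("frontal", "temporal", NA, "both", "pac", cross_code("theta", "gamma"),
        "theta phase -> gamma amplitude", TRUE),
    row("frontal", "parietal", NA, "both", "dste", cross_code("theta", "alpha2"),
        "theta -> alpha2", TRUE),
    row("parieto-occipital", "parieto-occipital", NA, "cross", "iplv",
        within_code("alpha1"), "alpha1 phase", TRUE),
    row("frontal", "frontal", NA, "within", "iplv", within_code("theta"),
        "theta phase", TRUE),
    row("temporal", "frontal", "L", "cross", "pac", cross_code("delta", "beta2"),
        "delta phase -> beta amplitude", TRUE),
    row("temporal", "frontal", "R", "both", "pac", cross_code("delta", "gamma"),
        "delta phase -> gamma amplitude", FALSE),
    row("parietal", "parieto-occipital", "L", "both", "iplv",
        within_code("alpha1"), "alpha1 phase", TRUE),
    row("parieto-occipital", "parieto-occipital", NA, "cross", "aec",
        within_code("beta2"), "beta envelope", TRUE),
    row("temporal", "parieto-occipital", "R", "both", "iplv",
        within_code("gamma"), "gamma phase", TRUE),
    row("temporal", "temporal", NA, "cross", "aec", within_code("beta2"),
        "beta envelope", TRUE),
    row("occipital", "occipital", NA, "cross", "pac",
        cross_code("alpha2", "gamma"), "alpha2 phase -> gamma amplitude",
        FALSE)
  )
  spec <- cbind(row = seq_len(nrow(spec)), spec)
  stopifnot(nrow(spec) == 12L, sum(spec$has_FO) == 10L)
  spec
}
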