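SCHEMA_VERSION <- "quadcell-1"

check_schema <- function(attrs, path) {
  ver <- attrs$schema_version
  if (is.null(ver)) {
    stop("file ", path, " carries no schema_version attribute; not a ",
         "quadcell file or written by an incompatible version",
         call. = FALSE)
  }
  major <- sub("-[0-9]+$", "", SCHEMA_VERSION)
  if (!startsWith(as.character(ver), major)) {
    stop("file ", path, " has schema '", ver, "'; this reader understands '",
         SCHEMA_VERSION, "'", call. = FALSE)
  }
  invisible(TRUE)
}

h5_attrs <- function(fid, values) {
  for (nm in names(values)) {
    v <- values[[nm]]
    if (is.null(v) || length(v) == 0 || all(is.na(v))) next
    rhdf5::h5writeAttribute(v, fid, nm)
  }
}

#' Write / read a multimodal recording (HDF5)
#'
#' Lossless round trip of a `quadcell_recording`: optical and potential
#' trace matrices (pixels x samples), pixel ids, the stimulation train with
#' its capture pattern, the array geometry and provenance metadata. Layout:
#' `/optical/traces`, `/optical/pixel_id`, `/potential/traces`,
#' `/potential/pixel_id`, `/stim/onsets_ms`, `/stim/captured`, with file
#' attributes `schema_version`, `sampling_rate_hz`, `rows`, `cols`,
#' `pitch_um`, `fov_mm`, `seed`, `preset` and the protocol fields.
#'
#' @param recording A `quadcell_recording`.
#' @param path Output HDF5 path (overwritten when `overwrite = TRUE`).
#' @param overwrite Replace an existing file (default TRUE).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `quadcell_recording`.
#' @export
write_recording <- function(recording, path, overwrite = TRUE) {
  stopifnot(inherits(recording, "quadcell_recording"))
  if (file.exists(path)) {
    if (!overwrite) stop("file exists: ", path, call. = FALSE)
    file.remove(path)
  }
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5createGroup(fid, "optical")
  rhdf5::h5createGroup(fid, "potential")
  rhdf5::h5createGroup(fid, "stim")
  if (nrow(recording$optical_traces) > 0) {
    rhdf5::h5write(recording$optical_traces, fid, "optical/traces")
    rhdf5::h5write(as.integer(recording$optical_pixels), fid,
                   "optical/pixel_id")
  }
  if (nrow(recording$potential_traces) > 0) {
    rhdf5::h5write(recording$potential_traces, fid, "potential/traces")
    rhdf5::h5write(as.integer(recording$potential_pixels), fid,
                   "potential/pixel_id")
  }
  rhdf5::h5write(length(recording$times_ms), fid, "n_samples")
  rhdf5::h5write(as.numeric(recording$train$onsets_ms), fid, "stim/onsets_ms")
  rhdf5::h5write(as.integer(recording$train$captured %||%
                              rep(1L, length(recording$train$onsets_ms))),
                 fid, "stim/captured")
  pr <- recording$protocol
  g <- recording$geometry
  h5_attrs(fid, list(
    schema_version = SCHEMA_VERSION,
    sampling_rate_hz = recording$sampling_rate_hz,
    rows = g$rows, cols = g$cols, pitch_um = g$pitch_um, fov_mm = g$fov_mm,
    photodiode_sites_per_pixel = g$photodiode_sites_per_pixel,
    seed = recording$meta$seed %||% NA_integer_,
    preset = as.character(recording$meta$preset %||% NA_character_),
    amplitude_uA = pr$amplitude_uA, pulse_width_ms = pr$pulse_width_ms,
    frequency_hz = pr$frequency_hz, n_pulses = pr$n_pulses,
    start_ms = pr$start_ms))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  contents <- rhdf5::h5ls(path)
  at <- rhdf5::h5readAttributes(path, "/")
  check_schema(at, path)
  if (!any(contents$group == "/" & contents$name == "stim")) {
    stop("file ", path, " lacks the /stim group: incompatible or truncated ",
         "recording layout", call. = FALSE)
  }
  at <- lapply(at, as.vector)
  n_samp <- as.integer(rhdf5::h5read(path, "n_samples"))
  has <- function(grp, nm) any(contents$group == grp & contents$name == nm)
  read_modality <- function(grp) {
    if (has(paste0("/", grp), "traces")) {
      list(traces = matrix(rhdf5::h5read(path, paste0(grp, "/traces")),
                           ncol = n_samp),
           ids = as.integer(rhdf5::h5read(path, paste0(grp, "/pixel_id"))))
    } else {
      list(traces = matrix(0, nrow = 0, ncol = n_samp), ids = integer(0))
    }
  }
  opt <- read_modality("optical")
  pot <- read_modality("potential")
  onsets <- as.numeric(rhdf5::h5read(path, "stim/onsets_ms"))
  captured <- as.logical(rhdf5::h5read(path, "stim/captured"))
  geometry <- array_geometry(
    rows = at$rows, cols = at$cols, pitch_um = at$pitch_um,
    photodiode_sites_per_pixel = at$photodiode_sites_per_pixel,
    fov_mm = at$fov_mm)
  protocol <- stim_protocol(
    amplitude_uA = at$amplitude_uA, pulse_width_ms = at$pulse_width_ms,
    frequency_hz = at$frequency_hz, n_pulses = at$n_pulses,
    start_ms = at$start_ms)
  train <- stim_train(onsets, protocol = protocol)
  train$captured <- captured
  sr <- as.numeric(at$sampling_rate_hz)
  structure(
    list(geometry = geometry, protocol = protocol, train = train,
         optical_traces = opt$traces, optical_pixels = opt$ids,
         potential_traces = pot$traces, potential_pixels = pot$ids,
         sampling_rate_hz = sr,
         times_ms = (seq_len(n_samp) - 1) * 1000 / sr,
         meta = list(seed = at$seed, preset = at$preset)),
    class = "quadcell_recording")
}

#' Write / read a frame series (HDF5)
#'
#' Layout: `/frames` (T x rows x cols), `/timestamps_h`, attributes
#' `modality`, `schema_version` and the geometry fields.
#'
#' @param series A `quadcell_frame_series`.
#' @param path HDF5 path.
#' @param overwrite Replace an existing file (default TRUE).
#' @return `write_frame_series()` returns `path` invisibly;
#'   `read_frame_series()` the series.
#' @export
write_frame_series <- function(series, path, overwrite = TRUE) {
  stopifnot(inherits(series, "quadcell_frame_series"))
  if (file.exists(path)) {
    if (!overwrite) stop("file exists: ", path, call. = FALSE)
    file.remove(path)
  }
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5write(series$frames, fid, "frames")
  rhdf5::h5write(series$timestamps_h, fid, "timestamps_h")
  g <- series$geometry
  h5_attrs(fid, list(
    schema_version = SCHEMA_VERSION, modality = series$modality,
    rows = g$rows, cols = g$cols, pitch_um = g$pitch_um, fov_mm = g$fov_mm,
    photodiode_sites_per_pixel = g$photodiode_sites_per_pixel))
  invisible(path)
}

#' @rdname write_frame_series
#' @export
read_frame_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  check_schema(at, path)
  at <- lapply(at, as.vector)
  frames <- rhdf5::h5read(path, "frames")
  ts <- as.numeric(rhdf5::h5read(path, "timestamps_h"))
  geometry <- array_geometry(
    rows = at$rows, cols = at$cols, pitch_um = at$pitch_um,
    photodiode_sites_per_pixel = at$photodiode_sites_per_pixel,
    fov_mm = at$fov_mm)
  frame_series(frames, ts, modality = as.character(at$modality),
               geometry = geometry)
}

FEATURE_COLUMNS <- c("pixel_id", "modality", "beat_index", "stim_ms",
                     "feature", "value", "units")

#' Write / read a per-beat feature table (CSV)
#'
#' Fixed column order (`pixel_id, modality, beat_index, stim_ms, feature,
#' value, units`), rows sorted by (pixel, beat), numeric values at full
#' precision. An empty record set yields a header-only file.
#'
#' @param records A feature tibble as produced by [extract_features()].
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the tibble.
#' @export
write_feature_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(FEATURE_COLUMNS, names(records))
  if (nrow(records) == 0 && length(missing_cols) > 0) {
    records <- tibble::as_tibble(
      stats::setNames(rep(list(logical(0)), length(FEATURE_COLUMNS)),
                      FEATURE_COLUMNS))
    missing_cols <- character(0)
  }
  if (length(missing_cols) > 0) {
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- dplyr::arrange(records[FEATURE_COLUMNS], pixel_id, beat_index)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      pixel_id = readr::col_integer(), modality = readr::col_character(),
      beat_index = readr::col_integer(), stim_ms = readr::col_double(),
      feature = readr::col_character(), value = readr::col_double(),
      units = readr::col_character()))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed feature table ", path, "; offending rows: ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  out
}

RUN_CONFIG_KEYS <- c("preset", "protocol", "geometry", "extraction", "seed",
                     "out")

#' Read a run configuration (YAML or JSON)
#'
#' Schema-validated configuration for scripted runs: a preset name,
#' optional protocol / geometry overrides, extraction thresholds, a seed
#' and output paths. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated list of class `quadcell_config` with constructed
#'   `protocol` ([stim_protocol()]), `geometry` ([array_geometry()]) and
#'   `extraction` ([feature_config()]) entries where given.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- raw
  if (!is.null(raw$protocol)) out$protocol <- do.call(stim_protocol,
                                                      as.list(raw$protocol))
  if (!is.null(raw$geometry)) out$geometry <- do.call(array_geometry,
                                                      as.list(raw$geometry))
  if (!is.null(raw$extraction)) out$extraction <- do.call(feature_config,
                                                          as.list(raw$extraction))
  if (!is.null(raw$seed)) out$seed <- as.integer(raw$seed)
  structure(out, class = "quadcell_config")
}
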