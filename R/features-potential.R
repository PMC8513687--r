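#' Extract per-beat extracellular potential features
#'
#' For every stimulation pulse, blanks the stimulation-artefact window (two
#' pulse phases plus a guard), detects the evoked spike as the largest
#' absolute excursion in the remainder of the pulse's window, and measures:
#' T_ap (spike extremum time minus pulse onset), spike peak-to-peak
#' amplitude, and FPD (spike extremum to the T-wave apex, the largest
#' smooth extremum after a refractory gap). Pulses with no supra-threshold
#' spike yield no row.
#'
#' @param trace A potential [pixel_trace()] (values in uV).
#' @param stim_train A [stim_train()].
#' @param config A [feature_config()]; the spike threshold is
#'   `spike_mad_mult` times the median absolute deviation of the blanked
#'   trace.
#' @return A tibble with columns `pixel_id`, `beat_index`, `stim_ms`,
#'   `t_ap_ms`, `spike_amplitude_uv`, `fpd_ms`.
#' @examples
#' tr <- synth_extracellular_trace(ep_params(),
#'   generate_stim_train(stim_protocol(n_pulses = 1)))
#' extract_potential_features(tr, stim_train(0))
#' @export
extract_potential_features <- function(trace, stim_train,
                                       config = feature_config()) {
  if (trace_modality(trace) != "potential") {
    stop("extract_potential_features requires a potential trace",
         call. = FALSE)
  }
  onsets <- stim_train$onsets_ms
  if (length(onsets) == 0) stop("empty stimulation train", call. = FALSE)
  sr <- trace_sampling_rate(trace)
  dt <- 1000 / sr
  t <- trace$time_ms
  v <- trace$value
  period <- stim_train$period_ms
  if (is.na(period)) period <- diff(range(t))
  width <- stim_train$protocol$pulse_width_ms %||% config$pulse_width_ms
  blank_ms <- 2 * width + config$blank_guard_ms

  blanked <- rep(FALSE, length(v))
  for (o in onsets) blanked[t >= o & t <= o + blank_ms] <- TRUE
  vv <- v
  vv[blanked] <- 0
  thr <- config$spike_mad_mult * stats::mad(vv[!blanked])

  sm <- smooth_and_differentiate(trace, 15)$smoothed$value

  empty <- tibble::tibble(
    pixel_id = integer(), beat_index = integer(), stim_ms = numeric(),
    t_ap_ms = numeric(), spike_amplitude_uv = numeric(), fpd_ms = numeric())
  rows <- list()
  for (i in seq_along(onsets)) {
    win_end <- if (i < length(onsets)) onsets[i + 1] else onsets[i] + period
    win <- which(t > onsets[i] & t <= win_end & !blanked)
    if (length(win) == 0) next
    sp <- win[which.max(abs(vv[win]))]
    if (abs(vv[sp]) <= thr || abs(vv[sp]) == 0) next

    near <- which(abs(t - t[sp]) <= 5)
    amp <- diff(range(v[near]))

    tw <- win[t[win] >= t[sp] + config$twave_gap_ms]
    if (length(tw) == 0) next
    apex <- tw[which.max(abs(sm[tw]))]
    fpd <- t[apex] - t[sp]

    rows[[length(rows) + 1L]] <- tibble::tibble(
      pixel_id = attr(trace, "pixel_id") %||% 1L,
      beat_index = NA_integer_, stim_ms = onsets[i],
      t_ap_ms = t[sp] - onsets[i], spike_amplitude_uv = amp, fpd_ms = fpd)
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$beat_index <- seq_len(nrow(out))
  out
}

#' Extract features from every trace of a recording
#'
#' Convenience wrapper running [extract_optical_features()] and
#' [extract_potential_features()] over all traces of a recording and
#' returning one tidy table.
#'
#' @param recording A `quadcell_recording`.
#' @param config A [feature_config()].
#' @param pixels Optional pixel ids to restrict to.
#' @return A tibble in long format with columns `pixel_id`, `modality`,
#'   `beat_index`, `stim_ms`, `feature`, `value`, `units`.
#' @export
extract_features <- function(recording, config = feature_config(),
                             pixels = NULL) {
  train <- recording$train
  do_one <- function(id, modality) {
    tr <- get_trace(recording, id, modality)
    wide <- if (modality == "optical") {
      extract_optical_features(tr, train, config)
    } else {
      extract_potential_features(tr, train, config)
    }
    if (nrow(wide) == 0) return(NULL)
    long <- tidyr::pivot_longer(wide,
      cols = -c(pixel_id, beat_index, stim_ms),
      names_to = "feature", values_to = "value")
    long$modality <- modality
    long$units <- ifelse(grepl("_ms$", long$feature), "ms",
                         ifelse(grepl("_uv$", long$feature), "uV", "a.u."))
    long
  }
  opt <- recording$optical_pixels
  pot <- recording$potential_pixels
  if (!is.null(pixels)) {
    opt <- intersect(opt, pixels)
    pot <- intersect(pot, pixels)
  }
  out <- dplyr::bind_rows(
    purrr::map(opt, do_one, modality = "optical"),
    purrr::map(pot, do_one, modality = "potential"))
  if (nrow(out) == 0) return(out)
  dplyr::select(dplyr::arrange(out, pixel_id, beat_index),
                pixel_id, modality, beat_index, stim_ms, feature, value, units)
}
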