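#' Deterministic refractory capture rule
#'
#' A pulse captures (evokes a beat) iff the time elapsed since the last
#' captured pulse is at least the absolute refractory period (closed
#' interval); the first pulse always captures.
#'
#' @param onsets_ms Pulse onset times, ms (increasing).
#' @param arp_ms Absolute refractory period, ms.
#' @return Logical vector, one element per pulse.
#' @examples
#' refractory_captures(seq(0, 19) * 111.1, 222) # alternating at 9 Hz
#' @export
refractory_captures <- function(onsets_ms, arp_ms) {
  stopifnot(arp_ms > 0)
  n <- length(onsets_ms)
  cap <- logical(n)
  if (n == 0) return(cap)
  cap[1] <- TRUE
  last <- onsets_ms[1]
  eps <- 1e-9 * max(1, arp_ms)
  for (i in seq_len(n)[-1]) {
    if (onsets_ms[i] - last >= arp_ms - eps) {
      cap[i] <- TRUE
      last <- onsets_ms[i]
    }
  }
  cap
}

#' Synthesize a paced multimodal recording
#'
#' Simulates pacing of a cardiomyocyte monolayer on the array. Pulse capture
#' follows the deterministic refractory rule ([refractory_captures()]). Each
#' captured pulse spawns, at every requested optical pixel, a contraction
#' transient whose onset is
#' `stimulus + mech_onset_intercept_ms + mech_onset_radial_slope_ms_per_um * r`
#' (`r` = pixel distance from the array centre, um) plus a per-beat,
#' per-pixel Gaussian timing jitter of sd `beat$jitter_sd_ms`; and, at every
#' requested potential pixel, an extracellular complex whose conduction
#' delay grows by `r / ep_conduction_um_per_ms`.
#'
#' @param params A [monolayer_params()] object.
#' @param protocol A [stim_protocol()].
#' @param duration_ms Recording duration; must cover the pulse train.
#'   Default: last pulse plus one full transient.
#' @param sampling_rate_hz Sampling rate, Hz (default 1000).
#' @param geometry An [array_geometry()].
#' @param optical_pixels `"centre"` (default, the pixel nearest the array
#'   centre), `"all"`, or an integer vector of pixel ids.
#' @param potential_pixels Integer vector of pixel ids recording
#'   extracellular potential (default none).
#'
#' @return A `quadcell_recording`: a list with `geometry`, `protocol`,
#'   `train` (with a `captured` element), matrices `optical_traces` /
#'   `potential_traces` (pixels x samples), the corresponding pixel-id
#'   vectors, `sampling_rate_hz`, `times_ms` and `meta`.
#' @examples
#' p <- quadcell_preset("PACED_BEAT")
#' rec <- synth_paced_recording(p$monolayer, p$protocol)
#' @export
synth_paced_recording <- function(params, protocol, duration_ms = NULL,
                                  sampling_rate_hz = 1000,
                                  geometry = array_geometry(),
                                  optical_pixels = "centre",
                                  potential_pixels = integer(0)) {
  stopifnot(inherits(params, "quadcell_monolayer_params"),
            inherits(protocol, "quadcell_protocol"),
            sampling_rate_hz >= 200)
  train <- generate_stim_train(protocol)
  tail_ms <- params$beat$t_d_ms * 1.2 + abs(params$mech_onset_intercept_ms)
  if (is.null(duration_ms)) duration_ms <- max(train$onsets_ms) + tail_ms
  if (duration_ms < max(train$onsets_ms)) {
    stop("duration_ms too short: recording must cover the pulse train",
         call. = FALSE)
  }

  centers <- pixel_centers(geometry)
  opt_ids <- resolve_pixels(optical_pixels, centers)
  pot_ids <- resolve_pixels(potential_pixels, centers)

  captured <- refractory_captures(train$onsets_ms, params$arp_ms)
  cap_onsets <- train$onsets_ms[captured]
  n_cap <- length(cap_onsets)

  dt <- 1000 / sampling_rate_hz
  t <- seq(0, duration_ms, by = dt)
  shape <- if (params$beat$amplitude_au > 0) {
    solve_beat_shape(params$beat$ct_prime_pk_ms, params$beat$ct_pk_ms,
                     params$beat$rx_prime_pk_ms, params$beat$t_d_ms)
  }
  support_ms <- if (is.null(shape)) 0 else params$beat$ct_pk_ms + shape$D

  # one jitter draw per (pixel, captured beat), all derived from the seed
  jitter <- withr::with_seed(params$seed, {
    matrix(stats::rnorm(length(opt_ids) * n_cap,
                        sd = params$beat$jitter_sd_ms),
           nrow = length(opt_ids))
  })

  optical <- matrix(0, nrow = length(opt_ids), ncol = length(t))
  for (k in seq_along(opt_ids)) {
    r <- centers$r_um[centers$pixel_id == opt_ids[k]]
    base_delay <- params$mech_onset_intercept_ms +
      params$mech_onset_radial_slope_ms_per_um * r
    row <- numeric(length(t))
    for (j in seq_len(n_cap)) {
      onset <- cap_onsets[j] + base_delay + jitter[k, j]
      i0 <- max(1L, floor(onset / dt) + 1L)
      i1 <- min(length(t), ceiling((onset + support_ms) / dt) + 1L)
      if (i1 >= i0) {
        idx <- i0:i1
        row[idx] <- row[idx] + beat_waveform(t[idx] - onset, params$beat, shape)
      }
    }
    optical[k, ] <- row
  }

  potential <- matrix(0, nrow = length(pot_ids), ncol = length(t))
  for (k in seq_along(pot_ids)) {
    r <- centers$r_um[centers$pixel_id == pot_ids[k]]
    ep_k <- params$ep
    ep_k$t_ap_ms <- ep_k$t_ap_ms + r / params$ep_conduction_um_per_ms
    tr <- synth_extracellular_trace(
      ep_k, train, sampling_rate_hz = sampling_rate_hz,
      duration_ms = duration_ms, seed = params$seed + k,
      pulse_width_ms = protocol$pulse_width_ms, captured = captured,
      pixel_id = pot_ids[k])
    potential[k, ] <- tr$value[seq_along(t)]
  }

  train$captured <- captured
  structure(
    list(geometry = geometry, protocol = protocol, train = train,
         optical_traces = optical, optical_pixels = opt_ids,
         potential_traces = potential, potential_pixels = pot_ids,
         sampling_rate_hz = sampling_rate_hz, times_ms = t,
         meta = list(seed = params$seed, preset = NA_character_,
                     arp_ms = params$arp_ms,
                     mech_onset_intercept_ms = params$mech_onset_intercept_ms,
                     mech_onset_radial_slope_ms_per_um =
                       params$mech_onset_radial_slope_ms_per_um)),
    class = "quadcell_recording"
  )
}

resolve_pixels <- function(spec, centers) {
  if (is.character(spec)) {
    if (identical(spec, "all")) return(centers$pixel_id)
    if (identical(spec, "centre") || identical(spec, "center")) {
      return(centers$pixel_id[which.min(centers$r_um)])
    }
    stop("optical_pixels must be 'centre', 'all' or pixel ids", call. = FALSE)
  }
  if (length(spec) == 0) return(integer(0))
  ids <- as.integer(spec)
  if (!all(ids %in% centers$pixel_id)) {
    stop("pixel ids outside the array geometry", call. = FALSE)
  }
  ids
}

#' @export
print.quadcell_recording <- function(x, ...) {
  cat(sprintf(paste0("<quadcell_recording> %d optical + %d potential traces, ",
                     "%d samples @ %g Hz, %d pulses (%d captured)\n"),
              nrow(x$optical_traces), nrow(x$potential_traces),
              length(x$times_ms), x$sampling_rate_hz,
              length(x$train$onsets_ms), sum(x$train$captured)))
  invisible(x)
}

#' Extract one pixel trace from a recording
#'
#' @param recording A `quadcell_recording`.
#' @param pixel_id Pixel id present in the recording.
#' @param modality `"optical"` or `"potential"`.
#' @return A [pixel_trace()].
#' @export
get_trace <- function(recording, pixel_id,
                      modality = c("optical", "potential")) {
  modality <- match.arg(modality)
  ids <- if (modality == "optical") recording$optical_pixels else
    recording$potential_pixels
  k <- match(pixel_id, ids)
  if (is.na(k)) stop("pixel ", pixel_id, " has no ", modality, " trace",
                     call. = FALSE)
  m <- if (modality == "optical") recording$optical_traces else
    recording$potential_traces
  pixel_trace(m[k, ], sampling_rate_hz = recording$sampling_rate_hz,
              t0_ms = recording$times_ms[1], pixel_id = pixel_id,
              modality = modality)
}

#' Tidy a recording into a long tibble
#'
#' One row per (pixel, modality, sample). Intended for small recordings and
#' plotting; full-array recordings are large in long form.
#'
#' @param x A `quadcell_recording`.
#' @param ... Unused.
#' @return A tibble with columns `pixel_id`, `modality`, `time_ms`, `value`.
#' @exportS3Method generics::tidy
tidy.quadcell_recording <- function(x, ...) {
  one <- function(m, ids, lab) {
    if (length(ids) == 0) return(NULL)
    tibble::tibble(
      pixel_id = rep(ids, each = ncol(m)),
      modality = lab,
      time_ms = rep(x$times_ms, times = length(ids)),
      value = as.vector(t(m)))
  }
  dplyr::bind_rows(one(x$optical_traces, x$optical_pixels, "optical"),
                   one(x$potential_traces, x$potential_pixels, "potential"))
}
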