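#' Synthesize an extracellular potential trace
#'
#' Builds a field-potential trace for a stimulation train: each captured
#' pulse contributes a charge-balanced biphasic rectangular stimulation
#' artefact at its onset, a sharp biphasic evoked spike whose dominant
#' (negative) extremum lies exactly `t_ap_ms` after the onset with
#' peak-to-peak amplitude `spike_amp_uv`, and a smooth unipolar T-wave whose
#' apex lies exactly `fpd_ms` after the spike extremum. Gaussian noise of sd
#' `noise_sd_uv` is added reproducibly from `seed`.
#'
#' @param ep An [ep_params()] object.
#' @param train A [stim_train()]; an empty train yields pure noise.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param duration_ms Trace duration; default covers the train plus one
#'   complete complex.
#' @param seed Integer seed for the noise.
#' @param pulse_width_ms Artefact phase width; taken from the train's
#'   protocol when present, else 1.2 ms.
#' @param captured Logical vector, one per pulse: which pulses evoked a
#'   response. Non-captured pulses contribute only their artefact.
#' @param pixel_id Pixel id stored in the trace metadata.
#'
#' @return A [pixel_trace()] with modality `"potential"`, values in uV.
#' @examples
#' tr <- synth_extracellular_trace(ep_params(fpd_ms = 238.6),
#'                                 generate_stim_train(stim_protocol(n_pulses = 1)))
#' @export
synth_extracellular_trace <- function(ep, train,
                                      sampling_rate_hz = 1000,
                                      duration_ms = NULL, seed = 1L,
                                      pulse_width_ms = NULL,
                                      captured = NULL, pixel_id = 1L) {
  stopifnot(inherits(ep, "quadcell_ep_params"), inherits(train, "quadcell_train"))
  onsets <- train$onsets_ms
  if (is.null(pulse_width_ms)) {
    pulse_width_ms <- train$protocol$pulse_width_ms %||% 1.2
  }
  if (is.null(duration_ms)) {
    tail_ms <- ep$t_ap_ms + ep$fpd_ms + 2 * ep$twave_width_ms
    duration_ms <- if (length(onsets)) max(onsets) + tail_ms else 1000
  }
  if (is.null(captured)) captured <- rep(TRUE, length(onsets))
  stopifnot(length(captured) == length(onsets))

  dt <- 1000 / sampling_rate_hz
  t <- seq(0, duration_ms, by = dt)
  v <- numeric(length(t))
  for (i in seq_along(onsets)) {
    v <- v + ep_complex(t, onsets[i], ep, pulse_width_ms,
                        with_response = captured[i])
  }
  if (ep$noise_sd_uv > 0) {
    v <- v + withr::with_seed(seed,
      stats::rnorm(length(t), sd = ep$noise_sd_uv))
  }
  pixel_trace(v, sampling_rate_hz = sampling_rate_hz, t0_ms = 0,
              pixel_id = pixel_id, modality = "potential")
}

# one stimulation complex evaluated on the time grid t (ms)
ep_complex <- function(t, onset, ep, pulse_width_ms, with_response = TRUE) {
  v <- numeric(length(t))
  # biphasic rectangular artefact: +A then -A, one phase width each
  v[t >= onset & t < onset + pulse_width_ms] <- ep$artefact_amp_uv
  v[t >= onset + pulse_width_ms & t < onset + 2 * pulse_width_ms] <-
    -ep$artefact_amp_uv
  if (!with_response) return(v)

  # biphasic spike: dominant negative lobe at onset + t_ap, smaller positive
  # rebound; rescaled so the realized sampled peak-to-peak equals spike_amp_uv
  t_sp <- onset + ep$t_ap_ms
  sg <- 1.2 # lobe width, ms
  shape <- -0.7 * exp(-(t - t_sp)^2 / (2 * sg^2)) +
    0.35 * exp(-(t - t_sp - 3 * sg)^2 / (2 * sg^2))
  near <- abs(t - t_sp) < 10 * sg
  ptp <- if (any(near)) diff(range(shape[near])) else 1
  v <- v + shape * ep$spike_amp_uv / ptp

  # smooth unipolar T-wave, apex at the spike extremum + FPD
  t_tw <- t_sp + ep$fpd_ms
  sd_tw <- ep$twave_width_ms / 2.355 # width parameter ~ FWHM
  v + 0.25 * ep$spike_amp_uv * exp(-(t - t_tw)^2 / (2 * sd_tw^2))
}
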