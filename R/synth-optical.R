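#' @keywords internal
#'
#' Solve the beat waveform shape for a set of requested fiducials.
#'
#' The transient is built from two regularized-incomplete-beta segments:
#' a rise `A * pbeta(t / ct, a1, b1)` on `[0, ct]` whose derivative (a beta
#' density) peaks exactly at CT'_PKS, and a decay
#' `A * pbeta(1 - (t - ct) / D, a2, b2)` on `[ct, ct + D]` whose steepest
#' descent lands on RX'_PKS and whose 10%-of-peak crossing lands on T_d.
#' Both segments meet the peak with zero slope (C1 join) and return to
#' baseline with zero slope, so realized fiducials equal the requested ones
#' up to sampling. `a + b` is fixed at 6 for both segments; the decay's
#' shape parameter and support are solved numerically (verify-and-adjust).
solve_beat_shape <- function(ct_prime_pk_ms, ct_pk_ms, rx_prime_pk_ms,
                             t_d_ms) {
  m1 <- ct_prime_pk_ms / ct_pk_ms          # mode of the rise density
  a1 <- 1 + 4 * m1                          # a1 + b1 = 6 => mode = (a1-1)/4
  b1 <- 6 - a1

  # decay: find a2 such that the 10% crossing hits t_d, with the steepest
  # descent pinned at rx' by D = (rx' - ct) / (1 - mode2)
  drop_ms <- rx_prime_pk_ms - ct_pk_ms
  td_of <- function(a2) {
    mode2 <- (a2 - 1) / 4
    D <- drop_ms / (1 - mode2)
    ct_pk_ms + D * (1 - stats::qbeta(0.1, a2, 6 - a2))
  }
  lo <- 1 + 1e-6
  hi <- 5 - 1e-6
  f <- function(a2) td_of(a2) - t_d_ms
  if (f(lo) > 0 || f(hi) < 0) {
    stop("requested fiducials are outside the representable beat family ",
         "(T_d incompatible with CT_PKS and RX'_PKS)", call. = FALSE)
  }
  a2 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  mode2 <- (a2 - 1) / 4
  D <- drop_ms / (1 - mode2)
  list(a1 = a1, b1 = b1, a2 = a2, b2 = 6 - a2, D = D)
}

# evaluate the beat waveform at times t_ms (ms after the beat onset)
beat_waveform <- function(t_ms, beat, shape = NULL) {
  if (beat$amplitude_au == 0) return(numeric(length(t_ms)))
  if (is.null(shape)) {
    shape <- solve_beat_shape(beat$ct_prime_pk_ms, beat$ct_pk_ms,
                              beat$rx_prime_pk_ms, beat$t_d_ms)
  }
  y <- numeric(length(t_ms))
  ct <- beat$ct_pk_ms
  rise <- t_ms > 0 & t_ms <= ct
  y[rise] <- stats::pbeta(t_ms[rise] / ct, shape$a1, shape$b1)
  dec <- t_ms > ct & t_ms < ct + shape$D
  y[dec] <- stats::pbeta(1 - (t_ms[dec] - ct) / shape$D, shape$a2, shape$b2)
  beat$amplitude_au * y
}

#' Synthesize a single optical contraction transient
#'
#' Generates a noiseless single-beat light-intensity trace whose realized
#' fiducials — the maximum of the first derivative during the rise
#' (CT'_PKS), the global maximum (CT_PKS), the most negative derivative
#' during the decay (RX'_PKS) and the 10%-of-peak decay crossing (T_d) —
#' equal the requested [beat_params()] within two sample periods. The trace
#' is zero before the stimulus and returns smoothly to baseline.
#'
#' @param beat A [beat_params()] object (jitter is ignored here; see
#'   [synth_paced_recording()] for jittered trains).
#' @param sampling_rate_hz Sampling rate, Hz (>= 200).
#' @param stim_ms Stimulus onset within the trace, ms.
#' @param duration_ms Total trace duration, ms; default covers the full
#'   transient plus 10%.
#' @param pixel_id Pixel id recorded in the trace metadata.
#'
#' @return A [pixel_trace()] with modality `"optical"`.
#' @examples
#' b <- quadcell_preset("PACED_BEAT")$beat
#' tr <- synth_optical_beat(b, sampling_rate_hz = 1000)
#' tr$time_ms[which.max(tr$value)] # ~190.3
#' @export
synth_optical_beat <- function(beat, sampling_rate_hz = 1000, stim_ms = 0,
                               duration_ms = NULL, pixel_id = 1L) {
  stopifnot(inherits(beat, "quadcell_beat_params"), sampling_rate_hz >= 200)
  if (is.null(duration_ms)) duration_ms <- stim_ms + beat$t_d_ms * 1.1
  dt <- 1000 / sampling_rate_hz
  t <- seq(0, duration_ms, by = dt)
  values <- beat_waveform(t - stim_ms, beat)
  pixel_trace(values, sampling_rate_hz = sampling_rate_hz, t0_ms = 0,
              pixel_id = pixel_id, modality = "optical")
}
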