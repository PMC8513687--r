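#' Biphasic stimulation protocol
#'
#' A charge-balanced biphasic current pulse train description. Each pulse has
#' a positive and a negative phase of equal width and amplitude, so the
#' injected charge per phase (`amplitude_uA * pulse_width_ms`) cancels.
#'
#' @param amplitude_uA Current amplitude per phase, microamperes (> 0).
#' @param pulse_width_ms Width of each phase, milliseconds (> 0).
#' @param frequency_hz Pulse repetition rate, Hz (> 0). The implied period
#'   `1000 / frequency_hz` must exceed the pulse width.
#' @param n_pulses Number of pulses in the train.
#' @param start_ms Onset of the first pulse, ms.
#'
#' @return An object of class `quadcell_protocol`.
#' @examples
#' stim_protocol(amplitude_uA = 8, pulse_width_ms = 0.8, frequency_hz = 0.5,
#'               n_pulses = 10)
#' @export
stim_protocol <- function(amplitude_uA = 8, pulse_width_ms = 0.8,
                          frequency_hz = 0.5, n_pulses = 10L, start_ms = 0) {
  if (!is.numeric(amplitude_uA) || amplitude_uA <= 0) {
    stop("amplitude_uA must be > 0", call. = FALSE)
  }
  if (!is.numeric(pulse_width_ms) || pulse_width_ms <= 0) {
    stop("pulse_width_ms must be > 0", call. = FALSE)
  }
  if (!is.numeric(frequency_hz) || frequency_hz <= 0) {
    stop("frequency_hz must be > 0", call. = FALSE)
  }
  if (1000 / frequency_hz <= pulse_width_ms) {
    stop("inter-pulse period 1000/frequency_hz must exceed pulse_width_ms",
         call. = FALSE)
  }
  n_pulses <- as.integer(n_pulses)
  stopifnot(n_pulses >= 1L, start_ms >= 0)
  structure(
    list(amplitude_uA = amplitude_uA, pulse_width_ms = pulse_width_ms,
         frequency_hz = frequency_hz, n_pulses = n_pulses,
         start_ms = start_ms, period_ms = 1000 / frequency_hz),
    class = "quadcell_protocol"
  )
}

#' @export
print.quadcell_protocol <- function(x, ...) {
  cat(sprintf("<quadcell_protocol> %g uA, %g ms/phase, %g Hz, %d pulses from %g ms\n",
              x$amplitude_uA, x$pulse_width_ms, x$frequency_hz, x$n_pulses,
              x$start_ms))
  invisible(x)
}

#' Realized pulse-onset schedule of a protocol
#'
#' Expands a [stim_protocol()] into the ordered pulse onset times it implies:
#' `n_pulses` onsets starting at `start_ms`, spaced by `1000 / frequency_hz`.
#'
#' @param protocol A [stim_protocol()].
#' @return A `quadcell_train` object: a list with `onsets_ms` (strictly
#'   increasing numeric vector), `period_ms` and the originating `protocol`.
#' @examples
#' generate_stim_train(stim_protocol(frequency_hz = 0.5, n_pulses = 10))$onsets_ms
#' @export
generate_stim_train <- function(protocol) {
  stopifnot(inherits(protocol, "quadcell_protocol"))
  onsets <- protocol$start_ms +
    (seq_len(protocol$n_pulses) - 1) * protocol$period_ms
  stim_train(onsets, protocol = protocol)
}

#' Construct a stimulation train from explicit onsets
#'
#' @param onsets_ms Strictly increasing pulse onset times, ms.
#' @param protocol Optional originating [stim_protocol()].
#' @return A `quadcell_train` object.
#' @export
stim_train <- function(onsets_ms, protocol = NULL) {
  onsets_ms <- as.numeric(onsets_ms)
  if (length(onsets_ms) > 1 && any(diff(onsets_ms) <= 0)) {
    stop("onsets_ms must be strictly increasing", call. = FALSE)
  }
  period <- if (length(onsets_ms) > 1) stats::median(diff(onsets_ms)) else
    if (!is.null(protocol)) protocol$period_ms else NA_real_
  structure(list(onsets_ms = onsets_ms, period_ms = period,
                 protocol = protocol),
            class = "quadcell_train")
}

#' @export
print.quadcell_train <- function(x, ...) {
  cat(sprintf("<quadcell_train> %d pulses, period %g ms, span [%g, %g] ms\n",
              length(x$onsets_ms), x$period_ms,
              if (length(x$onsets_ms)) min(x$onsets_ms) else NA,
              if (length(x$onsets_ms)) max(x$onsets_ms) else NA))
  invisible(x)
}

# TRUE when consecutive onset gaps agree within one sample period
train_is_periodic <- function(train, sampling_rate_hz) {
  if (length(train$onsets_ms) < 2) return(TRUE)
  d <- diff(train$onsets_ms)
  max(abs(d - stats::median(d))) <= 1000 / sampling_rate_hz
}
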