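#' Construct a pixel trace
#'
#' A uniformly sampled time series from one pixel of the array: optical light
#' intensity (arbitrary units) or extracellular potential (microvolts). The
#' trace is a tibble with columns `time_ms` and `value`, carrying the
#' sampling rate, pixel id and modality as attributes.
#'
#' @param values Numeric sample values (length >= 2, all finite).
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param t0_ms Time of the first sample, ms.
#' @param pixel_id Grid index of the source pixel.
#' @param modality `"optical"` or `"potential"`.
#'
#' @return A tibble of class `quadcell_trace`.
#' @examples
#' tr <- pixel_trace(sin(seq(0, 2 * pi, length.out = 100)),
#'                   sampling_rate_hz = 1000)
#' trace_sampling_rate(tr)
#' @export
pixel_trace <- function(values, sampling_rate_hz, t0_ms = 0, pixel_id = 1L,
                        modality = c("optical", "potential")) {
  modality <- match.arg(modality)
  values <- as.numeric(values)
  if (length(values) < 2) stop("trace must have length >= 2", call. = FALSE)
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  stopifnot(sampling_rate_hz > 0)
  out <- tibble::tibble(
    time_ms = t0_ms + (seq_along(values) - 1) * 1000 / sampling_rate_hz,
    value = values)
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  attr(out, "t0_ms") <- t0_ms
  attr(out, "pixel_id") <- as.integer(pixel_id)
  attr(out, "modality") <- modality
  class(out) <- c("quadcell_trace", class(out))
  out
}

#' @rdname pixel_trace
#' @param trace A `quadcell_trace`.
#' @export
trace_sampling_rate <- function(trace) {
  sr <- attr(trace, "sampling_rate_hz")
  if (is.null(sr)) sr <- 1000 / stats::median(diff(trace$time_ms))
  sr
}

#' @rdname pixel_trace
#' @export
trace_modality <- function(trace) {
  m <- attr(trace, "modality")
  if (is.null(m)) "optical" else m
}

# rebuild a trace with new values, preserving metadata
retrace <- function(trace, values) {
  pixel_trace(values, sampling_rate_hz = trace_sampling_rate(trace),
              t0_ms = trace$time_ms[1],
              pixel_id = attr(trace, "pixel_id") %||% 1L,
              modality = trace_modality(trace))
}

#' @export
print.quadcell_trace <- function(x, ...) {
  cat(sprintf("<quadcell_trace> %s, pixel %d, %d samples @ %g Hz\n",
              trace_modality(x), attr(x, "pixel_id") %||% 1L,
              nrow(x), trace_sampling_rate(x)))
  NextMethod()
}

#' Plot a pixel trace
#'
#' @param object A [pixel_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.quadcell_trace <- function(object, ...) {
  ylab <- if (trace_modality(object) == "optical") {
    "Δ light intensity (a.u.)"
  } else {
    "potential (µV)"
  }
  ggplot2::ggplot(object, ggplot2::aes(x = time_ms, y = value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = ylab) +
    ggplot2::theme_minimal()
}
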