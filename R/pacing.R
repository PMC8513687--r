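#' Stimulation capture rate from extracted features or a trace
#'
#' A pulse counts as captured iff the feature extractor attributes a beat
#' (optical) or a spike (potential) to it. Accepts either a feature table
#' from [extract_optical_features()] / [extract_potential_features()] or a
#' raw [pixel_trace()] (which is then extracted internally).
#'
#' @param x A per-beat feature tibble with a `stim_ms` column, or a
#'   [pixel_trace()].
#' @param stim_train A non-empty [stim_train()].
#' @param config A [feature_config()] (used when `x` is a trace).
#' @return A one-row tibble of class `quadcell_capture`: `frequency_hz`,
#'   `n_pulses`, `n_captured`, `capture_rate`.
#' @examples
#' p <- quadcell_preset("PACED_BEAT")
#' rec <- synth_paced_recording(p$monolayer, p$protocol)
#' detect_captures(get_trace(rec, rec$optical_pixels[1]), rec$train)
#' @export
detect_captures <- function(x, stim_train, config = feature_config()) {
  if (length(stim_train$onsets_ms) == 0) {
    stop("empty stimulation train", call. = FALSE)
  }
  feats <- if (inherits(x, "quadcell_trace")) {
    if (trace_modality(x) == "optical") {
      # peak attribution only: a capture needs an evoked peak, not a full
      # measurable cycle (high rates truncate the decay)
      attribute_beats(x, stim_train, config)
    } else {
      extract_potential_features(x, stim_train, config)
    }
  } else {
    x
  }
  if (!"stim_ms" %in% names(feats)) {
    stop("feature table must carry a stim_ms column", call. = FALSE)
  }
  n <- length(stim_train$onsets_ms)
  n_cap <- length(intersect(round(feats$stim_ms, 6),
                            round(stim_train$onsets_ms, 6)))
  freq <- if (!is.na(stim_train$period_ms)) 1000 / stim_train$period_ms
          else NA_real_
  out <- tibble::tibble(frequency_hz = freq, n_pulses = n,
                        n_captured = n_cap, capture_rate = n_cap / n)
  class(out) <- c("quadcell_capture", class(out))
  out
}

#' Deterministic refractory capture model
#'
#' Simulates the capture pattern of a periodic pulse train under the closed
#' refractory rule (a pulse captures iff at least `arp_ms` has elapsed since
#' the last captured pulse; the first pulse always captures) and reports the
#' capture fraction. The deterministic pattern is periodic with one capture
#' every `m = ceiling(arp_ms / period_ms)` pulses; for `n_pulses >= 20` the
#' asymptotic fraction `1 / m` implied by the simulated pattern is reported,
#' for shorter trains the finite-train fraction `captured / n_pulses`.
#'
#' @param arp_ms Absolute refractory period, ms.
#' @param period_ms Stimulation period, ms.
#' @param n_pulses Number of pulses simulated (default 20).
#' @return Capture fraction in (0, 1].
#' @examples
#' refractory_capture_model(222, 250) # 1.0 (4 Hz)
#' refractory_capture_model(222, 200) # 0.5 (5 Hz)
#' refractory_capture_model(222, 111) # 0.5 (9 Hz)
#' @export
refractory_capture_model <- function(arp_ms, period_ms, n_pulses = 20L) {
  stopifnot(arp_ms > 0, period_ms > 0, n_pulses >= 1)
  onsets <- (seq_len(n_pulses) - 1) * period_ms
  cap <- refractory_captures(onsets, arp_ms)
  idx <- which(cap)
  if (n_pulses >= 20L && length(idx) >= 2L) {
    m <- diff(idx)[1] # periodic inter-capture interval of the pattern
    1 / m
  } else {
    sum(cap) / n_pulses
  }
}

#' Interval from contraction peak to the next stimulus
#'
#' Pacing arithmetic: at stimulation frequency `frequency_hz`, the next
#' pulse arrives `1000 / frequency_hz - ct_pk_ms` after the contraction
#' peak. Negative values mean the next pulse precedes the peak.
#'
#' @param ct_pk_ms Contraction peak time after the stimulus, ms.
#' @param frequency_hz Stimulation rate, Hz.
#' @return Interval in ms.
#' @examples
#' peak_to_next_stimulus(190.3, 4) # 59.7
#' peak_to_next_stimulus(190.3, 5) # 9.7
#' @export
peak_to_next_stimulus <- function(ct_pk_ms, frequency_hz) {
  stopifnot(frequency_hz > 0, ct_pk_ms >= 0)
  1000 / frequency_hz - ct_pk_ms
}

#' Estimate the absolute refractory period from a capture curve
#'
#' Two estimators over a set of (frequency, capture rate) observations:
#'
#' * `half_capture_doubling` — the classical readout: at the highest
#'   frequency showing ~50% capture, every other pulse is blocked, so the
#'   refractory period is twice the period at that frequency.
#' * `sweep_bisection` — inverts [refractory_capture_model()] over a 1 ms
#'   ARP grid and keeps the ARPs reproducing every observed rate; reports
#'   the smallest consistent ARP and carries the full interval.
#'
#' @param capture_curve A tibble with columns `frequency_hz` and
#'   `capture_rate` (e.g. rows from [detect_captures()]).
#' @param method `"half_capture_doubling"` (default) or `"sweep_bisection"`.
#' @param half_tol Tolerance around 0.5 for "half capture" (default 0.05).
#' @return A `quadcell_arp` object: list with `arp_ms`, `method`,
#'   `supporting_frequencies_hz` and, for the sweep, `arp_lo_ms` /
#'   `arp_hi_ms` (the consistent interval).
#' @examples
#' estimate_arp(tibble::tibble(frequency_hz = 9, capture_rate = 0.5))
#' @export
estimate_arp <- function(capture_curve,
                         method = c("half_capture_doubling",
                                    "sweep_bisection"),
                         half_tol = 0.05) {
  method <- match.arg(method)
  cc <- tibble::as_tibble(capture_curve)
  stopifnot(all(c("frequency_hz", "capture_rate") %in% names(cc)))

  if (method == "half_capture_doubling") {
    half <- cc[abs(cc$capture_rate - 0.5) <= half_tol, ]
    if (nrow(half) == 0) {
      stop("no frequency with ~50% capture observed; extend the frequency ",
           "sweep until the capture rate falls to one half", call. = FALSE)
    }
    f <- max(half$frequency_hz)
    est <- list(arp_ms = 2 * 1000 / f, method = method,
                supporting_frequencies_hz = half$frequency_hz)
  } else {
    if (nrow(cc) < 1) stop("empty capture curve", call. = FALSE)
    grid <- seq_len(2L * as.integer(ceiling(1000 / min(cc$frequency_hz))))
    ok <- vapply(grid, function(a) {
      all(abs(vapply(1000 / cc$frequency_hz, function(p) {
        refractory_capture_model(a, p, 40L)
      }, numeric(1)) - cc$capture_rate) <= 0.025)
    }, logical(1))
    if (!any(ok)) {
      stop("no ARP on the grid reproduces the observed capture curve; ",
           "check that the curve brackets the 100% -> 50% transition",
           call. = FALSE)
    }
    if (ok[1]) {
      # consistent down to the grid minimum: the curve never left 100%
      stop("capture curve does not constrain the ARP (no transition ",
           "observed); sample higher frequencies", call. = FALSE)
    }
    est <- list(arp_ms = min(grid[ok]), method = method,
                arp_lo_ms = min(grid[ok]), arp_hi_ms = max(grid[ok]),
                supporting_frequencies_hz = cc$frequency_hz)
  }
  structure(est, class = "quadcell_arp")
}

#' @export
print.quadcell_arp <- function(x, ...) {
  cat(sprintf("<quadcell_arp> ARP = %g ms (%s)\n", x$arp_ms, x$method))
  if (!is.null(x$arp_lo_ms)) {
    cat(sprintf("  consistent interval: [%g, %g] ms\n",
                x$arp_lo_ms, x$arp_hi_ms))
  }
  invisible(x)
}

#' @rdname estimate_arp
#' @param x A `quadcell_arp` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.quadcell_arp <- function(x, ...) {
  tibble::tibble(
    arp_ms = x$arp_ms, method = x$method,
    arp_lo_ms = x$arp_lo_ms %||% NA_real_,
    arp_hi_ms = x$arp_hi_ms %||% NA_real_,
    n_supporting = length(x$supporting_frequencies_hz))
}
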