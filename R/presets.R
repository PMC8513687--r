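#' Measurement-condition presets
#'
#' The package ships a small library of named measurement conditions
#' (`inst/extdata/presets.json`) used throughout the examples and tests:
#'
#' * `PACED_BEAT` — single-pixel pacing at 0.5 Hz, contraction peak
#'   190.3 ms after the stimulus, beat-to-beat sd 13.2 ms.
#' * `BASELINE_0NM` — drug-free 1 Hz baseline (FPD 238.6 ms, CT_PKS 211.9,
#'   RX'_PKS 308.9, T_d 478.6; 19 beats).
#' * `ISO_3NM` — 3 nM isoproterenol (226.2 / 207.4 / 302.4 / 424.6).
#' * `ISO_10NM` — 10 nM isoproterenol; values are proportional design
#'   defaults, flagged non-authoritative in the presets file.
#' * `ARP_222` — refractory characterization, absolute refractory period
#'   222 ms.
#' * `FIBROBLAST_TIMELAPSE`, `CM_SPHEROID_TIMELAPSE` — time-lapse
#'   adhesion imaging presets with cell-type-specific impedance plateaus.
#'
#' @param name Preset name (see above). `list_presets()` returns all names.
#' @return `quadcell_preset()` returns a list whose elements are constructed
#'   parameter objects: `beat` ([beat_params()]), `ep` ([ep_params()]),
#'   `monolayer` ([monolayer_params()]), `protocol` ([stim_protocol()]) for
#'   recording presets, or `timelapse` ([timelapse_params()]) for time-lapse
#'   presets, plus `name`, `description`, `dose_nM`, `n_beats` and the raw
#'   entry under `$raw`.
#' @examples
#' p <- quadcell_preset("BASELINE_0NM")
#' p$beat$ct_pk_ms
#' @export
quadcell_preset <- function(name) {
  db <- load_preset_db()
  if (!name %in% names(db$presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(db$presets), collapse = ", "), call. = FALSE)
  }
  raw <- db$presets[[name]]
  out <- list(name = name, description = raw$description, raw = raw)
  if (!is.null(raw$beat)) {
    out$beat <- do.call(beat_params, raw$beat)
    out$ep <- do.call(ep_params, raw$ep)
    out$protocol <- do.call(stim_protocol, raw$protocol)
    out$monolayer <- monolayer_params(
      arp_ms = raw$monolayer$arp_ms,
      mech_onset_intercept_ms = raw$monolayer$mech_onset_intercept_ms,
      mech_onset_radial_slope_ms_per_um =
        raw$monolayer$mech_onset_radial_slope_ms_per_um,
      ep_conduction_um_per_ms = raw$monolayer$ep_conduction_um_per_ms,
      beat = out$beat, ep = out$ep)
    out$dose_nM <- if (is.null(raw$dose_nM)) NA_real_ else raw$dose_nM
    out$n_beats <- raw$n_beats
    out$sd <- raw$sd
  }
  if (!is.null(raw$aggregates)) {
    out$timelapse <- timelapse_params(
      aggregates = dplyr::bind_rows(lapply(raw$aggregates, tibble::as_tibble)),
      impedance_base_ohm = raw$impedance_base_ohm,
      impedance_plateau_ohm = raw$impedance_plateau_ohm,
      adhesion_tau_h = raw$adhesion_tau_h,
      detachment = raw$detachment)
    out$impedance_plateau_range <- unlist(raw$impedance_plateau_range)
  }
  out
}

#' @rdname quadcell_preset
#' @export
list_presets <- function() names(load_preset_db()$presets)

load_preset_db <- function() {
  path <- system.file("extdata", "presets.json", package = "quadcell")
  if (path == "") stop("presets.json not found in installed package")
  jsonlite::read_json(path, simplifyVector = FALSE)
}
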