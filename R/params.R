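#' Opto-mechanical beat parameters
#'
#' Ground-truth fiducials of a single contraction transient as seen by an
#' in-pixel photodiode: the light intensity rises from baseline to a
#' contraction peak and then relaxes back. All times are measured from the
#' stimulus onset.
#'
#' @param amplitude_au Peak intensity above baseline, arbitrary units
#'   (>= 0; zero yields a flat trace).
#' @param ct_prime_pk_ms Contraction slope peak time CT'_PKS: time of the
#'   maximum of the first derivative during the rise.
#' @param ct_pk_ms Contraction peak time CT_PKS: time of the intensity
#'   maximum.
#' @param rx_prime_pk_ms Relaxation slope peak time RX'_PKS: time of the
#'   most negative derivative during the decay.
#' @param t_d_ms Optical cycle duration T_d: time at which the intensity
#'   first falls below 10% of the peak above baseline.
#' @param jitter_sd_ms Beat-to-beat timing jitter standard deviation, ms.
#'
#' @return A `quadcell_beat_params` object.
#' @examples
#' beat_params(ct_prime_pk_ms = 120, ct_pk_ms = 211.9,
#'             rx_prime_pk_ms = 308.9, t_d_ms = 478.6)
#' @export
beat_params <- function(amplitude_au = 1, ct_prime_pk_ms, ct_pk_ms,
                        rx_prime_pk_ms, t_d_ms, jitter_sd_ms = 0) {
  stopifnot(is.numeric(amplitude_au), amplitude_au >= 0, jitter_sd_ms >= 0)
  if (!(0 < ct_prime_pk_ms && ct_prime_pk_ms < ct_pk_ms &&
        ct_pk_ms < rx_prime_pk_ms && rx_prime_pk_ms < t_d_ms)) {
    stop("fiducials must satisfy 0 < CT'_PKS < CT_PKS < RX'_PKS < T_d",
         call. = FALSE)
  }
  structure(
    list(amplitude_au = amplitude_au, ct_prime_pk_ms = ct_prime_pk_ms,
         ct_pk_ms = ct_pk_ms, rx_prime_pk_ms = rx_prime_pk_ms,
         t_d_ms = t_d_ms, jitter_sd_ms = jitter_sd_ms),
    class = "quadcell_beat_params"
  )
}

#' Extracellular potential parameters
#'
#' Ground truth for a synthetic evoked extracellular complex: a large
#' biphasic stimulation artefact at the pulse onset, a sharp biphasic spike
#' a conduction delay later, and a slow unipolar T-wave.
#'
#' @param t_ap_ms Action potential initiation time T_ap: delay from stimulus
#'   onset to the spike extremum, ms.
#' @param spike_amp_uv Spike peak-to-peak amplitude, microvolts.
#' @param fpd_ms Field potential duration FPD: spike extremum to T-wave
#'   apex, ms.
#' @param artefact_amp_uv Stimulation artefact amplitude per phase, uV;
#'   must dominate the spike.
#' @param twave_width_ms Gaussian width (approximately full width at half
#'   maximum) of the T-wave, ms.
#' @param noise_sd_uv Additive white noise standard deviation, uV.
#'
#' @return A `quadcell_ep_params` object.
#' @export
ep_params <- function(t_ap_ms = 8, spike_amp_uv = 100, fpd_ms = 238.6,
                      artefact_amp_uv = 2000, twave_width_ms = 80,
                      noise_sd_uv = 0) {
  stopifnot(t_ap_ms > 0, spike_amp_uv > 0, fpd_ms > 0, twave_width_ms > 0,
            noise_sd_uv >= 0)
  if (artefact_amp_uv < spike_amp_uv) {
    stop("artefact_amp_uv must be >= spike_amp_uv (the artefact dominates)",
         call. = FALSE)
  }
  structure(
    list(t_ap_ms = t_ap_ms, spike_amp_uv = spike_amp_uv, fpd_ms = fpd_ms,
         artefact_amp_uv = artefact_amp_uv, twave_width_ms = twave_width_ms,
         noise_sd_uv = noise_sd_uv),
    class = "quadcell_ep_params"
  )
}

#' Paced monolayer parameters
#'
#' Ground truth for a paced cardiomyocyte monolayer on the array: the
#' absolute refractory period governing pulse capture, the mechanical-onset
#' timing model across the array, and the conduction speed of the electrical
#' wave. The mechanical onset of the beat at a pixel at radial distance `r`
#' (um from the array centre) is
#' `stimulus + mech_onset_intercept_ms + mech_onset_radial_slope_ms_per_um * r`;
#' a negative slope means the periphery moves first.
#'
#' @param arp_ms Absolute refractory period, ms (> 0).
#' @param mech_onset_intercept_ms Mechanical onset delay at the array
#'   centre, ms.
#' @param mech_onset_radial_slope_ms_per_um Radial slope of mechanical
#'   onset, ms per um (negative: periphery leads).
#' @param ep_conduction_um_per_ms Electrical conduction speed, um/ms (> 0).
#' @param beat A [beat_params()] object.
#' @param ep An [ep_params()] object.
#' @param seed Integer seed controlling all stochastic draws.
#'
#' @return A `quadcell_monolayer_params` object.
#' @export
monolayer_params <- function(arp_ms = 222, mech_onset_intercept_ms = 0,
                             mech_onset_radial_slope_ms_per_um = 0,
                             ep_conduction_um_per_ms = 200,
                             beat = beat_params(ct_prime_pk_ms = 107.8,
                                                ct_pk_ms = 190.3,
                                                rx_prime_pk_ms = 277.4,
                                                t_d_ms = 429.8),
                             ep = ep_params(), seed = 1L) {
  stopifnot(arp_ms > 0, ep_conduction_um_per_ms > 0,
            inherits(beat, "quadcell_beat_params"),
            inherits(ep, "quadcell_ep_params"))
  structure(
    list(arp_ms = arp_ms,
         mech_onset_intercept_ms = mech_onset_intercept_ms,
         mech_onset_radial_slope_ms_per_um = mech_onset_radial_slope_ms_per_um,
         ep_conduction_um_per_ms = ep_conduction_um_per_ms,
         beat = beat, ep = ep, seed = as.integer(seed)),
    class = "quadcell_monolayer_params"
  )
}

#' Time-lapse culture parameters
#'
#' Ground truth for time-lapse opacity and impedance imaging of aggregates
#' seeded on the array: each aggregate is a radial blob whose opacity decays
#' (cells spread and become transparent) while its adhesion footprint grows
#' and the local impedance ramps from the cell-free baseline toward a
#' cell-type-specific plateau. An optional trypsinization phase decays the
#' impedance excess exponentially, slowly at room temperature and faster at
#' 37 C.
#'
#' @param aggregates A data frame with one row per aggregate and columns
#'   `centre_row`, `centre_col` (pixel grid coordinates, may be fractional),
#'   `seed_time_h`, `initial_radius_um`, `growth_rate_um_per_h`,
#'   `opacity_decay_per_h`.
#' @param impedance_base_ohm Cell-free baseline impedance, Ohm.
#' @param impedance_plateau_ohm Fully adhered impedance plateau, Ohm
#'   (> baseline).
#' @param adhesion_tau_h Time constant of the adhesion ramp toward the
#'   plateau, hours.
#' @param detachment `NULL`, or a list with `start_min`, `rt_end_min`,
#'   `rate_rt_per_min`, `rate_37c_per_min` describing enzymatic detachment:
#'   exponential decay of the impedance excess at the room-temperature rate
#'   from `start_min` to `rt_end_min`, then at the faster 37 C rate.
#'   Detachment times are minutes since the start of the detachment assay,
#'   taken to begin at the first timestamp at or after `start_min / 60` h
#'   relative to the series start.
#' @param seed Integer seed.
#'
#' @return A `quadcell_timelapse_params` object.
#' @export
timelapse_params <- function(aggregates,
                             impedance_base_ohm = 3e5,
                             impedance_plateau_ohm = 1.15e6,
                             adhesion_tau_h = 24,
                             detachment = NULL, seed = 1L) {
  stopifnot(impedance_base_ohm > 0,
            impedance_plateau_ohm > impedance_base_ohm,
            adhesion_tau_h > 0)
  aggregates <- tibble::as_tibble(aggregates)
  need <- c("centre_row", "centre_col", "seed_time_h", "initial_radius_um",
            "growth_rate_um_per_h", "opacity_decay_per_h")
  if (!all(need %in% names(aggregates))) {
    stop("aggregates must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(aggregates) > 0 &&
      any(aggregates$growth_rate_um_per_h < 0 |
          aggregates$opacity_decay_per_h < 0)) {
    stop("aggregate rates must be >= 0", call. = FALSE)
  }
  if (!is.null(detachment)) {
    stopifnot(is.list(detachment),
              all(c("start_min", "rt_end_min", "rate_rt_per_min",
                    "rate_37c_per_min") %in% names(detachment)))
    if (detachment$rate_37c_per_min <= detachment$rate_rt_per_min) {
      stop("rate_37c_per_min must exceed rate_rt_per_min", call. = FALSE)
    }
    if (detachment$rate_rt_per_min < 0) {
      stop("detachment rates must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(aggregates = aggregates, impedance_base_ohm = impedance_base_ohm,
         impedance_plateau_ohm = impedance_plateau_ohm,
         adhesion_tau_h = adhesion_tau_h, detachment = detachment,
         seed = as.integer(seed)),
    class = "quadcell_timelapse_params"
  )
}
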