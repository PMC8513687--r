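{
  "schema": "quadcell-presets-1",
  "comment": "Measurement-condition presets. Fields listed under 'authoritative' carry reported experimental values; every other number is a package design default chosen to satisfy the fiducial ordering and typical NRVM physiology, and is NOT authoritative.",
  "presets": {
    "PACED_BEAT": {
      "description": "Single-pixel optical pacing at 0.5 Hz: contraction peak 190.3 ms after the stimulus with 13.2 ms beat-to-beat sd.",
      "authoritative": ["beat.ct_pk_ms", "beat.jitter_sd_ms", "protocol"],
      "protocol": {"amplitude_uA": 8, "pulse_width_ms": 1.2, "frequency_hz": 0.5, "n_pulses": 10, "start_ms": 0},
      "beat": {"amplitude_au": 1.0, "ct_prime_pk_ms": 107.8, "ct_pk_ms": 190.3, "rx_prime_pk_ms": 277.4, "t_d_ms": 429.8, "jitter_sd_ms": 13.2},
      "ep": {"t_ap_ms": 8, "spike_amp_uv": 100, "fpd_ms": 238.6, "artefact_amp_uv": 2000, "twave_width_ms": 80, "noise_sd_uv": 0},
      "monolayer": {"arp_ms": 222, "mech_onset_intercept_ms": 0, "mech_onset_radial_slope_ms_per_um": 0, "ep_conduction_um_per_ms": 200},
      "dose_nM": null,
      "n_beats": 10
    },
    "BASELINE_0NM": {
      "description": "Drug-free 1 Hz paced baseline: FPD 238.6 ms; CT_PKS 211.9 (sd 9.1); RX'_PKS 308.9 (sd 16.5); T_d 478.6 (sd 23.6); n = 19 beats.",
      "authoritative": ["beat.ct_pk_ms", "beat.rx_prime_pk_ms", "beat.t_d_ms", "beat.jitter_sd_ms", "ep.fpd_ms", "n_beats", "sd"],
      "protocol": {"amplitude_uA": 33, "pulse_width_ms": 1.2, "frequency_hz": 1, "n_pulses": 19, "start_ms": 0},
      "beat": {"amplitude_au": 1.0, "ct_prime_pk_ms": 120.0, "ct_pk_ms": 211.9, "rx_prime_pk_ms": 308.9, "t_d_ms": 478.6, "jitter_sd_ms": 9.1},
      "sd": {"ct_pk_ms": 9.1, "rx_prime_pk_ms": 16.5, "t_d_ms": 23.6},
      "ep": {"t_ap_ms": 8, "spike_amp_uv": 100, "fpd_ms": 238.6, "artefact_amp_uv": 2000, "twave_width_ms": 80, "noise_sd_uv": 0},
      "monolayer": {"arp_ms": 222, "mech_onset_intercept_ms": 0, "mech_onset_radial_slope_ms_per_um": 0, "ep_conduction_um_per_ms": 200},
      "dose_nM": 0,
      "n_beats": 19
    },
    "ISO_3NM": {
      "description": "3 nM isoproterenol: FPD 226.2; CT_PKS 207.4; RX'_PKS 302.4; T_d 424.6; n = 19 beats.",
      "authoritative": ["beat.ct_pk_ms", "beat.rx_prime_pk_ms", "beat.t_d_ms", "ep.fpd_ms", "n_beats"],
      "protocol": {"amplitude_uA": 33, "pulse_width_ms": 1.2, "frequency_hz": 1, "n_pulses": 19, "start_ms": 0},
      "beat": {"amplitude_au": 1.0, "ct_prime_pk_ms": 117.5, "ct_pk_ms": 207.4, "rx_prime_pk_ms": 302.4, "t_d_ms": 424.6, "jitter_sd_ms": 9.1},
      "ep": {"t_ap_ms": 8, "spike_amp_uv": 100, "fpd_ms": 226.2, "artefact_amp_uv": 2000, "twave_width_ms": 80, "noise_sd_uv": 0},
      "monolayer": {"arp_ms": 215, "mech_onset_intercept_ms": 0, "mech_onset_radial_slope_ms_per_um": 0, "ep_conduction_um_per_ms": 200},
      "dose_nM": 3,
      "n_beats": 19
    },
    "ISO_10NM": {
      "description": "10 nM isoproterenol: a further ~8% proportional shortening of the 3 nM values. All numbers here are design defaults (non-authoritative).",
      "authoritative": ["n_beats"],
      "protocol": {"amplitude_uA": 33, "pulse_width_ms": 1.2, "frequency_hz": 1, "n_pulses": 19, "start_ms": 0},
      "beat": {"amplitude_au": 1.0, "ct_prime_pk_ms": 108.1, "ct_pk_ms": 190.8, "rx_prime_pk_ms": 278.2, "t_d_ms": 390.6, "jitter_sd_ms": 9.1},
      "ep": {"t_ap_ms": 8, "spike_amp_uv": 100, "fpd_ms": 208.1, "artefact_amp_uv": 2000, "twave_width_ms": 80, "noise_sd_uv": 0},
      "monolayer": {"arp_ms": 200, "mech_onset_intercept_ms": 0, "mech_onset_radial_slope_ms_per_um": 0, "ep_conduction_um_per_ms": 200},
      "dose_nM": 10,
      "n_beats": 19
    },
    "ARP_222": {
      "description": "Refractory characterization: absolute refractory period 222 ms (50% capture at 9 Hz, period 111 ms).",
      "authoritative": ["monolayer.arp_ms"],
      "protocol": {"amplitude_uA": 8, "pulse_width_ms": 1.2, "frequency_hz": 9, "n_pulses": 20, "start_ms": 0},
      "beat": {"amplitude_au": 1.0, "ct_prime_pk_ms": 107.8, "ct_pk_ms": 190.3, "rx_prime_pk_ms": 277.4, "t_d_ms": 429.8, "jitter_sd_ms": 0},
      "ep": {"t_ap_ms": 8, "spike_amp_uv": 100, "fpd_ms": 238.6, "artefact_amp_uv": 2000, "twave_width_ms": 80, "noise_sd_uv": 0},
      "monolayer": {"arp_ms": 222, "mech_onset_intercept_ms": 0, "mech_onset_radial_slope_ms_per_um": 0, "ep_conduction_um_per_ms": 200},
      "dose_nM": null,
      "n_beats": 20
    },
    "FIBROBLAST_TIMELAPSE": {
      "description": "Fibroblast aggregate time-lapse: adhesion plateau ~1.15 MOhm (reported range 1-1.2 MOhm); two aggregates seeded at t = 0 h and t = 39 h.",
      "authoritative": ["impedance_plateau_range", "aggregates.seed_time_h"],
      "impedance_base_ohm": 3e5,
      "impedance_plateau_ohm": 1.15e6,
      "impedance_plateau_range": [1.0e6, 1.2e6],
      "adhesion_tau_h": 24,
      "aggregates": [
        {"centre_row": 16.5, "centre_col": 8.5, "seed_time_h": 0, "initial_radius_um": 250, "growth_rate_um_per_h": 8, "opacity_decay_per_h": 0.02},
        {"centre_row": 6.5, "centre_col": 16.5, "seed_time_h": 39, "initial_radius_um": 350, "growth_rate_um_per_h": 8, "opacity_decay_per_h": 0.02}
      ],
      "detachment": null
    },
    "CM_SPHEROID_TIMELAPSE": {
      "description": "Cardiomyocyte spheroid time-lapse: adhesion plateau ~0.65 MOhm (reported range 0.5-0.8 MOhm), slight spreading over 96 h.",
      "authoritative": ["impedance_plateau_range"],
      "impedance_base_ohm": 3e5,
      "impedance_plateau_ohm": 6.5e5,
      "impedance_plateau_range": [5.0e5, 8.0e5],
      "adhesion_tau_h": 30,
      "aggregates": [
        {"centre_row": 16.5, "centre_col": 16.5, "seed_time_h": 0, "initial_radius_um": 300, "growth_rate_um_per_h": 2, "opacity_decay_per_h": 0.005}
      ],
      "detachment": null
    }
  }
}
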