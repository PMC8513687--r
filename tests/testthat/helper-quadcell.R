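# shared fixtures, all generated in code

# a preset's beat with jitter switched off (noiseless single-beat work)
noiseless_beat <- function(preset) {
  b <- quadcell_preset(preset)$beat
  b$jitter_sd_ms <- 0
  b
}

# small 8x8 array with the standard pitch (FoV scales with the grid)
small_geometry <- function(rows = 8L) {
  array_geometry(rows = rows, cols = rows, pitch_um = 58,
                 fov_mm = rows * 58 / 1000)
}

fiducials <- function(f) {
  c(f$ct_prime_pks_ms, f$ct_pks_ms, f$rx_prime_pks_ms, f$t_d_ms)
}

beat_truth <- function(b) {
  c(b$ct_prime_pk_ms, b$ct_pk_ms, b$rx_prime_pk_ms, b$t_d_ms)
}

# a one-aggregate time-lapse that fits the small 8x8 grid
small_timelapse_params <- function() {
  timelapse_params(
    aggregates = tibble::tibble(
      centre_row = 4.5, centre_col = 4.5, seed_time_h = 0,
      initial_radius_um = 120, growth_rate_um_per_h = 2,
      opacity_decay_per_h = 0.01),
    adhesion_tau_h = 12)
}
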