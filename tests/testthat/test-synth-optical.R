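# generator <-> extractor round trips at zero noise, parameterized over the
# shipped presets: every realized fiducial within 2 sample periods (2 ms at
# the 1 kHz default) of the requested value
test_that("noiseless beats reproduce their requested fiducials", {
  for (preset in c("BASELINE_0NM", "ISO_3NM", "ISO_10NM", "PACED_BEAT")) {
    b <- noiseless_beat(preset)
    tr <- synth_optical_beat(b, sampling_rate_hz = 1000, duration_ms = 1000)
    f <- extract_optical_features(tr, stim_train(0))
    expect_equal(nrow(f), 1, info = preset)
    expect_true(all(abs(fiducials(f) - beat_truth(b)) <= 2), info = preset)
  }
})

test_that("the PACED_BEAT waveform peaks 190.3 ms after the stimulus", {
  tr <- synth_optical_beat(noiseless_beat("PACED_BEAT"),
                           sampling_rate_hz = 1000, stim_ms = 100)
  expect_equal(tr$time_ms[which.max(tr$value)] - 100, 190.3, tolerance = 2 / 190.3)
  # baseline is exactly zero before the stimulus
  expect_true(all(tr$value[tr$time_ms <= 100] == 0))
})

test_that("zero amplitude yields a flat zero trace", {
  b <- noiseless_beat("PACED_BEAT")
  b$amplitude_au <- 0
  tr <- synth_optical_beat(b)
  expect_true(all(tr$value == 0))
})

test_that("fiducial ordering is validated at construction", {
  expect_error(beat_params(ct_prime_pk_ms = 200, ct_pk_ms = 190,
                           rx_prime_pk_ms = 300, t_d_ms = 480),
               "CT'")
  expect_error(beat_params(ct_prime_pk_ms = 100, ct_pk_ms = 190,
                           rx_prime_pk_ms = 480, t_d_ms = 300),
               "CT'")
})

test_that("identical seeds give bit-identical recordings", {
  p <- quadcell_preset("PACED_BEAT")
  rec1 <- synth_paced_recording(p$monolayer, p$protocol)
  rec2 <- synth_paced_recording(p$monolayer, p$protocol)
  expect_identical(rec1$optical_traces, rec2$optical_traces)
  m2 <- p$monolayer
  m2$seed <- p$monolayer$seed + 1L
  rec3 <- synth_paced_recording(m2, p$protocol)
  expect_false(identical(rec1$optical_traces, rec3$optical_traces))
})

test_that("refractory skipping: ARP 222 ms drops alternate pulses at 5 Hz", {
  p <- quadcell_preset("PACED_BEAT")
  proto5 <- stim_protocol(frequency_hz = 5, n_pulses = 10,
                          pulse_width_ms = 1.2)
  rec <- synth_paced_recording(p$monolayer, proto5)
  expect_equal(rec$train$captured, rep(c(TRUE, FALSE), 5))
  proto4 <- stim_protocol(frequency_hz = 4, n_pulses = 10,
                          pulse_width_ms = 1.2)
  rec4 <- synth_paced_recording(p$monolayer, proto4)
  expect_true(all(rec4$train$captured))
})

test_that("negative radial slope makes corner beats precede the centre", {
  geom <- small_geometry()
  pc <- pixel_centers(geom)
  corner <- pc$pixel_id[which.max(pc$r_um)]
  centre <- pc$pixel_id[which.min(pc$r_um)]
  mono <- monolayer_params(
    mech_onset_intercept_ms = 80,
    mech_onset_radial_slope_ms_per_um = -0.05,
    beat = noiseless_beat("PACED_BEAT"), seed = 3)
  rec <- synth_paced_recording(
    mono, stim_protocol(frequency_hz = 1, n_pulses = 1),
    geometry = geom, optical_pixels = c(corner, centre))
  onset_of <- function(id) {
    v <- rec$optical_traces[match(id, rec$optical_pixels), ]
    rec$times_ms[which(v > 0)[1]]
  }
  # onset formula: stim + 80 - 0.05 * r
  expect_lt(onset_of(corner), onset_of(centre))
  r_gap <- max(pc$r_um) - min(pc$r_um)
  expect_equal(onset_of(centre) - onset_of(corner), 0.05 * r_gap,
               tolerance = 2 / (0.05 * r_gap))
})

test_that("a recording not covering the train is rejected", {
  p <- quadcell_preset("PACED_BEAT")
  expect_error(
    synth_paced_recording(p$monolayer, p$protocol, duration_ms = 5000),
    "too short")
})
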