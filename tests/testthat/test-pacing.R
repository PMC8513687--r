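test_that("refractory model reproduces the reported capture rates", {
  expect_equal(refractory_capture_model(222, 250, 20), 1.0) # 4 Hz
  expect_equal(refractory_capture_model(222, 200, 20), 0.5) # 5 Hz
  expect_equal(refractory_capture_model(222, 111, 20), 0.5) # 9 Hz
  expect_equal(refractory_capture_model(100, 500, 20), 1.0)
})

test_that("model equals the closed form 1/ceil(ARP/period) on a grid", {
  for (arp in seq(100, 400, by = 20)) {
    for (f in seq(0.5, 10, by = 0.5)) {
      period <- 1000 / f
      m <- ceiling(arp / period - 1e-9)
      expect_equal(refractory_capture_model(arp, period, 20), 1 / m,
                   info = sprintf("arp=%g f=%g", arp, f))
    }
  }
})

test_that("capture fraction is non-increasing in frequency at fixed ARP", {
  for (arp in c(150, 222, 350)) {
    rates <- vapply(seq(0.5, 10, by = 0.5),
                    function(f) refractory_capture_model(arp, 1000 / f, 40),
                    numeric(1))
    expect_true(all(diff(rates) <= 1e-12), info = arp)
  }
})

test_that("generator capture pattern matches the model across the grid", {
  for (arp in seq(100, 400, by = 60)) {
    for (f in c(0.5, 2, 5, 9)) {
      onsets <- (0:19) * 1000 / f
      cap <- refractory_captures(onsets, arp)
      idx <- which(cap)
      expect_equal(1 / diff(idx)[1],
                   refractory_capture_model(arp, 1000 / f, 20),
                   info = sprintf("arp=%g f=%g", arp, f))
    }
  }
})

test_that("detect_captures counts beats attributed to pulses", {
  p <- quadcell_preset("PACED_BEAT")
  # 10 pulses at 0.5 Hz, ARP 222 ms: every pulse captures
  rec <- synth_paced_recording(p$monolayer, p$protocol)
  cr <- detect_captures(get_trace(rec, rec$optical_pixels[1]), rec$train)
  expect_equal(cr$n_pulses, 10L)
  expect_equal(cr$capture_rate, 1.0)

  # at 5 Hz the generator skips alternate pulses; extraction sees half
  mono <- monolayer_params(arp_ms = 222, beat = noiseless_beat("PACED_BEAT"),
                           seed = 2)
  rec5 <- synth_paced_recording(
    mono, stim_protocol(frequency_hz = 5, n_pulses = 10,
                        pulse_width_ms = 1.2))
  cr5 <- detect_captures(get_trace(rec5, rec5$optical_pixels[1]), rec5$train)
  expect_equal(cr5$capture_rate, 0.5)

  # no beats at all
  flat <- monolayer_params(beat = {
    b <- noiseless_beat("PACED_BEAT"); b$amplitude_au <- 0; b
  }, seed = 2)
  rec0 <- synth_paced_recording(flat, p$protocol)
  cr0 <- detect_captures(get_trace(rec0, rec0$optical_pixels[1]), rec0$train)
  expect_equal(cr0$capture_rate, 0)
  expect_error(detect_captures(cr0, stim_train(numeric(0))), "empty")
})

test_that("peak-to-next-stimulus arithmetic is exact", {
  expect_equal(peak_to_next_stimulus(190.3, 4), 59.7)
  expect_equal(peak_to_next_stimulus(190.3, 5), 9.7)
})

test_that("half-capture doubling reads ARP off the 50% frequency", {
  est <- estimate_arp(tibble::tibble(frequency_hz = 9, capture_rate = 0.5))
  expect_equal(est$arp_ms, 2 * 1000 / 9, tolerance = 1e-9) # ~222 ms
  expect_equal(round(est$arp_ms), 222)
  td <- tidy(est)
  expect_equal(td$arp_ms, est$arp_ms)
})

test_that("sweep bisection brackets the ARP between the observed rates", {
  curve <- tibble::tibble(frequency_hz = c(4, 5), capture_rate = c(1, 0.5))
  est <- estimate_arp(curve, method = "sweep_bisection")
  # oracle: exhaustive inversion on a 1 ms grid says (200, 250] is the
  # consistent set, so the smallest consistent ARP is 201
  expect_gt(est$arp_ms, 200)
  expect_lte(est$arp_ms, 250)
  expect_equal(est$arp_lo_ms, 201)
  expect_equal(est$arp_hi_ms, 250)
})

test_that("a flat 100% capture curve cannot constrain the ARP", {
  expect_error(
    estimate_arp(tibble::tibble(frequency_hz = 1, capture_rate = 1)),
    "50%")
  expect_error(
    estimate_arp(tibble::tibble(frequency_hz = 1, capture_rate = 1),
                 method = "sweep_bisection"),
    "transition")
})
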