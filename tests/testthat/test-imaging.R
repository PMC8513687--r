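test_that("opacity assembly places sites on a 2x2 subgrid per pixel", {
  g <- array_geometry()
  fr <- assemble_opacity_frame(rep(2.5, 4096), g)
  expect_equal(dim(fr$site_frame$values), c(64, 64))
  expect_equal(dim(fr$pixel_frame$values), c(32, 32))
  expect_true(all(fr$site_frame$values == 2.5))
  expect_true(all(fr$pixel_frame$values == 2.5))
  expect_error(assemble_opacity_frame(rep(1, 4095), g), "4096")
})

test_that("pixel value is the mean of its four sites", {
  g <- small_geometry(2L) # 2x2 pixels, 16 sites on a 4x4 grid
  site <- matrix(0, 4, 4)
  site[1:2, 1:2] <- c(1, 2, 3, 4) # pixel (1,1) sites
  fr <- assemble_opacity_frame(as.vector(t(site)), g)
  expect_equal(fr$pixel_frame$values[1, 1], mean(c(1, 2, 3, 4)))
  expect_equal(fr$pixel_frame$values[2, 2], 0)
})

test_that("a full adjacent-pair scan of the 32x32 grid has 1984 pairs", {
  g <- array_geometry()
  base <- array_frame(matrix(5e5, g$rows, g$cols), "impedance")
  scans <- frame_to_pair_scans(base)
  expect_equal(nrow(scans), 2 * 32 * 31)
  expect_equal(sum(scans$orientation == "horizontal"), 32 * 31)
  re <- assemble_impedance_frame(scans, g)
  expect_true(all(re$values == 5e5))
})

test_that("pair assembly is local and linear", {
  g <- small_geometry(4L)
  fr <- array_frame(matrix(1e5, 4, 4), "impedance")
  scans <- frame_to_pair_scans(fr)
  re0 <- assemble_impedance_frame(scans, g)

  # perturb one pair: only its two incident pixels change
  scans2 <- scans
  scans2$impedance_ohm[1] <- 2e5
  re1 <- assemble_impedance_frame(scans2, g)
  changed <- which(re1$values != re0$values, arr.ind = TRUE)
  expect_equal(nrow(changed), 2)

  # linearity: a*scan1 + b*scan2 assembles to a*frame1 + b*frame2
  a <- 0.3; b <- 1.7
  mix <- scans
  mix$impedance_ohm <- a * scans$impedance_ohm + b * scans2$impedance_ohm
  rem <- assemble_impedance_frame(mix, g)
  expect_equal(rem$values, a * re0$values + b * re1$values)
})

test_that("non-adjacent pairs are rejected", {
  g <- small_geometry(4L)
  bad <- tibble::tibble(row1 = 1, col1 = 1, row2 = 3, col2 = 1,
                        impedance_ohm = 1e5)
  expect_error(assemble_impedance_frame(bad, g), "adjacent")
})

test_that("adhesion metrics classify baseline and plateau frames", {
  g <- small_geometry()
  base <- 3e5
  expect_equal(
    adhesion_metrics(array_frame(matrix(base, 8, 8), "impedance"), base)$
      attached_fraction, 0)
  expect_equal(
    adhesion_metrics(array_frame(matrix(1.15e6, 8, 8), "impedance"), base)$
      attached_fraction, 1)
  expect_error(
    adhesion_metrics(array_frame(matrix(1, 8, 8), "opacity"), base),
    "impedance")
})

test_that("front radius tracks the synthetic adhesion disc", {
  tp <- timelapse_params(
    aggregates = tibble::tibble(
      centre_row = 16.5, centre_col = 16.5, seed_time_h = 0,
      initial_radius_um = 300, growth_rate_um_per_h = 5,
      opacity_decay_per_h = 0.01),
    adhesion_tau_h = 10)
  tl <- synth_timelapse(tp, timestamps_h = c(60, 80))
  fr <- series_frame(tl$impedance, 1)
  # threshold at half the plateau excess: the logistic front then sits at
  # the nominal disc radius
  tf <- 0.5 * (tp$impedance_plateau_ohm - tp$impedance_base_ohm) /
    tp$impedance_base_ohm
  m <- adhesion_metrics(fr, tp$impedance_base_ohm, threshold_fraction = tf,
                        centres = tibble::tibble(centre_row = 16.5,
                                                 centre_col = 16.5))
  r_true <- 300 + 5 * 60
  expect_equal(m$front_radius_um$front_radius_um, r_true, tolerance = 58 / r_true)
})

test_that("attached fraction grows monotonically before detachment", {
  tp <- quadcell_preset("FIBROBLAST_TIMELAPSE")$timelapse
  ts <- seq(2, 142, by = 20)
  tl <- synth_timelapse(tp, timestamps_h = ts)
  fracs <- vapply(seq_along(ts), function(i) {
    adhesion_metrics(series_frame(tl$impedance, i),
                     tp$impedance_base_ohm)$attached_fraction
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  # per-pixel impedance itself is non-decreasing in time
  expect_true(all(apply(tl$impedance$frames, c(2, 3), function(v)
    all(diff(v) >= -1e-9))))
})

test_that("plateau impedances fall in the reported cell-type ranges", {
  for (preset in c("FIBROBLAST_TIMELAPSE", "CM_SPHEROID_TIMELAPSE")) {
    pr <- quadcell_preset(preset)
    tp <- pr$timelapse
    tl <- synth_timelapse(tp, timestamps_h = c(140, 142))
    fr <- series_frame(tl$impedance, 2)
    # core of the aggregate: pixels well inside the adhesion front
    ag <- tp$aggregates[1, ]
    d <- sqrt((row(fr$values) - ag$centre_row)^2 +
              (col(fr$values) - ag$centre_col)^2) * 58
    core <- d < ag$initial_radius_um
    rng <- pr$impedance_plateau_range
    expect_true(all(fr$values[core] >= rng[1] & fr$values[core] <= rng[2]),
                info = preset)
  }
})

test_that("zero aggregates give constant-baseline frames", {
  tp <- timelapse_params(
    aggregates = tibble::tibble(
      centre_row = numeric(), centre_col = numeric(),
      seed_time_h = numeric(), initial_radius_um = numeric(),
      growth_rate_um_per_h = numeric(), opacity_decay_per_h = numeric()))
  tl <- synth_timelapse(tp, timestamps_h = c(0, 10))
  expect_true(all(tl$opacity$frames == 0))
  expect_true(all(tl$impedance$frames == tp$impedance_base_ohm))
})

test_that("aggregate centres must lie on the grid", {
  tp <- timelapse_params(
    aggregates = tibble::tibble(
      centre_row = 99, centre_col = 1, seed_time_h = 0,
      initial_radius_um = 100, growth_rate_um_per_h = 1,
      opacity_decay_per_h = 0))
  expect_error(synth_timelapse(tp, timestamps_h = 0), "outside")
})

test_that("detachment kinetics recover the decay rate", {
  g <- small_geometry()
  k <- 0.23 # per minute
  t_min <- seq(0, 10, by = 1)
  frames <- array(0, dim = c(length(t_min), 8, 8))
  base <- 3e5
  for (i in seq_along(t_min)) {
    frames[i, , ] <- base + 7e5 * exp(-k * t_min[i])
  }
  ser <- frame_series(frames, t_min / 60, "impedance", g)
  fit <- detachment_kinetics(ser, base,
                             phases = tibble::tibble(start_min = 0,
                                                     end_min = 10))
  expect_equal(fit$phases$half_time_min, log(2) / k,
               tolerance = 0.05)

  # constant series: infinite half-time
  frames[] <- base + 7e5
  cfit <- detachment_kinetics(frame_series(frames, t_min / 60, "impedance", g),
                              base,
                              phases = tibble::tibble(start_min = 0,
                                                      end_min = 10))
  expect_true(is.infinite(cfit$phases$half_time_min))
})

test_that("the 37C phase detaches faster than the room-temperature phase", {
  fib <- quadcell_preset("FIBROBLAST_TIMELAPSE")$timelapse
  ag <- fib$aggregates[1, ]
  ag$seed_time_h <- -200 # long-established culture, fully adhered
  tp <- timelapse_params(
    aggregates = ag,
    impedance_base_ohm = fib$impedance_base_ohm,
    impedance_plateau_ohm = fib$impedance_plateau_ohm,
    adhesion_tau_h = fib$adhesion_tau_h,
    detachment = list(start_min = 0, rt_end_min = 11,
                      rate_rt_per_min = 0.05, rate_37c_per_min = 0.35))
  t_h <- seq(0, 20 / 60, by = 1 / 60)
  tl <- synth_timelapse(tp, timestamps_h = t_h)
  fit <- detachment_kinetics(
    tl$impedance, tp$impedance_base_ohm,
    phases = tibble::tibble(start_min = c(0, 11), end_min = c(11, 20)))
  expect_lt(fit$phases$half_time_min[2], fit$phases$half_time_min[1])
  expect_lt(fit$final_fraction, 0.2)
})
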