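#' Frame series container
#'
#' @param frames Numeric array `T x rows x cols`.
#' @param timestamps_h Increasing acquisition times, hours (length T).
#' @param modality `"opacity"` or `"impedance"`.
#' @param geometry An [array_geometry()].
#' @return A `quadcell_frame_series` object.
#' @export
frame_series <- function(frames, timestamps_h,
                         modality = c("opacity", "impedance"),
                         geometry = array_geometry()) {
  modality <- match.arg(modality)
  stopifnot(length(dim(frames)) == 3,
            dim(frames)[1] == length(timestamps_h),
            dim(frames)[2] == geometry$rows,
            dim(frames)[3] == geometry$cols)
  if (length(timestamps_h) > 1 && any(diff(timestamps_h) <= 0)) {
    stop("timestamps_h must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, timestamps_h = as.numeric(timestamps_h),
                 modality = modality, geometry = geometry),
            class = "quadcell_frame_series")
}

#' @export
print.quadcell_frame_series <- function(x, ...) {
  cat(sprintf("<quadcell_frame_series> %s, %d frames %d x %d, t = [%g, %g] h\n",
              x$modality, length(x$timestamps_h), x$geometry$rows,
              x$geometry$cols, min(x$timestamps_h), max(x$timestamps_h)))
  invisible(x)
}

#' Extract one frame from a series
#'
#' @param series A `quadcell_frame_series`.
#' @param i Frame index.
#' @return A `quadcell_frame`.
#' @export
series_frame <- function(series, i) {
  structure(list(values = series$frames[i, , ], modality = series$modality,
                 timestamp_h = series$timestamps_h[i]),
            class = "quadcell_frame")
}

#' Synthesize time-lapse opacity and impedance imaging
#'
#' Emulates aggregate seeding, spreading, adhesion and (optionally)
#' enzymatic detachment on the array. Opacity frames are sums of radial
#' Gaussian blobs, one per seeded aggregate, whose amplitude decays at
#' `opacity_decay_per_h` (cells spread and become transparent) while the
#' radius grows at `growth_rate_um_per_h`. Impedance frames start at the
#' cell-free baseline and, under each aggregate's growing footprint
#' (a logistic disc one pitch wide at its edge), ramp toward the plateau
#' with time constant `adhesion_tau_h`; overlapping aggregates saturate at
#' the strongest local excess rather than summing. After the detachment
#' start, the impedance excess decays exponentially at the
#' room-temperature rate, switching to the faster 37 C rate at
#' `rt_end_min`.
#'
#' @param params A [timelapse_params()] object.
#' @param geometry An [array_geometry()].
#' @param timestamps_h Strictly increasing frame times, hours.
#' @return A list with elements `opacity` and `impedance`, both
#'   `quadcell_frame_series`.
#' @examples
#' tp <- quadcell_preset("CM_SPHEROID_TIMELAPSE")$timelapse
#' tl <- synth_timelapse(tp, timestamps_h = c(0, 24, 48, 96))
#' @export
synth_timelapse <- function(params, geometry = array_geometry(),
                            timestamps_h) {
  stopifnot(inherits(params, "quadcell_timelapse_params"))
  timestamps_h <- as.numeric(timestamps_h)
  if (length(timestamps_h) > 1 && any(diff(timestamps_h) <= 0)) {
    stop("timestamps_h must be strictly increasing", call. = FALSE)
  }
  ag <- params$aggregates
  if (nrow(ag) > 0 &&
      (any(ag$centre_row < 1 | ag$centre_row > geometry$rows) ||
       any(ag$centre_col < 1 | ag$centre_col > geometry$cols))) {
    stop("aggregate centre outside the pixel grid", call. = FALSE)
  }
  nt <- length(timestamps_h)
  op <- array(0, dim = c(nt, geometry$rows, geometry$cols))
  im <- array(params$impedance_base_ohm,
              dim = c(nt, geometry$rows, geometry$cols))
  grid_r <- matrix(seq_len(geometry$rows), geometry$rows, geometry$cols)
  grid_c <- matrix(seq_len(geometry$cols), geometry$rows, geometry$cols,
                   byrow = TRUE)
  w <- geometry$pitch_um # logistic edge width of the adhesion disc
  dz <- params$impedance_plateau_ohm - params$impedance_base_ohm

  for (i in seq_len(nt)) {
    t <- timestamps_h[i]
    excess <- matrix(0, geometry$rows, geometry$cols)
    for (a in seq_len(nrow(ag))) {
      dt_h <- t - ag$seed_time_h[a]
      if (dt_h < 0) next
      d <- sqrt((grid_r - ag$centre_row[a])^2 +
                (grid_c - ag$centre_col[a])^2) * geometry$pitch_um
      rad <- ag$initial_radius_um[a] + ag$growth_rate_um_per_h[a] * dt_h
      op[i, , ] <- op[i, , ] +
        exp(-ag$opacity_decay_per_h[a] * dt_h) *
        exp(-d^2 / (2 * (rad / 2)^2))
      ramp <- 1 - exp(-dt_h / params$adhesion_tau_h)
      disc <- 1 / (1 + exp((d - rad) / w))
      excess <- pmax(excess, dz * ramp * disc)
    }
    if (!is.null(params$detachment)) {
      t_min <- t * 60
      det <- params$detachment
      if (t_min >= det$start_min) {
        rt_span <- min(t_min, det$rt_end_min) - det$start_min
        hot_span <- max(0, t_min - det$rt_end_min)
        excess <- excess * exp(-(det$rate_rt_per_min * rt_span +
                                 det$rate_37c_per_min * hot_span))
      }
    }
    im[i, , ] <- params$impedance_base_ohm + excess
  }
  list(opacity = frame_series(op, timestamps_h, "opacity", geometry),
       impedance = frame_series(im, timestamps_h, "impedance", geometry))
}
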