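#' Reconstruct the spatiotemporal contraction movie
#'
#' Pixels of the array are scanned sequentially under periodic pacing, so a
#' full-array movie is reconstructed by folding every pixel's trace to
#' stimulus-relative time (averaging over its available stimulation cycles)
#' and baseline-referencing each folded trace at the stimulus onset, i.e.
#' the movie stores the light-intensity change relative to the intensity at
#' the stimulus instant. The frame at time 0 is therefore identically zero.
#'
#' @param recording A `quadcell_recording` whose optical traces cover at
#'   least one full stimulation period each, paced by a periodic train.
#' @return A `quadcell_movie`: list with `geometry`, `times_ms` (one
#'   period, starting at 0), `delta` (array `T x rows x cols`), `n_traces`
#'   and `pixel_ids`.
#' @examples
#' p <- quadcell_preset("PACED_BEAT")
#' rec <- synth_paced_recording(p$monolayer,
#'   stim_protocol(frequency_hz = 1, n_pulses = 2),
#'   geometry = array_geometry(rows = 4, cols = 4, fov_mm = 0.232),
#'   optical_pixels = "all")
#' movie <- align_sequential_traces(rec)
#' @export
align_sequential_traces <- function(recording) {
  stopifnot(inherits(recording, "quadcell_recording"))
  train <- recording$train
  if (!train_is_periodic(train, recording$sampling_rate_hz)) {
    stop("alignment requires a periodic stimulation train", call. = FALSE)
  }
  sr <- recording$sampling_rate_hz
  dt <- 1000 / sr
  period <- train$period_ms
  if (is.na(period)) period <- diff(range(recording$times_ms))
  n_fold <- floor(period / dt)
  t_end <- recording$times_ms[length(recording$times_ms)]
  # onsets with a complete cycle inside the recording
  usable <- train$onsets_ms[train$onsets_ms + (n_fold - 1) * dt <= t_end]
  if (length(usable) == 0) {
    stop("no stimulation cycle fully covered by the recording", call. = FALSE)
  }
  geom <- recording$geometry
  ids <- recording$optical_pixels
  delta <- array(0, dim = c(n_fold, geom$rows, geom$cols))
  centers <- pixel_centers(geom)
  for (k in seq_along(ids)) {
    v <- recording$optical_traces[k, ]
    folded <- numeric(n_fold)
    for (o in usable) {
      i0 <- round(o / dt) + 1L
      folded <- folded + v[i0:(i0 + n_fold - 1L)]
    }
    folded <- folded / length(usable)
    folded <- folded - folded[1] # reference at the stimulus instant
    px <- centers[centers$pixel_id == ids[k], ]
    delta[, px$row, px$col] <- folded
  }
  structure(
    list(geometry = geom, times_ms = (seq_len(n_fold) - 1) * dt,
         delta = delta, n_traces = length(ids), pixel_ids = ids,
         n_cycles = length(usable)),
    class = "quadcell_movie")
}

#' @export
print.quadcell_movie <- function(x, ...) {
  cat(sprintf("<quadcell_movie> %d frames x %d x %d, %d traces, %d cycle(s) folded\n",
              length(x$times_ms), x$geometry$rows, x$geometry$cols,
              x$n_traces, x$n_cycles))
  invisible(x)
}

#' Mechanical activation map
#'
#' Per-pixel mechanical onset: the first time the delta intensity exceeds
#' `onset_criterion` (default 20%) of that pixel's own peak delta. Pixels
#' whose peak falls below `noise_floor` are marked missing.
#'
#' @param movie A `quadcell_movie` from [align_sequential_traces()].
#' @param onset_criterion Fraction of the per-pixel peak (default 0.2).
#' @param noise_floor Minimum peak delta for a pixel to count as responding
#'   (same units as the movie; default 0).
#' @return A tibble with one row per pixel: `row`, `col`, `pixel_id`,
#'   `x_um`, `y_um`, `r_um`, `peak`, `onset_ms` (`NA` for non-responding
#'   pixels).
#' @export
activation_map <- function(movie, onset_criterion = 0.2, noise_floor = 0) {
  stopifnot(inherits(movie, "quadcell_movie"),
            onset_criterion > 0, onset_criterion < 1)
  centers <- pixel_centers(movie$geometry)
  res <- purrr::pmap(list(centers$row, centers$col), function(r, c) {
    v <- movie$delta[, r, c]
    pk <- max(v)
    if (!is.finite(pk) || pk <= noise_floor || pk <= 0) {
      return(c(NA_real_, pk))
    }
    i <- which(v >= onset_criterion * pk)[1]
    c(movie$times_ms[i], pk)
  })
  centers$onset_ms <- vapply(res, `[`, numeric(1), 1)
  centers$peak <- vapply(res, `[`, numeric(1), 2)
  centers
}

#' Periphery-versus-centre propagation index
#'
#' Least-squares slope of mechanical onset time versus radial distance from
#' the array centre, in ms per micrometre. A negative slope means the
#' periphery moves first (contraction initiated at the rim, as seen when
#' central stress strains the less constrained edge); a positive slope is
#' the classical centre-outward electrical propagation signature.
#'
#' @param map An [activation_map()] tibble (or any tibble with `onset_ms`
#'   and `r_um`).
#' @param min_pixels Minimum number of finite onsets required (default 10).
#' @return A one-row tibble: `slope_ms_per_um`, `intercept_ms`, `n_pixels`,
#'   `r_squared`.
#' @export
periphery_centre_index <- function(map, min_pixels = 10) {
  ok <- is.finite(map$onset_ms) & is.finite(map$r_um)
  if (sum(ok) < min_pixels) {
    stop("fewer than ", min_pixels, " pixels with a finite onset",
         call. = FALSE)
  }
  d <- map[ok, ]
  if (stats::var(d$r_um) == 0) {
    stop("all pixels at the same radius: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(onset_ms ~ r_um, data = d)
  ss_tot <- sum((d$onset_ms - mean(d$onset_ms))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  tibble::tibble(
    slope_ms_per_um = unname(stats::coef(fit)[2]),
    intercept_ms = unname(stats::coef(fit)[1]),
    n_pixels = nrow(d),
    r_squared = r2)
}

#' Plot an activation map
#'
#' @param map An [activation_map()] tibble.
#' @return A ggplot raster of onset times.
#' @export
plot_activation_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(x = col, y = row, fill = onset_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "onset (ms)") +
    ggplot2::theme_minimal()
}
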