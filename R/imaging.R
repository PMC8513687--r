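#' Construct an array-scan frame
#'
#' @param values Numeric matrix (rows x cols) of per-pixel values:
#'   opacity in arbitrary units (>= 0) or impedance magnitude in Ohm (> 0).
#' @param modality `"opacity"` or `"impedance"`.
#' @param timestamp_h Acquisition time, hours.
#' @return A `quadcell_frame` object.
#' @export
array_frame <- function(values, modality = c("opacity", "impedance"),
                        timestamp_h = 0) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (modality == "impedance" && any(values <= 0)) {
    stop("impedance values must be > 0", call. = FALSE)
  }
  if (modality == "opacity" && any(values < 0)) {
    stop("opacity values must be >= 0", call. = FALSE)
  }
  structure(list(values = values, modality = modality,
                 timestamp_h = timestamp_h),
            class = "quadcell_frame")
}

#' @export
print.quadcell_frame <- function(x, ...) {
  cat(sprintf("<quadcell_frame> %s %d x %d at t = %g h\n", x$modality,
              nrow(x$values), ncol(x$values), x$timestamp_h))
  invisible(x)
}

#' Assemble an opacity frame from photodiode site measurements
#'
#' The four photodiode sites of each pixel form a 2 x 2 subgrid, so a full
#' scan of `rows * cols * 4` sites yields a site-resolution image twice the
#' pixel grid in each dimension; the pixel-resolution image is the mean of
#' each pixel's four sites.
#'
#' @param site_values Numeric vector of length `rows * cols * 4`, ordered
#'   row-major over the site grid (2*rows x 2*cols).
#' @param geometry An [array_geometry()] with 4 sites per pixel.
#' @param timestamp_h Acquisition time, hours.
#' @return A list with `site_frame` (2*rows x 2*cols `quadcell_frame`) and
#'   `pixel_frame` (rows x cols).
#' @examples
#' g <- array_geometry()
#' fr <- assemble_opacity_frame(rep(1, 4096), g)
#' @export
assemble_opacity_frame <- function(site_values, geometry = array_geometry(),
                                   timestamp_h = 0) {
  n_exp <- geometry$n_pixels * geometry$photodiode_sites_per_pixel
  if (length(site_values) != n_exp) {
    stop("expected ", n_exp, " site values, got ", length(site_values),
         call. = FALSE)
  }
  if (geometry$photodiode_sites_per_pixel != 4L) {
    stop("site assembly assumes 4 photodiode sites per pixel", call. = FALSE)
  }
  sr <- 2L * geometry$rows
  sc <- 2L * geometry$cols
  site <- matrix(site_values, nrow = sr, ncol = sc, byrow = TRUE)
  # pixel value = mean of its 2 x 2 site block
  pix <- (site[seq(1, sr, 2), seq(1, sc, 2)] +
          site[seq(1, sr, 2), seq(2, sc, 2)] +
          site[seq(2, sr, 2), seq(1, sc, 2)] +
          site[seq(2, sr, 2), seq(2, sc, 2)]) / 4
  list(site_frame = array_frame(site, "opacity", timestamp_h),
       pixel_frame = array_frame(pix, "opacity", timestamp_h))
}

#' Assemble an impedance frame from adjacent-electrode pair scans
#'
#' Each impedance measurement excites one pixel's electrode and terminates
#' on a horizontally or vertically adjacent pixel. A pixel's image value is
#' the mean of all pair measurements incident to it. A full scan covers
#' `rows * (cols - 1)` horizontal plus `(rows - 1) * cols` vertical pairs
#' (1984 on the 32 x 32 grid).
#'
#' @param scans A data frame with columns `row1`, `col1`, `row2`, `col2`
#'   (grid coordinates of the two electrodes; must be Manhattan-adjacent)
#'   and `impedance_ohm` (> 0).
#' @param geometry An [array_geometry()].
#' @param timestamp_h Acquisition time, hours.
#' @return An impedance `quadcell_frame`; pixels touched by no pair are NA.
#' @export
assemble_impedance_frame <- function(scans, geometry = array_geometry(),
                                     timestamp_h = 0) {
  scans <- tibble::as_tibble(scans)
  need <- c("row1", "col1", "row2", "col2", "impedance_ohm")
  stopifnot(all(need %in% names(scans)))
  if (any(scans$impedance_ohm <= 0)) {
    stop("impedance_ohm must be > 0", call. = FALSE)
  }
  manh <- abs(scans$row1 - scans$row2) + abs(scans$col1 - scans$col2)
  if (any(manh != 1)) {
    stop("all pairs must be Manhattan-adjacent electrodes", call. = FALSE)
  }
  inside <- function(r, c) r >= 1 & r <= geometry$rows &
    c >= 1 & c <= geometry$cols
  if (!all(inside(scans$row1, scans$col1) & inside(scans$row2, scans$col2))) {
    stop("pair coordinates outside the grid", call. = FALSE)
  }
  acc <- matrix(0, geometry$rows, geometry$cols)
  cnt <- matrix(0L, geometry$rows, geometry$cols)
  for (i in seq_len(nrow(scans))) {
    for (e in 1:2) {
      r <- scans[[paste0("row", e)]][i]
      c <- scans[[paste0("col", e)]][i]
      acc[r, c] <- acc[r, c] + scans$impedance_ohm[i]
      cnt[r, c] <- cnt[r, c] + 1L
    }
  }
  vals <- acc / cnt # pixels with no incident pair become NaN
  vals[cnt == 0L] <- NA_real_
  out <- structure(list(values = vals, modality = "impedance",
                        timestamp_h = timestamp_h),
                   class = "quadcell_frame")
  out
}

#' Enumerate the full adjacent-pair scan of a frame
#'
#' Expands a per-pixel impedance image into the complete horizontal and
#' vertical adjacent-pair scan list, each pair carrying the mean of its two
#' pixel values. Inverse companion to [assemble_impedance_frame()] for
#' synthetic data.
#'
#' @param frame An impedance `quadcell_frame`.
#' @return A tibble of pair scans (columns as in
#'   [assemble_impedance_frame()], plus `orientation`).
#' @export
frame_to_pair_scans <- function(frame) {
  stopifnot(inherits(frame, "quadcell_frame"), frame$modality == "impedance")
  v <- frame$values
  nr <- nrow(v)
  nc <- ncol(v)
  horiz <- tidyr::expand_grid(row1 = seq_len(nr), col1 = seq_len(nc - 1))
  horiz <- dplyr::mutate(horiz, row2 = row1, col2 = col1 + 1L,
                         orientation = "horizontal")
  vert <- tidyr::expand_grid(row1 = seq_len(nr - 1), col1 = seq_len(nc))
  vert <- dplyr::mutate(vert, row2 = row1 + 1L, col2 = col1,
                        orientation = "vertical")
  out <- dplyr::bind_rows(horiz, vert)
  out$impedance_ohm <- (v[cbind(out$row1, out$col1)] +
                        v[cbind(out$row2, out$col2)]) / 2
  out
}

#' Adhesion metrics of an impedance frame
#'
#' Attached pixels are those exceeding `baseline_ohm * (1 +
#' threshold_fraction)`. Per supplied aggregate centre, the advancing-front
#' radius is the radius of the smallest centred disc containing 95% of the
#' attached pixels assigned (by nearest centre) to that aggregate.
#'
#' @param frame An impedance `quadcell_frame`.
#' @param baseline_ohm Cell-free baseline impedance, Ohm.
#' @param threshold_fraction Attachment threshold as a fraction above
#'   baseline (default 0.1).
#' @param centres Optional data frame of aggregate centres with columns
#'   `centre_row`, `centre_col` (grid coordinates, fractional allowed).
#' @param pitch_um Pixel pitch for radii in um (default 58).
#' @param front_quantile Disc coverage quantile (default 0.95).
#' @return A list of class `quadcell_adhesion`: `attached_fraction`,
#'   `mean_attached_impedance_ohm`, `n_attached` and a tibble
#'   `front_radius_um` (one row per centre; empty when no centres given).
#' @export
adhesion_metrics <- function(frame, baseline_ohm, threshold_fraction = 0.1,
                             centres = NULL, pitch_um = 58,
                             front_quantile = 0.95) {
  stopifnot(inherits(frame, "quadcell_frame"))
  if (frame$modality != "impedance") {
    stop("adhesion_metrics requires an impedance frame", call. = FALSE)
  }
  v <- frame$values
  att <- !is.na(v) & v > baseline_ohm * (1 + threshold_fraction)
  n_att <- sum(att)
  fronts <- tibble::tibble(aggregate = integer(), front_radius_um = numeric())
  if (!is.null(centres) && n_att > 0) {
    centres <- tibble::as_tibble(centres)
    idx <- which(att, arr.ind = TRUE)
    dmat <- sapply(seq_len(nrow(centres)), function(a) {
      sqrt((idx[, 1] - centres$centre_row[a])^2 +
           (idx[, 2] - centres$centre_col[a])^2) * pitch_um
    })
    dmat <- matrix(dmat, nrow = nrow(idx))
    assign <- max.col(-dmat)
    fronts <- dplyr::bind_rows(lapply(seq_len(nrow(centres)), function(a) {
      d <- dmat[assign == a, a]
      tibble::tibble(aggregate = a,
                     front_radius_um = if (length(d)) {
                       unname(stats::quantile(d, front_quantile))
                     } else NA_real_)
    }))
  }
  structure(
    list(attached_fraction = n_att / length(v),
         mean_attached_impedance_ohm = if (n_att) mean(v[att]) else NA_real_,
         n_attached = n_att, front_radius_um = fronts,
         timestamp_h = frame$timestamp_h),
    class = "quadcell_adhesion")
}

#' @export
print.quadcell_adhesion <- function(x, ...) {
  cat(sprintf("<quadcell_adhesion> %.1f%% attached, mean %.3g Ohm\n",
              100 * x$attached_fraction, x$mean_attached_impedance_ohm))
  invisible(x)
}

#' Detachment kinetics from an impedance frame series
#'
#' Fits a single-exponential decay to the mean impedance excess (above
#' baseline) of a region for each temperature phase of a detachment assay,
#' returning the per-phase half-time and the final attached fraction
#' (final excess / initial excess). Phases with no appreciable decay get an
#' infinite half-time.
#'
#' @param series A `quadcell_frame_series` (see [frame_series()]) of
#'   impedance frames; timestamps in hours.
#' @param baseline_ohm Cell-free baseline impedance, Ohm.
#' @param phases A data frame with columns `start_min` and `end_min`
#'   delimiting each phase (minutes relative to the first frame).
#' @param region Optional logical matrix selecting pixels; default all.
#' @return A list of class `quadcell_detachment`: tibble `phases` with
#'   `phase`, `half_time_min`, `rate_per_min`, `n_frames`; plus
#'   `final_fraction`.
#' @export
detachment_kinetics <- function(series, baseline_ohm, phases,
                                region = NULL) {
  stopifnot(inherits(series, "quadcell_frame_series"),
            series$modality == "impedance")
  if (length(series$timestamps_h) < 3) {
    stop("need at least 3 frames", call. = FALSE)
  }
  phases <- tibble::as_tibble(phases)
  stopifnot(all(c("start_min", "end_min") %in% names(phases)))
  t_min <- (series$timestamps_h - series$timestamps_h[1]) * 60
  excess <- vapply(seq_along(t_min), function(i) {
    v <- series$frames[i, , ]
    if (!is.null(region)) v <- v[region]
    mean(v) - baseline_ohm
  }, numeric(1))
  if (any(diff(excess) > 1e-9 * max(abs(excess)))) {
    warning("impedance excess is not monotonically decreasing; ",
            "series may not be a detachment assay")
  }
  res <- dplyr::bind_rows(lapply(seq_len(nrow(phases)), function(p) {
    in_p <- t_min >= phases$start_min[p] & t_min <= phases$end_min[p]
    tp <- t_min[in_p]
    ep <- excess[in_p]
    if (sum(in_p) < 2 || any(ep <= 0)) {
      return(tibble::tibble(phase = p, half_time_min = NA_real_,
                            rate_per_min = NA_real_, n_frames = sum(in_p)))
    }
    # log-linear least squares: excess ~ excess0 * exp(-k t)
    k <- -unname(stats::coef(stats::lm(log(ep) ~ tp))[2])
    tibble::tibble(phase = p,
                   half_time_min = if (k > 1e-12) log(2) / k else Inf,
                   rate_per_min = k, n_frames = sum(in_p))
  }))
  structure(list(phases = res,
                 final_fraction = excess[length(excess)] / excess[1]),
            class = "quadcell_detachment")
}

#' @export
print.quadcell_detachment <- function(x, ...) {
  cat("<quadcell_detachment>\n")
  print(x$phases)
  cat(sprintf("final attached fraction: %.3f\n", x$final_fraction))
  invisible(x)
}
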