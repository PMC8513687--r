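#' Sensing-array geometry
#'
#' Describes the physical layout of the quad-modality sensing array: a square
#' grid of multimodal pixels, each carrying four photodiode sites, covering a
#' millimetre-scale field of view.
#'
#' @param rows,cols Number of pixel rows and columns (default 32 x 32 = 1024
#'   pixels).
#' @param pitch_um Pixel-to-pixel pitch in micrometres (default 58).
#' @param photodiode_sites_per_pixel Optical sensing sites per pixel
#'   (default 4, arranged as a 2 x 2 subgrid).
#' @param fov_mm Field-of-view edge length in millimetres (default 1.85).
#'
#' @return An object of class `quadcell_geometry`: a list with the above
#'   fields plus `n_pixels`.
#' @examples
#' geom <- array_geometry()
#' geom$n_pixels # 1024
#' @export
array_geometry <- function(rows = 32L, cols = 32L, pitch_um = 58,
                           photodiode_sites_per_pixel = 4L, fov_mm = 1.85) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L, pitch_um > 0,
            photodiode_sites_per_pixel >= 1L, fov_mm > 0)
  # the pixel grid must tile the stated field of view
  if (abs(pitch_um * rows - fov_mm * 1000) / (fov_mm * 1000) > 0.02) {
    stop("pitch_um * rows must match fov_mm within 2%", call. = FALSE)
  }
  structure(
    list(rows = rows, cols = cols, pitch_um = pitch_um,
         photodiode_sites_per_pixel = as.integer(photodiode_sites_per_pixel),
         fov_mm = fov_mm, n_pixels = rows * cols),
    class = "quadcell_geometry"
  )
}

#' @export
print.quadcell_geometry <- function(x, ...) {
  cat(sprintf("<quadcell_geometry> %d x %d pixels (%d sites), %g um pitch, %g mm FoV\n",
              x$rows, x$cols, x$n_pixels * x$photodiode_sites_per_pixel,
              x$pitch_um, x$fov_mm))
  invisible(x)
}

#' Pixel centre coordinates
#'
#' Tabulates every pixel's grid index and physical centre coordinates, plus
#' its radial distance from the array centre (the mean of all pixel centres).
#' Pixel ids run row-major from 1.
#'
#' @param geometry An [array_geometry()] object.
#' @return A tibble with columns `pixel_id`, `row`, `col`, `x_um`, `y_um`,
#'   `r_um`.
#' @examples
#' pixel_centers(array_geometry())
#' @export
pixel_centers <- function(geometry = array_geometry()) {
  stopifnot(inherits(geometry, "quadcell_geometry"))
  grid <- tidyr::expand_grid(row = seq_len(geometry$rows),
                             col = seq_len(geometry$cols))
  grid <- dplyr::mutate(grid,
    pixel_id = (row - 1L) * geometry$cols + col,
    x_um = (col - 0.5) * geometry$pitch_um,
    y_um = (row - 0.5) * geometry$pitch_um)
  cx <- mean(grid$x_um)
  cy <- mean(grid$y_um)
  dplyr::select(
    dplyr::mutate(grid, r_um = sqrt((x_um - cx)^2 + (y_um - cy)^2)),
    pixel_id, row, col, x_um, y_um, r_um)
}
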