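#' Pixel-movie container
#'
#' A `pixel_movie` wraps one processing stage of a wide-field recording as a
#' 3-D array (rows x columns x frames) together with its binary ROI mask and
#' acquisition metadata. Analyses are restricted to ROI pixels. Stages follow
#' the fixed processing order `raw` -> `baseline`/`dff` -> `deconvolved`.
#'
#' @param data numeric array, rows x columns x frames (a matrix is treated as
#'   a single frame).
#' @param roi logical matrix, rows x columns; `NULL` means all pixels.
#' @param pitch_um pixel pitch in micrometers (default 46.9, i.e. a pixel
#'   area of 0.0022 mm^2).
#' @param frame_ms frame interval in milliseconds (default 20, i.e. 50 Hz).
#' @param stage processing stage tag, one of `"raw"`, `"baseline"`, `"dff"`,
#'   `"deconvolved"`.
#' @return An object of class `pixel_movie`.
#' @export
pixel_movie <- function(data, roi = NULL, pitch_um = 46.9, frame_ms = 20,
                        stage = c("raw", "baseline", "dff", "deconvolved")) {
  stage <- match.arg(stage)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a rows x cols x frames array")
  if (dim(data)[3] < 1L) abort("movie must have at least one frame")
  if (is.null(roi)) roi <- matrix(TRUE, dim(data)[1], dim(data)[2])
  if (!identical(dim(roi), dim(data)[1:2]))
    abort("`roi` dimensions must match the movie grid")
  if (pitch_um <= 0 || frame_ms <= 0)
    abort("`pitch_um` and `frame_ms` must be positive")
  structure(
    list(data = data, roi = roi == TRUE, pitch_um = pitch_um,
         frame_ms = frame_ms, stage = stage),
    class = "pixel_movie"
  )
}

#' @export
print.pixel_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<pixel_movie> stage=%s  %d x %d px, %d frames (%.1f s)\n",
    x$stage, d[1], d[2], d[3], d[3] * x$frame_ms / 1000))
  cat(sprintf("  pitch %.1f um (%.4f mm^2/px), frame %.0f ms, ROI %d px\n",
              x$pitch_um, pixel_area_mm2(x), x$frame_ms, sum(x$roi)))
  invisible(x)
}

#' @export
dim.pixel_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3]

#' Pixel area in mm^2
#'
#' @param x a `pixel_movie`, or a numeric pixel pitch in micrometers.
#' @return Pixel area in mm^2 (0.0022 for the default 46.9 um pitch).
#' @export
pixel_area_mm2 <- function(x) {
  pitch <- if (inherits(x, "pixel_movie")) x$pitch_um else x
  (pitch / 1000)^2
}

# movie data as a pixels x frames matrix (column-major pixel order)
as_pixel_matrix <- function(movie) {
  d <- dim(movie$data)
  matrix(movie$data, d[1] * d[2], d[3])
}

# replace data keeping geometry, with a new stage tag; reshapes in place
# (dim<-) so large movies are not copied an extra time
movie_like <- function(movie, data, stage) {
  dim(data) <- dim(movie$data)
  pixel_movie(data, roi = movie$roi, pitch_um = movie$pitch_um,
              frame_ms = movie$frame_ms, stage = stage)
}

# pixel-center coordinates in mm relative to the ROI centroid;
# x = columns (increasing right), y = rows (increasing down)
roi_coords_mm <- function(roi, pitch_um) {
  idx <- which(roi, arr.ind = TRUE)
  ctr <- colMeans(idx)
  tibble(
    row = idx[, 1], col = idx[, 2],
    x_mm = (idx[, 2] - ctr[2]) * pitch_um / 1000,
    y_mm = (idx[, 1] - ctr[1]) * pitch_um / 1000
  )
}
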