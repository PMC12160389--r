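#' Running rank-order baseline
#'
#' Estimates the slow fluorescence baseline F0 per pixel as a running
#' order statistic of the raw trace: the 36th-percentile value within a
#' 28.5 s window centered on each frame. Nearest-rank (ceiling) indexing is
#' used and windows are truncated, not padded, at the trace edges. If the
#' window exceeds the recording, the whole-trace percentile is used
#' (with a message).
#'
#' @param raw a raw-stage [pixel_movie()].
#' @param rank percentile rank as a fraction (default 0.36).
#' @param window_s window length in seconds (default 28.5); converted to
#'   frames and forced odd for centering.
#' @return A baseline-stage [pixel_movie()].
#' @export
compute_baseline <- function(raw, rank = 0.36, window_s = 28.5) {
  stopifnot(inherits(raw, "pixel_movie"))
  if (raw$stage != "raw") abort("`raw` must be a raw-stage movie")
  nt <- n_frames(raw)
  w <- round(window_s * 1000 / raw$frame_ms)
  if (w %% 2 == 0) w <- w + 1
  if (w < 3) abort("baseline window must span at least 3 frames")
  if (w > nt) {
    inform(sprintf(
      "baseline window (%d frames) exceeds recording (%d); using whole-trace percentile",
      w, nt))
    w <- if (nt %% 2 == 1) nt else nt + 1 # truncation makes this whole-trace
  }
  x <- as_pixel_matrix(raw)                     # pixels x frames
  f0 <- .run_rank_filter(x, as.integer(w), rank)
  rm(x)
  movie_like(raw, f0, "baseline")
}

#' Baseline-normalized fluorescence change (dF/F)
#'
#' `r = (F - F0) / F0`, elementwise.
#'
#' @param raw raw-stage [pixel_movie()].
#' @param baseline baseline-stage [pixel_movie()] from [compute_baseline()],
#'   strictly positive on the ROI.
#' @return A dff-stage [pixel_movie()].
#' @export
dff <- function(raw, baseline) {
  stopifnot(inherits(raw, "pixel_movie"), inherits(baseline, "pixel_movie"))
  if (!identical(dim(raw$data), dim(baseline$data)))
    abort("raw and baseline movies must share dimensions")
  if (min(baseline$data) <= 0) {
    bad <- which(baseline$data <= 0)
    px <- arrayInd(bad, dim(raw$data))
    inside <- which(baseline$roi[px[, 1:2, drop = FALSE]])
    if (length(inside) > 0) {
      p1 <- px[inside[1], ]
      abort(sprintf(
        "nonpositive baseline inside ROI, e.g. pixel (%d, %d) frame %d",
        p1[1], p1[2], p1[3]))
    }
  }
  f <- as_pixel_matrix(raw)
  f0 <- as_pixel_matrix(baseline)
  out <- .dff_ratio(f, f0)
  rm(f, f0)
  movie_like(raw, out, "dff")
}

#' Prior-frame subtraction deconvolution
#'
#' Removes single-frame exponential indicator decay to emphasize new
#' activity: `y_t = r_t - gamma * r_{t-1}`, with `y_1 = r_1` (the frame
#' before the recording is taken as silent).
#'
#' @param x dff-stage [pixel_movie()].
#' @param gamma per-frame decay factor (default 0.89, GCaMP8m over 20 ms).
#' @return A deconvolved-stage [pixel_movie()].
#' @export
deconvolve <- function(x, gamma = 0.89) {
  stopifnot(inherits(x, "pixel_movie"))
  if (x$stage != "dff") abort("`x` must be a dff-stage movie")
  if (gamma <= 0 || gamma >= 1) abort("`gamma` must be in (0, 1)")
  r <- as_pixel_matrix(x)
  y <- .prior_frame_subtract(r, gamma)
  rm(r)
  movie_like(x, y, "deconvolved")
}

#' Preprocess a raw movie end to end
#'
#' Optional motion-correction hook (identity by default), baseline, dF/F,
#' and deconvolution in one call.
#'
#' @param raw raw-stage [pixel_movie()].
#' @param gamma,rank,window_s see [deconvolve()] and [compute_baseline()].
#' @param motion_correct optional function `movie -> movie` applied before
#'   baseline estimation (e.g. a frame-registration step); `NULL` = identity.
#' @return A list with `baseline`, `dff`, and `deconvolved` movies.
#' @export
preprocess_movie <- function(raw, gamma = 0.89, rank = 0.36,
                             window_s = 28.5, motion_correct = NULL) {
  if (!is.null(motion_correct)) raw <- motion_correct(raw)
  f0 <- compute_baseline(raw, rank = rank, window_s = window_s)
  r <- dff(raw, f0)
  list(baseline = f0, dff = r, deconvolved = deconvolve(r, gamma = gamma))
}
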