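#' Per-pixel activity threshold mask
#'
#' A pixel is active on a frame when its deconvolved value exceeds its own
#' mean plus `k_sd` standard deviations, both computed over the full
#' recording. Pixels outside the ROI, and zero-variance pixels, are never
#' active.
#'
#' @param y deconvolved-stage [pixel_movie()].
#' @param k_sd threshold in per-pixel SD units (default 4).
#' @return Logical rows x cols x frames array.
#' @export
active_mask <- function(y, k_sd = 4) {
  stopifnot(inherits(y, "pixel_movie"))
  if (y$stage != "deconvolved") abort("`y` must be a deconvolved-stage movie")
  m <- as_pixel_matrix(y)
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowMeans(m^2) - mu^2, 0) * ncol(m) / (ncol(m) - 1))
  thr <- mu + k_sd * s
  thr[s == 0 | !as.vector(y$roi)] <- Inf
  mask <- m > thr          # recycles thr down columns: per-pixel threshold
  rm(m)
  dim(mask) <- dim(y$data)
  mask
}

# opening (3x3 erosion then dilation) + minimum-component-size rule on one
# frame; components are 8-connected
clean_frame_mask <- function(frame, min_px) {
  opened <- .binary_dilate3x3(.binary_erode3x3(frame, 1L), 1L)
  if (!any(opened)) return(opened)
  lab <- .label_components8(opened)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim(frame))
}

#' Morphological mask cleanup
#'
#' Removes spuriously active pixels frame by frame: binary opening (erosion
#' then dilation with a 3 x 3 all-ones element) followed by removal of any
#' remaining 8-connected component smaller than `min_area_mm2`.
#'
#' @param mask logical rows x cols x frames array from [active_mask()].
#' @param min_area_mm2 minimum contiguous active area (default 0.028 mm^2,
#'   i.e. 13 pixels at 0.0022 mm^2 per pixel).
#' @param pitch_um pixel pitch, micrometers.
#' @return Cleaned logical array of the same shape.
#' @export
clean_mask <- function(mask, min_area_mm2 = 0.028, pitch_um = 46.9) {
  min_px <- ceiling(min_area_mm2 / pixel_area_mm2(pitch_um) - 1e-9)
  d <- dim(mask)
  out <- mask
  for (t in seq_len(d[3]))
    out[, , t] <- clean_frame_mask(mask[, , t, drop = TRUE], min_px)
  out
}

#' Segment the recording into events
#'
#' An event is a maximal run of consecutive frames each containing at least
#' one active pixel, bounded by fully inactive frames. Runs touching the
#' first or last recorded frame are kept but flagged as boundary events.
#'
#' @param y deconvolved-stage [pixel_movie()].
#' @param mask cleaned activity mask from [clean_mask()].
#' @return A list of `spont_event` objects. Each holds the inclusive frame
#'   range (`t_start`, `t_end`, 1-based), the per-frame masks and
#'   deconvolved activity cropped to the event, the onset mask (first-frame
#'   active pixels), and a `boundary` flag.
#' @export
segment_events <- function(y, mask) {
  stopifnot(inherits(y, "pixel_movie"))
  nt <- dim(mask)[3]
  any_active <- apply(mask, 3, any)
  r <- rle(any_active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(seq_along(keep), function(i) {
    k <- keep[i]
    ts <- starts[k]; te <- ends[k]
    new_event(
      t_start = ts, t_end = te,
      masks = mask[, , ts:te, drop = FALSE],
      activity = y$data[, , ts:te, drop = FALSE],
      frame_ms = y$frame_ms, pitch_um = y$pitch_um, roi = y$roi,
      boundary = (ts == 1L || te == nt), id = i)
  })
}

new_event <- function(t_start, t_end, masks, activity, frame_ms, pitch_um,
                      roi, boundary, id = NA_integer_) {
  structure(
    list(id = id, t_start = t_start, t_end = t_end, masks = masks,
         activity = activity, onset_mask = masks[, , 1, drop = TRUE],
         frame_ms = frame_ms, pitch_um = pitch_um, roi = roi,
         boundary = boundary),
    class = "spont_event")
}

#' @export
print.spont_event <- function(x, ...) {
  cat(sprintf(
    "<spont_event #%s> frames %d-%d (%d frames, %.0f ms)%s; union %d px (%.2f mm^2)\n",
    x$id, x$t_start, x$t_end, event_n_frames(x),
    event_n_frames(x) * x$frame_ms, if (x$boundary) " [boundary]" else "",
    sum(event_union_mask(x)), event_area_mm2(x)))
  invisible(x)
}

event_n_frames <- function(event) dim(event$masks)[3]

event_union_mask <- function(event) apply(event$masks, c(1, 2), any)

event_area_mm2 <- function(event)
  sum(event_union_mask(event)) * pixel_area_mm2(event$pitch_um)

#' Minimum-size event filter
#'
#' Keeps events whose union of active pixels across all frames covers at
#' least `min_total_area_mm2` of cortex (default 1 mm^2, i.e. 455 pixels at
#' 0.0022 mm^2 per pixel), focusing the analysis on large events.
#'
#' @param events list from [segment_events()].
#' @param min_total_area_mm2 area threshold, mm^2.
#' @return Filtered list of events.
#' @export
filter_events <- function(events, min_total_area_mm2 = 1.0) {
  keep <- vapply(events, function(e)
    event_area_mm2(e) >= min_total_area_mm2, logical(1))
  events[keep]
}

#' Maximally active frame of an event
#'
#' The event frame with the largest summed deconvolved activity over its
#' active pixels; ties break to the earliest frame.
#'
#' @param event a `spont_event`.
#' @param relative return the index within the event (default) rather than
#'   the absolute recording frame.
#' @return Frame index (1-based).
#' @export
max_active_frame <- function(event, relative = TRUE) {
  sums <- vapply(seq_len(event_n_frames(event)), function(t)
    sum(event$activity[, , t][event$masks[, , t]]), numeric(1))
  i <- which.max(sums)  # which.max takes the first maximum
  if (relative) i else event$t_start + i - 1L
}

#' Event summary table
#'
#' @param events list of `spont_event` objects.
#' @return A tibble with one row per event: id, frame range, duration (ms),
#'   union active area (mm^2), and the boundary flag.
#' @export
event_table <- function(events) {
  dplyr::bind_rows(lapply(events, function(e) tibble(
    event_id = e$id, t_start = e$t_start, t_end = e$t_end,
    n_frames = event_n_frames(e),
    duration_ms = event_n_frames(e) * e$frame_ms,
    area_mm2 = event_area_mm2(e), boundary = e$boundary)))
}

#' Detect and segment events in one call
#'
#' [active_mask()], [clean_mask()], [segment_events()], [filter_events()]
#' chained with the standard thresholds.
#'
#' @param y deconvolved-stage [pixel_movie()].
#' @param k_sd activity threshold in SD units.
#' @param min_component_mm2 minimum contiguous component during cleanup.
#' @param min_event_mm2 minimum union area per event.
#' @return List of `spont_event` objects.
#' @export
detect_events <- function(y, k_sd = 4, min_component_mm2 = 0.028,
                          min_event_mm2 = 1.0) {
  mask <- clean_mask(active_mask(y, k_sd = k_sd),
                     min_area_mm2 = min_component_mm2,
                     pitch_um = y$pitch_um)
  filter_events(segment_events(y, mask), min_total_area_mm2 = min_event_mm2)
}
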