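#' Gaussian spatial band-pass filter
#'
#' Difference-of-Gaussians filter emphasizing modular structure: the frame
#' smoothed at `s_low_um` minus the frame smoothed at `s_high_um`
#' (defaults 23 and 194 um SD). Smoothing uses normalized convolution so
#' pixels outside the ROI contribute no support; ROI-exterior output is 0.
#'
#' @param frame numeric matrix on the recording grid.
#' @param roi logical matrix (`NULL`: all pixels).
#' @param pitch_um pixel pitch, micrometers.
#' @param s_low_um,s_high_um Gaussian SDs of the pass band, micrometers
#'   (`0 < s_low < s_high`).
#' @return Filtered matrix, zero outside the ROI.
#' @export
bandpass <- function(frame, roi = NULL, pitch_um = 46.9,
                     s_low_um = 23, s_high_um = 194) {
  if (s_low_um <= 0 || s_high_um <= s_low_um)
    abort("need 0 < s_low_um < s_high_um")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(frame), ncol(frame))
  m <- roi * 1
  x <- frame * m
  lo <- gauss_smooth(x, s_low_um / pitch_um) /
    pmax(gauss_smooth(m, s_low_um / pitch_um), 1e-12)
  hi <- gauss_smooth(x, s_high_um / pitch_um) /
    pmax(gauss_smooth(m, s_high_um / pitch_um), 1e-12)
  (lo - hi) * m
}

# separable Gaussian smoothing with zero padding (normalized by the caller)
gauss_smooth <- function(x, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(m, kern) {
    n <- nrow(m); r <- (length(kern) - 1L) / 2L
    pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(kern))
      out <- out + kern[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x, k)), k))
}

#' Seed-point correlation map
#'
#' Pearson correlation, across events, between each ROI pixel and a seed
#' pixel, using one frame per event (typically the band-passed maximally
#' active frame, or the within-event sum).
#'
#' @param frames rows x cols x n_events array (or list of matrices), one
#'   frame per event. `NA` pixels (e.g. rotated out of the ROI in
#'   surrogates) are handled pairwise.
#' @param seed_px integer `c(row, col)` of the seed pixel.
#' @param roi logical matrix (`NULL`: all pixels).
#' @return A `correlation_result`: list with `map` (matrix of r, `NA`
#'   outside ROI), `seed_px`, and `n_events`.
#' @export
correlation_map <- function(frames, seed_px, roi = NULL) {
  frames <- as_frame_array(frames)
  d <- dim(frames)
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  if (d[3] < 10)
    warn(sprintf("correlation map from only %d events", d[3]))
  x <- matrix(frames, d[1] * d[2], d[3])     # pixels x events
  seed_i <- seed_px[1] + (seed_px[2] - 1L) * d[1]
  sv <- x[seed_i, ]
  if (sd(sv, na.rm = TRUE) == 0 || all(is.na(sv)))
    abort("seed pixel has zero variance across events")
  use <- if (anyNA(x)) "pairwise.complete.obs" else "everything"
  r <- suppressWarnings(as.vector(cor(sv, t(x), use = use)))
  map <- matrix(r, d[1], d[2])
  map[!roi] <- NA_real_
  structure(list(map = map, seed_px = seed_px, n_events = d[3]),
            class = "correlation_result")
}

as_frame_array <- function(frames) {
  if (is.list(frames))
    frames <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  frames
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> seed (%d, %d), %d events, r in [%.2f, %.2f]\n",
              x$seed_px[1], x$seed_px[2], x$n_events,
              min(x$map, na.rm = TRUE), max(x$map, na.rm = TRUE)))
  invisible(x)
}

# cache of nearest-neighbour source indices for rotation/reflection about
# the ROI centroid; entries outside the grid or ROI map to NA
rotation_index <- function(roi, angle_deg, refl_x, refl_y) {
  nr <- nrow(roi); nc <- ncol(roi)
  idx <- which(roi, arr.ind = TRUE)
  ctr <- colMeans(idx)
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dy <- g$row - ctr[1]; dx <- g$col - ctr[2]
  if (refl_x) dx <- -dx      # reflect at the y-axis (flip x)
  if (refl_y) dy <- -dy
  th <- -angle_deg * pi / 180  # inverse rotation to pull source pixels
  sx <- cos(th) * dx - sin(th) * dy
  sy <- sin(th) * dx + cos(th) * dy
  sr <- round(ctr[1] + sy); sc <- round(ctr[2] + sx)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  src <- rep(NA_integer_, nr * nc)
  lin <- as.integer(sr + (sc - 1) * nr)
  src[ok] <- lin[ok]
  have <- !is.na(src)
  src[have][!roi[src[have]]] <- NA_integer_   # source outside the ROI
  src[!roi] <- NA_integer_                    # target outside the ROI
  src
}

#' Rotation/reflection surrogate correlation maps
#'
#' Builds a null ensemble for the spatial extent of correlations: each
#' surrogate independently transforms every event frame by a random
#' rotation (uniform over 0-350 degrees in 10 degree steps) and random
#' reflections (probability 0.5 at each axis, about the ROI centroid,
#' nearest-neighbour resampling), then recomputes the seed correlation map.
#' Pixels rotated outside the ROI are excluded pairwise.
#'
#' @param frames rows x cols x n_events array, one frame per event.
#' @param seed_px seed pixel `c(row, col)`.
#' @param roi logical ROI matrix.
#' @param n_surrogates number of surrogate maps (default 100).
#' @param rotation_step_deg rotation grid step (default 10).
#' @param seed RNG seed.
#' @return List of `correlation_result` objects, length `n_surrogates`.
#' @export
surrogate_ensemble <- function(frames, seed_px, roi, n_surrogates = 100,
                               rotation_step_deg = 10, seed = NULL) {
  frames <- as_frame_array(frames)
  d <- dim(frames)
  angles <- seq(0, 360 - rotation_step_deg, by = rotation_step_deg)
  cache <- new.env(parent = emptyenv())
  get_idx <- function(a, rx, ry) {
    key <- paste(a, rx, ry)
    if (is.null(cache[[key]]))
      cache[[key]] <- rotation_index(roi, a, rx, ry)
    cache[[key]]
  }
  with_seed(seed, {
    lapply(seq_len(n_surrogates), function(s) {
      out <- array(NA_real_, d)
      fm <- matrix(frames, d[1] * d[2], d[3])
      om <- matrix(NA_real_, d[1] * d[2], d[3])
      for (e in seq_len(d[3])) {
        a <- sample(angles, 1)
        rx <- runif(1) < 0.5; ry <- runif(1) < 0.5
        src <- get_idx(a, rx, ry)
        v <- rep(NA_real_, d[1] * d[2])
        ok <- !is.na(src)
        v[ok] <- fm[src[ok], e]
        om[, e] <- v
      }
      correlation_map(array(om, d), seed_px, roi)
    })
  })
}

# 8-neighbourhood local maxima with greedy minimum-separation suppression;
# returns tibble(row, col, value, dist_mm) with distance from `from_px`
local_maxima <- function(map, roi, pitch_um, from_px,
                         min_sep_um = 800) {
  nr <- nrow(map); nc <- ncol(map)
  cand <- which(!is.na(map) & roi, arr.ind = TRUE)
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]; v <- map[i, j]
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !is.na(map[ii, jj]) && map[ii, jj] > v) return(FALSE)
    }
    TRUE
  }, logical(1))
  pk <- cand[is_max, , drop = FALSE]
  if (nrow(pk) == 0)
    return(tibble(row = integer(), col = integer(), value = numeric(),
                  dist_mm = numeric()))
  vals <- map[pk]
  ord <- order(vals, decreasing = TRUE)
  pk <- pk[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(pk))
  min_sep_px <- min_sep_um / pitch_um
  for (k in seq_len(nrow(pk))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    dd <- sqrt((pk[keep, 1] - pk[k, 1])^2 + (pk[keep, 2] - pk[k, 2])^2)
    if (all(dd >= min_sep_px)) keep[k] <- TRUE
  }
  pk <- pk[keep, , drop = FALSE]; vals <- vals[keep]
  tibble(row = pk[, 1], col = pk[, 2], value = vals,
         dist_mm = sqrt((pk[, 1] - from_px[1])^2 +
                        (pk[, 2] - from_px[2])^2) * pitch_um / 1000)
}

#' Long-range correlation significance
#'
#' Tests whether correlation strength at long range (local maxima of the
#' map located `band_mm` from the seed, minimum peak separation 800 um)
#' exceeds the rotation-surrogate null: the p value is the fraction of
#' surrogate median peak correlations greater than or equal to the real
#' median.
#'
#' @param real a `correlation_result` from [correlation_map()].
#' @param surrogates list from [surrogate_ensemble()].
#' @param roi logical ROI matrix.
#' @param pitch_um pixel pitch, micrometers.
#' @param band_mm distance band from the seed (default 1.3-1.7 mm).
#' @param min_peak_sep_um minimum separation between counted maxima.
#' @param s_low_um,s_high_um band-pass SDs applied to the correlation map
#'   before peak detection (peaks are located on the band-passed map; the
#'   reported correlation strengths are read from the raw map).
#' @return A list: `p_value` (`NA` with `undefined = TRUE` if the real map
#'   has no maxima in the band), `real_median`, `surrogate_medians`.
#' @export
long_range_significance <- function(real, surrogates, roi,
                                    pitch_um = 46.9, band_mm = c(1.3, 1.7),
                                    min_peak_sep_um = 800,
                                    s_low_um = 23, s_high_um = 194) {
  band_median <- function(cr) {
    ok <- roi & !is.na(cr$map)
    m0 <- cr$map
    m0[!ok] <- 0
    bp <- bandpass(m0, ok, pitch_um, s_low_um, s_high_um)
    bp[!ok] <- NA_real_
    pks <- local_maxima(bp, ok, pitch_um, cr$seed_px, min_peak_sep_um)
    pks <- pks[pks$dist_mm >= band_mm[1] & pks$dist_mm <= band_mm[2], ]
    if (nrow(pks) == 0) return(NA_real_)
    median(cr$map[cbind(pks$row, pks$col)])
  }
  real_med <- band_median(real)
  if (is.na(real_med))
    return(list(p_value = NA_real_, undefined = TRUE,
                real_median = NA_real_, surrogate_medians = numeric()))
  sur <- vapply(surrogates, band_median, numeric(1))
  sur_ok <- sur[!is.na(sur)]
  list(p_value = mean(sur_ok >= real_med), undefined = FALSE,
       real_median = real_med, surrogate_medians = sur)
}

#' Spatial wavelength of a frame
#'
#' Twice the distance from the origin to the first local minimum of the
#' radially averaged 2-D spatial autocorrelation of a band-passed activity
#' frame. Radial bins are one pixel pitch wide; the first minimum is the
#' first bin below both neighbours.
#'
#' @param frame band-passed activity matrix (see [bandpass()]).
#' @param roi logical ROI matrix (`NULL`: all pixels).
#' @param pitch_um pixel pitch, micrometers.
#' @return Wavelength in mm, or `NA` if no minimum lies within the ROI
#'   radius.
#' @export
wavelength_frame <- function(frame, roi = NULL, pitch_um = 46.9) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(frame), ncol(frame))
  prof <- radial_autocorr(frame, roi)
  v <- prof$r
  i <- 2L
  found <- FALSE
  while (i < length(v)) {
    if (!is.na(v[i - 1]) && !is.na(v[i]) && !is.na(v[i + 1]) &&
        v[i] < v[i - 1] && v[i] < v[i + 1]) { found <- TRUE; break }
    i <- i + 1L
  }
  if (!found) return(NA_real_)
  2 * prof$lag_px[i] * pitch_um / 1000
}

#' Wavelength of an event
#'
#' Applies [wavelength_frame()] to the band-passed maximally active frame
#' of an event.
#'
#' @param event a `spont_event`.
#' @param s_low_um,s_high_um band-pass SDs, micrometers.
#' @return Wavelength in mm (or `NA`).
#' @export
event_wavelength <- function(event, s_low_um = 23, s_high_um = 194) {
  f <- event$activity[, , max_active_frame(event), drop = TRUE]
  bp <- bandpass(f, event$roi, event$pitch_um, s_low_um, s_high_um)
  wavelength_frame(bp, event$roi, event$pitch_um)
}

# FFT-based masked spatial autocorrelation, radially averaged in 1-px bins;
# amplitude-normalized so the zero-lag value is 1
radial_autocorr <- function(frame, roi) {
  nr <- nrow(frame); nc <- ncol(frame)
  m <- roi * 1
  x <- frame
  x[!roi] <- 0
  x <- x - sum(x) / sum(m) * m          # zero mean on the ROI
  pr <- 2 * nr; pc <- 2 * nc            # zero padding against wrap-around
  pad <- function(a) { o <- matrix(0, pr, pc); o[1:nr, 1:nc] <- a; o }
  F1 <- fft(pad(x)); F2 <- fft(pad(m))
  num <- Re(fft(F1 * Conj(F1), inverse = TRUE)) / (pr * pc)
  den <- Re(fft(F2 * Conj(F2), inverse = TRUE)) / (pr * pc)
  a <- num / pmax(den, 0.5)             # per-lag overlap normalization
  a <- a / a[1, 1]
  lag_r <- c(0:(nr - 1), rep(NA, pr - 2 * nr + 1), -( (nr - 1):1))
  lag_c <- c(0:(nc - 1), rep(NA, pc - 2 * nc + 1), -( (nc - 1):1))
  rr <- outer(lag_r^2, lag_c^2, `+`)
  ok <- !is.na(rr) & den > sum(m) * 0.05   # require some mask overlap
  bin <- round(sqrt(rr[ok]))
  vals <- a[ok]
  prof <- tapply(vals, bin, mean)
  tibble(lag_px = as.integer(names(prof)), r = as.numeric(prof))
}
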