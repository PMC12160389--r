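#' Propagation-area exclusion radius
#'
#' The exclusion radius implied by iterated 3 x 3 dilation of the onset
#' mask: `n_dilate` iterations cover a Chebyshev radius of `n_dilate`
#' pixels, i.e. `n_dilate * pitch_um` micrometers (~420 um for the default
#' nine iterations at 46.9 um pitch).
#'
#' @param pitch_um pixel pitch, micrometers.
#' @param n_dilate dilation iterations (default 9).
#' @return Radius in micrometers.
#' @export
propagation_exclusion_radius_um <- function(pitch_um = 46.9, n_dilate = 9) {
  n_dilate * pitch_um
}

#' Event geometry: active, onset, and propagation areas
#'
#' Computes the areas that classify events as static or dynamic. The onset
#' mask is dilated `n_dilate` times with a 3 x 3 all-ones element
#' (exclusion radius ~420 um by default); the propagation area PA is the
#' area of ever-active pixels falling outside that dilated onset
#' footprint. `PA = 0` defines a static event, `PA > 0` a dynamic
#' (propagating) one.
#'
#' @param event a `spont_event`.
#' @param n_dilate onset-mask dilation iterations (default 9).
#' @return One-row tibble: `event_id`, `p_sum` (ever-active pixel count),
#'   `a_active_mm2`, `a_on_mm2`, `pa_mm2`, `ra` (active / ROI area),
#'   `is_static`.
#' @export
event_geometry <- function(event, n_dilate = 9) {
  apx <- pixel_area_mm2(event$pitch_um)
  ever <- event_union_mask(event)
  onset <- event$onset_mask
  dil <- .binary_dilate3x3(onset, as.integer(n_dilate))
  pa_px <- sum(ever & !dil)
  p_sum <- sum(ever)
  a_total <- sum(event$roi) * apx
  tibble(
    event_id = event$id, p_sum = p_sum,
    a_active_mm2 = p_sum * apx, a_on_mm2 = sum(onset) * apx,
    pa_mm2 = pa_px * apx, ra = p_sum * apx / a_total,
    is_static = pa_px == 0)
}

#' Per-pixel onset times
#'
#' The first frame at which each ever-active pixel is active, in
#' milliseconds relative to the event start (onset-frame pixels have
#' `t_on = 0`).
#'
#' @param event a `spont_event`.
#' @return Tibble: `row`, `col`, `t_on_ms`.
#' @export
onset_times <- function(event) {
  d <- dim(event$masks)
  m <- matrix(event$masks, d[1] * d[2], d[3])
  ever <- which(rowSums(m) > 0)
  first <- apply(m[ever, , drop = FALSE], 1, function(v) which(v)[1])
  tibble(
    row = ((ever - 1) %% d[1]) + 1L,
    col = ((ever - 1) %/% d[1]) + 1L,
    t_on_ms = (first - 1) * event$frame_ms)
}

#' Fit a linear traveling wavefront
#'
#' Fits the planar onset model
#' `t_hat = x . [cos(theta), sin(theta)] / v + t_shift` to observed pixel
#' onset times by minimizing mean squared error: a grid search over
#' log-spaced speeds (1-300 mm/s) and directions (10 degree steps) with the
#' closed-form optimal `t_shift`, followed by Nelder-Mead refinement.
#' Coordinates are pixel centers in mm relative to the ROI centroid, x
#' along columns and y along rows (increasing down); theta is measured
#' from +x in the image plane.
#'
#' @param onsets tibble from [onset_times()].
#' @param roi logical ROI matrix used for the coordinate origin.
#' @param pitch_um pixel pitch, micrometers.
#' @param frame_ms frame interval (carried into the result for reporting).
#' @param v_grid speed grid, mm/s.
#' @param theta_step_deg direction grid step.
#' @return A `wave_fit`: list with `v_mm_s`, `theta_deg` in [0, 360),
#'   `theta_axial_deg` in [0, 180), `t_shift_ms`, `mse_ms2`, `n_px`, and
#'   `degenerate` (`TRUE` when all onsets coincide, leaving the speed
#'   undefined).
#' @export
fit_linear_wave <- function(onsets, roi, pitch_um = 46.9, frame_ms = 20,
                            v_grid = exp(seq(log(1), log(300),
                                             length.out = 30)),
                            theta_step_deg = 10) {
  idx <- which(roi, arr.ind = TRUE)
  ctr <- colMeans(idx)
  x <- (onsets$col - ctr[2]) * pitch_um / 1000
  y <- (onsets$row - ctr[1]) * pitch_um / 1000
  t_on <- onsets$t_on_ms
  n <- length(t_on)
  if (n < 3) abort("need at least 3 onset pixels to fit a wavefront")
  if (sd(t_on) == 0) {
    return(new_wave_fit(NA_real_, NA_real_, mean(t_on), 0, n, frame_ms,
                        degenerate = TRUE))
  }
  mse_of <- function(v, th_rad) {
    proj <- (x * cos(th_rad) + y * sin(th_rad)) / v * 1000  # ms
    shift <- mean(t_on - proj)
    mean((t_on - proj - shift)^2)
  }
  thetas <- seq(0, 360 - theta_step_deg, by = theta_step_deg) * pi / 180
  best <- c(Inf, NA, NA)
  for (v in v_grid) for (th in thetas) {
    m <- mse_of(v, th)
    if (m < best[1]) best <- c(m, v, th)
  }
  opt <- optim(c(log(best[2]), best[3]),
               function(p) mse_of(exp(p[1]), p[2]),
               method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 500))
  v_hat <- exp(opt$par[1])
  th_hat <- opt$par[2] %% (2 * pi)
  proj <- (x * cos(th_hat) + y * sin(th_hat)) / v_hat * 1000
  new_wave_fit(v_hat, th_hat * 180 / pi, mean(t_on - proj), opt$value, n,
               frame_ms)
}

new_wave_fit <- function(v, theta_deg, t_shift, mse, n_px, frame_ms,
                         degenerate = FALSE, significant = NA) {
  structure(
    list(v_mm_s = v, theta_deg = theta_deg,
         theta_axial_deg = if (is.na(theta_deg)) NA_real_ else
           theta_deg %% 180,
         t_shift_ms = t_shift, mse_ms2 = mse, n_px = n_px,
         frame_ms = frame_ms, degenerate = degenerate,
         significant = significant),
    class = "wave_fit")
}

#' @export
print.wave_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<wave_fit> degenerate: simultaneous activation, speed undefined\n")
  } else {
    cat(sprintf(
      "<wave_fit> v = %.1f mm/s, theta = %.1f deg (axial %.1f), MSE = %.1f ms^2, %d px%s\n",
      x$v_mm_s, x$theta_deg, x$theta_axial_deg, x$mse_ms2, x$n_px,
      if (isTRUE(x$significant)) ", significant" else ""))
  }
  invisible(x)
}

#' @export
tidy.wave_fit <- function(x, ...) {
  tibble(v_mm_s = x$v_mm_s, theta_deg = x$theta_deg,
         theta_axial_deg = x$theta_axial_deg, t_shift_ms = x$t_shift_ms,
         mse_ms2 = x$mse_ms2, n_px = x$n_px,
         degenerate = x$degenerate, significant = x$significant)
}

#' @export
glance.wave_fit <- function(x, ...) tidy(x)

#' Permutation test for a significant linear wave
#'
#' Permutes the order of an event's frames, recomputes onset times, and
#' refits the wavefront for each permutation. The real fit is significant
#' when its fit quality (-MSE) exceeds the 95th percentile of permuted fit
#' qualities, i.e. its MSE beats the 5th percentile of permuted MSEs.
#' Events with fewer than 5 frames are excluded (too few distinct
#' permutations), returning `NA`.
#'
#' @param event a `spont_event`.
#' @param fit optional precomputed real `wave_fit` (refit when absent).
#' @param n_perm number of frame-order permutations (default 100).
#' @param alpha_percentile percentile of the permuted quality distribution
#'   the real fit must exceed (default 95).
#' @param seed RNG seed.
#' @return A list: `significant` (logical or `NA` when excluded), `fit`
#'   (the real `wave_fit` with its `significant` field set), `real_mse`,
#'   `perm_mse`.
#' @export
wave_significance <- function(event, fit = NULL, n_perm = 100,
                              alpha_percentile = 95, seed = NULL) {
  nf <- event_n_frames(event)
  if (nf < 5)
    return(list(significant = NA, fit = fit, real_mse = NA_real_,
                perm_mse = numeric()))
  if (is.null(fit))
    fit <- fit_linear_wave(onset_times(event), event$roi, event$pitch_um,
                           event$frame_ms)
  perm_mse <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(nf)
    pe <- event
    pe$masks <- event$masks[, , ord, drop = FALSE]
    pf <- fit_linear_wave(onset_times(pe), event$roi, event$pitch_um,
                          event$frame_ms)
    pf$mse_ms2
  }, numeric(1)))
  sig <- -fit$mse_ms2 > quantile(-perm_mse, alpha_percentile / 100,
                                 names = FALSE)
  fit$significant <- sig
  list(significant = sig, fit = fit, real_mse = fit$mse_ms2,
       perm_mse = perm_mse)
}

#' Maximum detectable propagation velocity
#'
#' Activity can at most be seen to traverse the field of view within one
#' frame: `fov_mm / frame_interval`. For a 3 mm window at 20 ms frames this
#' is 150 mm/s; fitted speeds above the ceiling are excluded from the
#' linear-fraction statistic.
#'
#' @param fov_diameter_mm imaging window diameter, mm.
#' @param frame_ms frame interval, ms.
#' @return Velocity ceiling in mm/s.
#' @export
velocity_ceiling <- function(fov_diameter_mm, frame_ms) {
  stopifnot(fov_diameter_mm > 0, frame_ms > 0)
  fov_diameter_mm / (frame_ms / 1000)
}

#' Axial direction statistics for significant waves
#'
#' Tests for a preferred axis of propagation: the Rayleigh test applied to
#' doubled axial angles (so opposite directions count as one axis), and,
#' when the axis is significant, a binomial test comparing the number of
#' waves traveling along either direction of the mean axis (split at
#' +/-90 degrees around it, null proportion 0.5).
#'
#' @param theta_deg vector of propagation directions in degrees.
#' @param alpha significance level gating the follow-up binomial test.
#' @return Tibble: `n`, `rayleigh_r` (resultant length on doubled angles),
#'   `rayleigh_p`, `mean_axis_deg` in [0, 180), `n_along`, `n_against`,
#'   `binomial_p` (`NA` when the axis is not significant).
#' @export
axial_direction_stats <- function(theta_deg, alpha = 0.05) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  n <- length(theta_deg)
  if (n < 10) warn(sprintf("axial statistics from only %d directions", n))
  phi <- 2 * (theta_deg %% 180) * pi / 180
  C <- mean(cos(phi)); S <- mean(sin(phi))
  rbar <- sqrt(C^2 + S^2)
  p_ray <- rayleigh_p(rbar, n)
  mean_axis <- (atan2(S, C) / 2 * 180 / pi) %% 180
  binom_p <- NA_real_
  n_along <- n_against <- NA_integer_
  if (!is.na(p_ray) && p_ray < alpha) {
    along <- cos((theta_deg - mean_axis) * pi / 180) >= 0
    n_along <- sum(along); n_against <- n - n_along
    binom_p <- binom.test(n_along, n, 0.5)$p.value
  }
  tibble(n = n, rayleigh_r = rbar, rayleigh_p = p_ray,
         mean_axis_deg = mean_axis, n_along = n_along,
         n_against = n_against, binomial_p = binom_p)
}

# Rayleigh uniformity test p value (Zar's approximation, accurate for
# n >= 10 and usable down to small n)
rayleigh_p <- function(rbar, n) {
  if (n < 2) return(NA_real_)
  R <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, 0), 1)
}

#' Wave fits for a set of events
#'
#' Runs geometry, onset extraction, wavefront fitting, and the permutation
#' significance test over a list of events, assembling the per-event wave
#' table. Static events (PA = 0), boundary-touching events, and events
#' shorter than `min_frames` are excluded from fitting; fits faster than
#' `v_max_mm_s` are flagged for exclusion from the linear-fraction
#' statistic.
#'
#' @param events list of `spont_event` objects.
#' @param n_perm permutations per event for [wave_significance()].
#' @param min_frames minimum event length for the permutation test.
#' @param v_max_mm_s velocity ceiling (see [velocity_ceiling()]).
#' @param n_dilate onset dilation iterations for [event_geometry()].
#' @param seed RNG seed.
#' @return Tibble: one row per event joining geometry with `v_mm_s`,
#'   `theta_deg`, `theta_axial_deg`, `mse_ms2`, `significant`,
#'   `above_ceiling`, `fitted`.
#' @export
fit_event_waves <- function(events, n_perm = 100, min_frames = 5,
                            v_max_mm_s = 150, n_dilate = 9, seed = NULL) {
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max - 1L,
                                max(length(events), 1L)))
  rows <- lapply(seq_along(events), function(i) {
    e <- events[[i]]
    g <- event_geometry(e, n_dilate = n_dilate)
    base <- dplyr::mutate(g, n_frames = event_n_frames(e),
                          duration_ms = event_n_frames(e) * e$frame_ms,
                          boundary = e$boundary)
    fit_ok <- !g$is_static && !e$boundary && event_n_frames(e) >= min_frames
    if (!fit_ok)
      return(dplyr::mutate(base, fitted = FALSE, v_mm_s = NA_real_,
                           theta_deg = NA_real_,
                           theta_axial_deg = NA_real_, mse_ms2 = NA_real_,
                           significant = NA, above_ceiling = NA))
    ws <- wave_significance(e, n_perm = n_perm, seed = seeds[i])
    f <- ws$fit
    dplyr::mutate(base, fitted = TRUE, v_mm_s = f$v_mm_s,
                  theta_deg = f$theta_deg,
                  theta_axial_deg = f$theta_axial_deg,
                  mse_ms2 = f$mse_ms2, significant = ws$significant,
                  above_ceiling = !is.na(f$v_mm_s) &&
                    f$v_mm_s > v_max_mm_s)
  })
  dplyr::bind_rows(rows)
}
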