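#' Synthetic-session configuration
#'
#' Bundles every knob of the ground-truth movie generator. Defaults are the
#' acquisition and activity statistics the analysis assumes: 46.9 um pixels
#' (0.0022 mm^2), 20 ms frames (50 Hz), indicator decay gamma = 0.89 per
#' frame, modular patterns with a 0.69 mm wavelength, a 6.9% static-event
#' rate, and planar waves at 32 mm/s.
#'
#' @param grid_shape integer (rows, cols) of the simulated grid. The default
#'   64 x 64 at 46.9 um spans 3 mm, the size of a typical imaging window.
#' @param pitch_um pixel pitch, micrometers.
#' @param frame_ms frame interval, milliseconds.
#' @param wavelength_mm modular spatial wavelength, defined operationally as
#'   twice the first-minimum radius of the radially averaged spatial
#'   autocorrelation (the analysis-side estimator's definition).
#' @param gamma per-frame calcium decay factor, in (0, 1).
#' @param n_events number of planted events.
#' @param static_fraction,wave_fraction fractions of static and planar-wave
#'   events; the remainder are repeated 5-frame motif events. Must sum to
#'   at most 1.
#' @param motif_library_size number of distinct 5-frame motif sequences.
#' @param wave_speed_mm_s planted wave speed, mm/s.
#' @param wave_theta_deg planted wave direction in degrees, or `NULL` for
#'   uniformly random directions per event.
#' @param onset_jitter_ms Gaussian jitter (SD, ms) added to continuous wave
#'   onset times before frame quantization.
#' @param amp peak deconvolved amplitude of planted activity.
#' @param envelope_floor activity envelope minimum, as a fraction of `amp`;
#'   events ramp linearly up to `amp` mid-event and back down.
#' @param static_n_frames,wave_hold_frames,motif_n_frames event-shape
#'   parameters: static duration, per-pixel active duration within a wave,
#'   and motif duration (5 frames = 100 ms at 50 Hz).
#' @param static_area_mm2 footprint area of static events (mm^2); events
#'   must clear the 1 mm^2 analysis filter, and 1.4 mm^2 matches typical
#'   static-event sizes.
#' @param wave_coverage footprint of wave events as a fraction of the ROI
#'   (waves sweep most of the field of view).
#' @param motif_frame_area_mm2 active area of a motif's localized onset
#'   frame (mm^2).
#' @param motif_spread_area_mm2 active area of each later motif frame
#'   (mm^2), distributed across the ROI: motif events initiate within a
#'   single region and progress into multiple active modules.
#' @param noise_sd additive camera noise SD, fluorescence units.
#' @param baseline_level mean baseline fluorescence.
#' @param drift_amplitude,drift_period_s slow additive baseline drift
#'   (fluorescence units / seconds); amplitude 0 disables drift.
#' @param quiet_range_s range of the uniform inactive-gap duration between
#'   events, seconds.
#' @param session_s optional fixed session length (seconds); an error is
#'   raised if the planted events do not fit.
#' @param seed integer RNG seed; identical configs generate bitwise
#'   identical sessions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(64, 64), pitch_um = 46.9,
                       frame_ms = 20, wavelength_mm = 0.69, gamma = 0.89,
                       n_events = 100, static_fraction = 0.069,
                       wave_fraction = 0.5, motif_library_size = 6,
                       wave_speed_mm_s = 32, wave_theta_deg = NULL,
                       onset_jitter_ms = 0, amp = 1, envelope_floor = 0.75,
                       static_n_frames = 2, wave_hold_frames = 2,
                       motif_n_frames = 5, static_area_mm2 = 1.4,
                       wave_coverage = 0.5, motif_frame_area_mm2 = 1.0,
                       motif_spread_area_mm2 = 1.5,
                       noise_sd = 2, baseline_level = 100,
                       drift_amplitude = 5, drift_period_s = 60,
                       quiet_range_s = c(0.2, 2), session_s = NULL,
                       seed = 1L) {
  if (any(grid_shape < 1)) abort("`grid_shape` must be positive")
  if (static_fraction < 0 || wave_fraction < 0 ||
      static_fraction + wave_fraction > 1 + 1e-12)
    abort("static_fraction + wave_fraction must lie in [0, 1]")
  if (wavelength_mm * 1000 <= 2 * pitch_um)
    abort("`wavelength_mm` must exceed twice the pixel pitch (Nyquist)")
  if (gamma <= 0 || gamma >= 1) abort("`gamma` must be in (0, 1)")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# first local minimum of the Bessel J0 at x = 3.8317; ring noise with
# center frequency f0 has radial autocorrelation J0(2 pi f0 r), so planting
# f0 = (3.8317 / 2 pi) / (lambda / 2) puts the first minimum at lambda / 2.
J0_FIRST_MIN <- 3.8317059702

#' Modular spatial pattern
#'
#' Generates a zero-mean pseudo-random pattern with modular (quasi-periodic,
#' isotropic) structure: Gaussian white noise band-passed on an annulus in
#' frequency space. The annulus center is calibrated so that the radially
#' averaged spatial autocorrelation has its first minimum at
#' `wavelength_mm / 2`, i.e. the pattern's wavelength under the
#' twice-first-minimum estimator equals `wavelength_mm`.
#'
#' @param shape integer (rows, cols).
#' @param wavelength_mm target wavelength, mm.
#' @param pitch_um pixel pitch, micrometers.
#' @param seed RNG seed (`NULL` uses the current RNG stream).
#' @param rel_bandwidth Gaussian annulus width relative to its center
#'   frequency.
#' @return A rows x cols numeric matrix with mean 0 and SD 1.
#' @export
make_modular_pattern <- function(shape, wavelength_mm, pitch_um = 46.9,
                                 seed = NULL, rel_bandwidth = 0.15) {
  if (wavelength_mm * 1000 <= 2 * pitch_um)
    abort("wavelength at or below the Nyquist period of the grid")
  nr <- shape[1]; nc <- shape[2]
  f0 <- (J0_FIRST_MIN / pi) / wavelength_mm     # cycles per mm
  nyq <- 1 / (2 * pitch_um / 1000)
  if (f0 >= nyq) abort("wavelength too short for this pixel pitch")
  fr <- fft_freq(nr) / (pitch_um / 1000)        # cycles per mm, per axis
  fc <- fft_freq(nc) / (pitch_um / 1000)
  fmag <- sqrt(outer(fr^2, fc^2, `+`))
  H <- exp(-(fmag - f0)^2 / (2 * (rel_bandwidth * f0)^2))
  H[1, 1] <- 0                                  # kill DC
  noise <- with_seed(seed, matrix(rnorm(nr * nc), nr, nc))
  pat <- Re(fft(fft(noise) * H, inverse = TRUE)) / (nr * nc)
  pat <- pat - mean(pat)
  pat / sd(pat)
}

fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) # cycles per sample
  k / n
}

# linear rise-and-fall amplitude envelope over n frames, in [floor, 1];
# the peak frame always reaches 1
event_envelope <- function(n, floor = 0.75) {
  if (n == 1) return(1)
  peak <- ceiling(n / 2)
  spread <- max(peak - 1, n - peak)
  tri <- 1 - abs(seq_len(n) - peak) / spread
  floor + (1 - floor) * tri
}

# footprint = top `coverage` fraction of a modular pattern, cleaned with the
# same opening + minimum-component rule the analysis uses, so planted masks
# survive mask cleanup unchanged
modular_footprint <- function(cfg, coverage, seed = NULL) {
  pat <- make_modular_pattern(cfg$grid_shape, cfg$wavelength_mm,
                              cfg$pitch_um, seed = seed)
  fp <- pat > quantile(pat, 1 - coverage)
  min_px <- ceiling(0.028 / pixel_area_mm2(cfg$pitch_um))
  clean_frame_mask(fp, min_px)
}

# spatially localized modular footprint: the `area_mm2 / A_PIX` strongest
# pattern pixels within a disk around `center_px` (disk sized to twice the
# target area, so roughly the top half of local modules is taken), cleaned
# like the analysis masks. Events initiate in a subregion, as real events do.
localized_footprint <- function(cfg, area_mm2, center_px = NULL,
                                pattern = NULL) {
  apx <- pixel_area_mm2(cfg$pitch_um)
  if (is.null(pattern))
    pattern <- make_modular_pattern(cfg$grid_shape, cfg$wavelength_mm,
                                    cfg$pitch_um)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  r_px <- sqrt(2 * area_mm2 / pi) / (cfg$pitch_um / 1000)
  if (is.null(center_px))
    center_px <- c(runif(1, 1 + r_px / 2, nr - r_px / 2),
                   runif(1, 1 + r_px / 2, nc - r_px / 2))
  dd <- outer((seq_len(nr) - center_px[1])^2,
              (seq_len(nc) - center_px[2])^2, `+`)
  score <- pattern
  score[dd > r_px^2] <- -Inf
  n_target <- min(round(area_mm2 / apx), sum(is.finite(score)))
  thr <- sort(score[is.finite(score)], decreasing = TRUE)[n_target]
  fp <- score >= thr
  min_px <- ceiling(0.028 / apx)
  clean_frame_mask(fp, min_px)
}

#' Plant a single ground-truth event
#'
#' Builds the true (deconvolved-scale) activity of one event. Static events
#' activate a fixed modular footprint for their whole duration; wave events
#' follow the planar onset model `t_on = x . [cos(theta), sin(theta)] / v`
#' quantized to the frame grid; motif events replay one of
#' `motif_library_size` fixed 5-frame sequences with small amplitude jitter.
#'
#' @param kind `"static"`, `"wave"`, or `"motif"`.
#' @param config a [sim_config()].
#' @param seed RNG seed for this event.
#' @param motif_library optional library from [make_motif_library()]; built
#'   on the fly (from `seed`) when absent.
#' @param motif_id which library sequence to replay (default: drawn).
#' @return A list with `activity` (rows x cols x frames array),
#'   `onset_mask`, and a one-row `record` tibble (kind, n_frames, planted
#'   wave parameters, motif id).
#' @export
make_event <- function(kind, config, seed = NULL, motif_library = NULL,
                       motif_id = NULL) {
  if (!kind %in% c("static", "wave", "motif"))
    abort(sprintf("unknown event kind '%s'", kind))
  with_seed(seed, {
    switch(kind,
      static = make_static_event(config),
      wave = make_wave_event(config),
      motif = make_motif_event(config, motif_library, motif_id))
  })
}

make_static_event <- function(cfg) {
  for (try in 1:20) {
    fp <- localized_footprint(cfg, cfg$static_area_mm2)
    if (sum(fp) * pixel_area_mm2(cfg$pitch_um) >= 1.05) break
  }
  nf <- cfg$static_n_frames
  env <- event_envelope(nf, cfg$envelope_floor)
  act <- array(0, c(cfg$grid_shape, nf))
  for (t in seq_len(nf)) act[, , t] <- fp * (cfg$amp * env[t])
  list(activity = act, onset_mask = fp,
       record = tibble(kind = "static", n_frames = nf,
                       v_mm_s = NA_real_, theta_deg = NA_real_,
                       motif_id = NA_integer_))
}

make_wave_event <- function(cfg) {
  for (try in 1:20) {
    fp <- modular_footprint(cfg, cfg$wave_coverage)
    theta <- cfg$wave_theta_deg %||% runif(1, 0, 360)
    v <- cfg$wave_speed_mm_s
    idx <- which(fp, arr.ind = TRUE)
    ctr <- c(mean(which(rowSums(fp) > 0)), mean(which(colSums(fp) > 0)))
    x_mm <- (idx[, 2] - mean(idx[, 2])) * cfg$pitch_um / 1000
    y_mm <- (idx[, 1] - mean(idx[, 1])) * cfg$pitch_um / 1000
    th <- theta * pi / 180
    t_cont <- (x_mm * cos(th) + y_mm * sin(th)) / v * 1000    # ms
    if (cfg$onset_jitter_ms > 0)
      t_cont <- t_cont + rnorm(length(t_cont), 0, cfg$onset_jitter_ms)
    t_cont <- t_cont - min(t_cont)
    q <- floor(t_cont / cfg$frame_ms)                         # 0-based frame
    nf <- max(q) + cfg$wave_hold_frames
    # reject rare footprints that leave an internal frame empty (the
    # segmenter would split the event)
    occupied <- logical(nf)
    for (k in seq_along(q))
      occupied[(q[k] + 1):min(q[k] + cfg$wave_hold_frames, nf)] <- TRUE
    if (all(occupied)) break
  }
  env <- event_envelope(nf, cfg$envelope_floor)
  act <- array(0, c(cfg$grid_shape, nf))
  for (k in seq_along(q)) {
    tt <- (q[k] + 1):min(q[k] + cfg$wave_hold_frames, nf)
    act[idx[k, 1], idx[k, 2], tt] <- cfg$amp * env[tt]
  }
  list(activity = act, onset_mask = fp & (act[, , 1] > 0),
       record = tibble(kind = "wave", n_frames = nf, v_mm_s = v,
                       theta_deg = theta %% 360, motif_id = NA_integer_))
}

#' Motif sequence library
#'
#' Builds `motif_library_size` fixed 5-frame activity sequences, each frame
#' an independent modular footprint scaled by the event envelope.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return A list of rows x cols x `motif_n_frames` arrays.
#' @export
make_motif_library <- function(config, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(config$motif_library_size), function(m) {
      nf <- config$motif_n_frames
      env <- event_envelope(nf, config$envelope_floor)
      act <- array(0, c(config$grid_shape, nf))
      a_roi <- prod(config$grid_shape) * pixel_area_mm2(config$pitch_um)
      cov <- min(config$motif_spread_area_mm2 / a_roi, 0.6)
      min_px <- ceiling(0.028 / pixel_area_mm2(config$pitch_um))
      # events initiate within a single localized region (frame 1) and
      # progress into multiple modules distributed across the ROI; later
      # frames mix a motif-specific core pattern (shared modules persist
      # across the event, as in real data) with frame-specific structure,
      # so frames are correlated within the event yet temporally distinct
      core <- make_modular_pattern(config$grid_shape, config$wavelength_mm,
                                   config$pitch_um)
      w <- 0.85
      for (t in seq_len(nf)) {
        if (t == 1) {
          fp <- localized_footprint(config, config$motif_frame_area_mm2)
          score <- core
        } else {
          indep <- make_modular_pattern(config$grid_shape,
                                        config$wavelength_mm,
                                        config$pitch_um)
          score <- w * core + sqrt(1 - w^2) * indep
          fp <- clean_frame_mask(score > quantile(score, 1 - cov), min_px)
        }
        # graded amplitude (calcium signals are graded): the pattern value
        # modulates activity in [0.75, 1] x envelope within the footprint
        gr <- matrix(0, nrow(fp), ncol(fp))
        if (any(fp)) {
          sv <- score[fp]
          rng <- range(sv)
          g01 <- if (diff(rng) > 0) (sv - rng[1]) / diff(rng) else 1
          gr[fp] <- 0.75 + 0.25 * g01
        }
        act[, , t] <- gr * (config$amp * env[t])
      }
      act
    })
  })
}

make_motif_event <- function(cfg, library = NULL, motif_id = NULL) {
  if (is.null(library)) library <- make_motif_library(cfg)
  if (is.null(motif_id)) motif_id <- sample.int(length(library), 1)
  base <- library[[motif_id]]
  nf <- dim(base)[3]
  jit <- runif(nf, 0.9, 1.1)   # per-frame amplitude jitter, masks unchanged
  act <- base
  for (t in seq_len(nf)) act[, , t] <- base[, , t] * jit[t]
  list(activity = act, onset_mask = base[, , 1] > 0,
       record = tibble(kind = "motif", n_frames = nf, v_mm_s = NA_real_,
                       theta_deg = NA_real_, motif_id = as.integer(motif_id)))
}

#' Calcium indicator forward model
#'
#' Integrates planted (deconvolved-scale) activity through single-frame
#' exponential decay, `c_t = y_t + gamma * c_{t-1}`, then composes raw
#' fluorescence `F_t = baseline(t) * (1 + c_t) + noise` with an additive
#' slow sinusoidal baseline drift. Deconvolving the noiseless output
#' recovers the planted activity exactly.
#'
#' @param activity rows x cols x frames array of planted activity.
#' @param config a [sim_config()] (supplies gamma, baseline, drift, noise).
#' @param seed RNG seed for the noise (`NULL`: current stream).
#' @return A raw-stage [pixel_movie()].
#' @export
calcium_forward_model <- function(activity, config, seed = NULL) {
  d <- dim(activity)
  y <- matrix(activity, d[1] * d[2], d[3])
  t_s <- (seq_len(d[3]) - 1) * config$frame_ms / 1000
  b <- config$baseline_level +
    if (config$drift_amplitude > 0)
      config$drift_amplitude * sin(2 * pi * t_s / config$drift_period_s)
    else rep(0, d[3])
  f <- with_seed(seed,
                 .forward_model(y, config$gamma, rep_len(b, d[3]),
                                config$noise_sd))
  rm(y)
  dim(f) <- d
  pixel_movie(f, pitch_um = config$pitch_um,
              frame_ms = config$frame_ms, stage = "raw")
}

#' Synthesize a full ground-truth session
#'
#' Plants `n_events` events (static / wave / motif mix per the configured
#' fractions, counts rounded) separated by fully inactive gaps drawn
#' uniformly from `quiet_range_s`, then passes the session through the
#' calcium forward model.
#'
#' @param config a [sim_config()].
#' @param keep_activity keep the planted deconvolved-scale session array
#'   (memory: one extra session-sized array).
#' @return A list with `movie` (raw [pixel_movie()]), `truth` (tibble: one
#'   row per event with kind, frame range, planted parameters), `activity`
#'   (planted deconvolved-stage [pixel_movie()] or `NULL`),
#'   `onset_masks` (list of planted onset masks), and `config`.
#' @export
synthesize_session <- function(config, keep_activity = TRUE) {
  cfg <- config
  n <- cfg$n_events
  n_static <- round(n * cfg$static_fraction)
  n_wave <- round(n * cfg$wave_fraction)
  n_motif <- n - n_static - n_wave
  with_seed(cfg$seed, {
    kinds <- sample(rep(c("static", "wave", "motif"),
                        c(n_static, n_wave, n_motif)))
    library <- if (n_motif > 0) make_motif_library(cfg) else NULL
    motif_ids <- if (n_motif > 0)
      sample(rep_len(seq_along(library), n_motif)) else integer()
    gap_frames <- function()
      max(1L, as.integer(round(
        runif(1, cfg$quiet_range_s[1], cfg$quiet_range_s[2]) *
          1000 / cfg$frame_ms)))
    ev_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))
    events <- vector("list", n)
    mi <- 0L
    for (i in seq_len(n)) {
      id <- NULL
      if (n > 0 && kinds[i] == "motif") { mi <- mi + 1L; id <- motif_ids[mi] }
      events[[i]] <- make_event(kinds[i], cfg, seed = ev_seeds[i],
                                motif_library = library, motif_id = id)
    }
    gaps <- vapply(seq_len(n + 1), function(i) gap_frames(), integer(1))
    durs <- vapply(events, function(e) dim(e$activity)[3], numeric(1))
    total <- sum(gaps) + sum(durs)
    if (!is.null(cfg$session_s)) {
      need <- round(cfg$session_s * 1000 / cfg$frame_ms)
      if (total > need)
        abort(sprintf("events need %d frames but session_s allows %d",
                      total, need))
      total <- need
    }
    act <- array(0, c(cfg$grid_shape, total))
    t_start <- integer(n); t_end <- integer(n)
    cursor <- 0L
    for (i in seq_len(n)) {
      cursor <- cursor + gaps[i]
      t_start[i] <- cursor + 1L
      t_end[i] <- cursor + durs[i]
      act[, , t_start[i]:t_end[i]] <- events[[i]]$activity
      cursor <- t_end[i]
    }
    truth <- if (n > 0)
      dplyr::bind_rows(lapply(events, `[[`, "record")) else
      tibble(kind = character(), n_frames = numeric(), v_mm_s = numeric(),
             theta_deg = numeric(), motif_id = integer())
    truth$event_id <- seq_len(nrow(truth))
    truth$t_start <- t_start
    truth$t_end <- t_end
    movie <- calcium_forward_model(act, cfg, seed = NULL)
    out <- list(
      movie = movie,
      truth = truth[, c("event_id", "kind", "t_start", "t_end", "n_frames",
                        "v_mm_s", "theta_deg", "motif_id")],
      activity = if (keep_activity)
        pixel_movie(act, pitch_um = cfg$pitch_um, frame_ms = cfg$frame_ms,
                    stage = "deconvolved") else NULL,
      onset_masks = lapply(events, `[[`, "onset_mask"),
      config = cfg)
    out
  })
}
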