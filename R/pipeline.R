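#' Pipeline configuration
#'
#' Aggregates all stage parameters with their standard defaults:
#' gamma = 0.89, baseline rank 0.36 over 28.5 s, activity threshold 4 SD,
#' minimum component 0.028 mm^2, minimum event 1 mm^2, 9 onset dilations
#' (~420 um exclusion), band-pass SDs 23/194 um, 100 correlation
#' surrogates, 100 wave permutations, 1000 motif permutations with a
#' 99th-percentile threshold, 5-frame motifs, >= 10 events per cluster,
#' 10-minute coverage bins, <= 200 ms template events, top 7 groups with
#' >= 15 members, 8 decoding PCs, +/- 2000 ms offsets, 100 subsamples and
#' shuffles.
#'
#' @param ... named overrides of any default.
#' @param seed global seed; stochastic stages derive child seeds from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(
    gamma = 0.89, rank = 0.36, window_s = 28.5,
    k_sd = 4, min_component_mm2 = 0.028, min_event_mm2 = 1.0,
    n_dilate = 9, s_low_um = 23, s_high_um = 194,
    n_surrogates = 100, n_perm_wave = 100, min_wave_frames = 5,
    fov_diameter_mm = 3,
    n_perm_motif = 1000, motif_percentile = 99, motif_frames = 5,
    n_components = 20, min_cluster = 10, bin_min = 10,
    template_max_ms = 200, top_k = 7, min_members = 15,
    n_pc = 8, offsets_ms = seq(-2000, 2000, by = 20),
    n_subsample = 100, n_shuffle = 100,
    seed = as.integer(seed))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    abort(paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Preprocessing, event detection, spatial statistics, wave fitting, motif
#' clustering, and template grouping on a raw movie (or a synthetic
#' session). Stages write their tables to `out_dir` (when given) together
#' with a manifest recording the configuration hash and seed; a stage whose
#' output file already exists is reloaded, not recomputed, so a partially
#' deleted output directory resumes mid-pipeline.
#'
#' @param config a [pipeline_config()].
#' @param movie raw-stage [pixel_movie()], or `NULL` to simulate a session
#'   from `sim` first.
#' @param sim a [sim_config()] used when `movie` is `NULL`.
#' @param seed_px seed pixel for the correlation analysis (default: ROI
#'   centroid).
#' @param out_dir optional output directory for tables and the manifest.
#' @param decode run the (expensive) trajectory-decoding stage.
#' @return A list: `events` (table), `geometry_waves` (per-event geometry
#'   and wave fits), `wavelength_mm` (per-event estimates), `correlation`
#'   (`correlation_result` + long-range p value), `motifs`
#'   (`motif_clustering`), `template_groups`, `decoding` (or `NULL`),
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), movie = NULL,
                         sim = NULL, seed_px = NULL, out_dir = NULL,
                         decode = FALSE) {
  truth <- NULL
  if (is.null(movie)) {
    if (is.null(sim)) sim <- sim_config(seed = config$seed)
    session <- synthesize_session(sim, keep_activity = FALSE)
    movie <- session$movie
    truth <- session$truth
  }
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 8))
  stage <- stage_cache(out_dir)

  pp <- preprocess_movie(movie, gamma = config$gamma, rank = config$rank,
                         window_s = config$window_s)
  y <- pp$deconvolved
  events <- detect_events(y, k_sd = config$k_sd,
                          min_component_mm2 = config$min_component_mm2,
                          min_event_mm2 = config$min_event_mm2)
  ev_tab <- stage("events", function() event_table(events))

  gw <- stage("geometry_waves", function()
    fit_event_waves(events, n_perm = config$n_perm_wave,
                    min_frames = config$min_wave_frames,
                    v_max_mm_s = velocity_ceiling(config$fov_diameter_mm,
                                                  movie$frame_ms),
                    n_dilate = config$n_dilate, seed = seeds[1]))

  wl <- stage("wavelength", function() tibble(
    event_id = vapply(events, function(e) e$id, integer(1)),
    wavelength_mm = vapply(events, event_wavelength, numeric(1),
                           s_low_um = config$s_low_um,
                           s_high_um = config$s_high_um)))

  correlation <- NULL
  if (length(events) >= 10) {
    frames <- event_frame_stack(events, type = "max",
                                s_low_um = config$s_low_um,
                                s_high_um = config$s_high_um)
    if (is.null(seed_px)) {
      ctr <- which(movie$roi, arr.ind = TRUE)
      seed_px <- round(colMeans(ctr))
    }
    real <- correlation_map(frames, seed_px, movie$roi)
    sur <- surrogate_ensemble(frames, seed_px, movie$roi,
                              n_surrogates = config$n_surrogates,
                              seed = seeds[2])
    lr <- long_range_significance(real, sur, movie$roi, movie$pitch_um)
    correlation <- list(map = real, long_range = lr)
  }

  subset <- select_fixed_duration(events, geometry = gw,
                                  n_frames = config$motif_frames,
                                  s_low_um = config$s_low_um,
                                  s_high_um = config$s_high_um)
  motifs <- NULL
  if (length(subset$events) >= 10)
    motifs <- cluster_motifs(
      subset, t_total_min = n_frames(y) * y$frame_ms / 60000,
      n_components = config$n_components, n_perm = config$n_perm_motif,
      percentile = config$motif_percentile,
      min_cluster = config$min_cluster, bin_min = config$bin_min,
      seed = seeds[3])

  pool <- collect_frames(events, max_duration_ms = config$template_max_ms)
  groups <- NULL
  if (nrow(pool$info) > 0)
    groups <- build_template_groups(pool, top_k = config$top_k,
                                    min_members = config$min_members)

  decoding <- NULL
  if (decode && !is.null(groups) && length(groups) >= 2)
    decoding <- trajectory_decoding(groups, y,
                                    offsets_ms = config$offsets_ms,
                                    n_pc = config$n_pc,
                                    n_subsample = config$n_subsample,
                                    n_shuffle = config$n_shuffle,
                                    seed = seeds[4])

  manifest <- list(
    package_version = as.character(utils::packageVersion("spontdyn")),
    seed = config$seed, config_hash = rlang::hash(unclass(config)),
    n_frames = n_frames(movie), n_events = length(events),
    n_significant_waves = sum(gw$significant %in% TRUE),
    n_motif_clusters = if (is.null(motifs)) 0L else length(motifs$clusters),
    n_template_groups = length(groups %||% list()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    write_table_csv(ev_tab, file.path(out_dir, "events.csv"))
    write_table_csv(gw, file.path(out_dir, "geometry_waves.csv"))
    write_table_csv(wl, file.path(out_dir, "wavelength.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(events = ev_tab, geometry_waves = gw, wavelength = wl,
       correlation = correlation, motifs = motifs,
       template_groups = groups, decoding = decoding, truth = truth,
       manifest = manifest)
}

# tiny CSV-backed stage cache: recompute only when the file is absent
stage_cache <- function(out_dir) {
  function(name, fn) {
    if (is.null(out_dir)) return(fn())
    path <- file.path(out_dir, paste0(name, ".csv"))
    if (file.exists(path)) return(as_tibble(read.csv(path)))
    res <- fn()
    if (is.data.frame(res)) write_table_csv(res, path)
    res
  }
}

#' Band-passed single frames per event
#'
#' One frame per event for the correlation analysis: either the maximally
#' active frame or the within-event sum of frames, band-pass filtered.
#'
#' @param events list of `spont_event` objects.
#' @param type `"max"` (maximally active frame) or `"sum"` (within-event
#'   sum).
#' @param s_low_um,s_high_um band-pass SDs.
#' @return rows x cols x n_events array.
#' @export
event_frame_stack <- function(events, type = c("max", "sum"),
                              s_low_um = 23, s_high_um = 194) {
  type <- match.arg(type)
  e1 <- events[[1]]
  out <- array(NA_real_, c(dim(e1$masks)[1:2], length(events)))
  for (i in seq_along(events)) {
    e <- events[[i]]
    f <- switch(type,
                max = e$activity[, , max_active_frame(e), drop = TRUE],
                sum = apply(e$activity, c(1, 2), sum))
    out[, , i] <- bandpass(f, e$roi, e$pitch_um, s_low_um, s_high_um)
  }
  out
}

## ---- file formats ---------------------------------------------------------

#' Write / read a movie as multi-page TIFF
#'
#' Movies are stored as 16-bit multi-page TIFF with a linear scale recorded
#' in a JSON sidecar (`<path>.json`) together with ROI, pitch, frame
#' interval, and stage, so a read restores the movie to within 16-bit
#' quantization of the original values.
#'
#' @param movie a [pixel_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  lo <- min(movie$data); hi <- max(movie$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3]), function(t)
    (movie$data[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(lo = lo, scale = scale, pitch_um = movie$pitch_um,
               frame_ms = movie$frame_ms, stage = movie$stage,
               roi_rle = roi_to_rle(movie$roi))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  data <- array(0, d)
  for (t in seq_along(pages))
    data[, , t] <- pages[[t]] * meta$scale + meta$lo
  pixel_movie(data, roi = rle_to_roi(meta$roi_rle), pitch_um = meta$pitch_um,
              frame_ms = meta$frame_ms, stage = meta$stage)
}

roi_to_rle <- function(roi) {
  r <- rle(as.vector(roi))
  list(dim = dim(roi), lengths = r$lengths, values = r$values)
}

rle_to_roi <- function(x) {
  v <- inverse.rle(structure(list(lengths = x$lengths,
                                  values = as.logical(x$values)),
                             class = "rle"))
  matrix(v, x$dim[1], x$dim[2])
}

#' Write / read an ROI mask as PNG
#'
#' @param roi logical matrix.
#' @param path PNG path.
#' @return `path` (write) or logical matrix (read).
#' @export
write_roi_png <- function(roi, path) {
  png::writePNG(roi * 1, path)
  invisible(path)
}

#' @rdname write_roi_png
#' @export
read_roi_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

write_table_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a configuration as YAML
#'
#' Round-trips [sim_config()] or [pipeline_config()] objects losslessly.
#'
#' @param config configuration object.
#' @param path YAML file path.
#' @return `path` (write) or the restored configuration (read).
#' @export
write_config_yaml <- function(config, path) {
  cls <- class(config)[1]
  yaml::write_yaml(c(list(.class = cls), unclass(config)), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  nulls <- c("wave_theta_deg", "session_s")
  for (f in intersect(nulls, names(x))) if (length(x[[f]]) == 0)
    x[f] <- list(NULL)
  structure(x, class = cls)
}
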