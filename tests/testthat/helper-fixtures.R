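# Fixtures are generated in code and cached for the duration of the test
# run; every downstream check recovers quantities the generator planted.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# mixed static / wave / motif session on a 1.9 mm grid
mixed_session <- function() get_fixture("mixed", function() {
  cfg <- sim_config(grid_shape = c(40, 40), n_events = 50,
                    quiet_range_s = c(0.3, 1.5), seed = 7)
  ses <- synthesize_session(cfg)
  pp <- preprocess_movie(ses$movie)
  ev <- detect_events(pp$deconvolved)
  tab <- event_table(ev)
  geom <- dplyr::bind_rows(lapply(ev, event_geometry))
  matched <- merge(cbind(tab, is_static = geom$is_static), ses$truth,
                   by = "t_start")
  list(cfg = cfg, ses = ses, pp = pp, ev = ev, tab = tab, geom = geom,
       matched = matched)
})

# motif-only session: 4 repeated 5-frame sequences, 20 instances each
motif_session <- function() get_fixture("motif", function() {
  cfg <- sim_config(grid_shape = c(48, 48), n_events = 80,
                    static_fraction = 0, wave_fraction = 0,
                    motif_library_size = 4, quiet_range_s = c(0.2, 1.2),
                    seed = 9)
  ses <- synthesize_session(cfg)
  pp <- preprocess_movie(ses$movie)
  ev <- detect_events(pp$deconvolved)
  tab <- event_table(ev)
  matched <- merge(tab, ses$truth, by = "t_start")
  subset <- select_fixed_duration(ev)
  planted_id <- matched$motif_id[match(subset$event_ids,
                                       matched$event_id.x)]
  mc <- cluster_motifs(subset,
                       t_total_min = dim(ses$movie$data)[3] *
                         ses$movie$frame_ms / 60000,
                       n_perm = 200, seed = 5)
  list(cfg = cfg, ses = ses, pp = pp, ev = ev, matched = matched,
       subset = subset, planted_id = planted_id, mc = mc)
})

# template groups + decoding inputs built from the motif session
template_groups_fixture <- function() get_fixture("templates", function() {
  ms <- motif_session()
  pool <- collect_frames(ms$ev)
  groups <- suppressWarnings(
    build_template_groups(pool, top_k = 4, min_members = 8))
  list(pool = pool, groups = groups)
})

# a hand-built spont_event for unit checks
toy_event <- function(masks, activity = NULL, frame_ms = 20,
                      pitch_um = 46.9, t_start = 1L) {
  if (is.null(activity)) activity <- masks * 1
  roi <- matrix(TRUE, dim(masks)[1], dim(masks)[2])
  spontdyn:::new_event(t_start, t_start + dim(masks)[3] - 1L, masks,
                       activity, frame_ms, pitch_um, roi, FALSE, 1L)
}

# adjusted Rand index between two labelings (independent of any package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ij <- si * sj / n2
  (sij - exp_ij) / ((si + sj) / 2 - exp_ij)
}

# brute-force radially averaged spatial autocorrelation (direct shifts),
# the independent oracle for the FFT implementation
brute_radial_acf <- function(p, maxlag = 15) {
  nr <- nrow(p); nc <- ncol(p)
  pm <- p - mean(p)
  vals <- list(); bins <- list()
  for (di in -maxlag:maxlag) for (dj in -maxlag:maxlag) {
    i1 <- max(1, 1 - di):min(nr, nr - di)
    j1 <- max(1, 1 - dj):min(nc, nc - dj)
    vals[[length(vals) + 1]] <-
      cor(as.vector(pm[i1, j1]), as.vector(pm[i1 + di, j1 + dj]))
    bins[[length(bins) + 1]] <- round(sqrt(di^2 + dj^2))
  }
  prof <- tapply(unlist(vals), unlist(bins), mean)
  as.numeric(prof)
}

first_local_min_idx <- function(v) {
  i <- 2L
  while (i < length(v)) {
    if (v[i] < v[i - 1] && v[i] < v[i + 1]) return(i)
    i <- i + 1L
  }
  NA_integer_
}
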