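test_that("modular patterns are deterministic, zero-mean, unit-SD", {
  p1 <- make_modular_pattern(c(48, 48), 0.69, 46.9, seed = 2)
  p2 <- make_modular_pattern(c(48, 48), 0.69, 46.9, seed = 2)
  expect_identical(p1, p2)
  p3 <- make_modular_pattern(c(48, 48), 0.69, 46.9, seed = 3)
  expect_false(identical(p1, p3))
  expect_lt(abs(mean(p1)), 1e-12)
  expect_equal(sd(p1), 1, tolerance = 1e-12)
  expect_error(make_modular_pattern(c(48, 48), 0.09, 46.9), "Nyquist")
})

test_that("pattern wavelength calibration holds under the brute-force radial ACF oracle", {
  mins <- vapply(1:8, function(s) {
    p <- make_modular_pattern(c(64, 64), 0.69, 46.9, seed = s)
    idx <- first_local_min_idx(brute_radial_acf(p, maxlag = 12))
    (idx - 1) * 46.9 / 1000          # bin index 1 is lag 0
  }, numeric(1))
  # first minimum near lambda / 2 = 0.345 mm, within one pixel pitch
  expect_lt(abs(median(mins) - 0.345), 46.9 / 1000)
})

test_that("planted static events stay inside their onset footprint", {
  cfg <- sim_config(grid_shape = c(40, 40), seed = 1)
  e <- make_event("static", cfg, seed = 4)
  expect_true(all(e$activity[, , 1][e$onset_mask] > 0))
  for (t in seq_len(dim(e$activity)[3]))
    expect_true(all((e$activity[, , t] > 0) <= e$onset_mask))
  expect_identical(e$record$kind, "static")
  expect_error(make_event("spiral", cfg), "unknown event kind")
})

test_that("planted wave onsets follow the planar model before noise", {
  cfg <- sim_config(grid_shape = c(64, 64), wave_theta_deg = 0,
                    onset_jitter_ms = 0, seed = 1)
  e <- make_event("wave", cfg, seed = 11)
  ev <- toy_event(e$activity > 0, e$activity)
  ot <- onset_times(ev)
  # along +x at 32 mm/s the continuous onset ramp is 31.25 ms per mm;
  # with one row, regression of t_on on x recovers the slope up to the
  # 20 ms frame quantization
  fitc <- coef(lm(t_on_ms ~ I(col * 46.9 / 1000), data = ot))
  expect_equal(unname(fitc[2]), 1000 / 32, tolerance = 0.12)
  # all pixels in one column activate simultaneously for theta = 0
  per_col <- tapply(ot$t_on_ms, ot$col, function(v) diff(range(v)))
  expect_true(all(per_col == 0))
})

test_that("motif instances repeat their library sequence with identical masks", {
  cfg <- sim_config(grid_shape = c(40, 40), seed = 1)
  lib <- make_motif_library(cfg, seed = 6)
  expect_length(lib, cfg$motif_library_size)
  e1 <- make_event("motif", cfg, seed = 21, motif_library = lib,
                   motif_id = 3)
  e2 <- make_event("motif", cfg, seed = 22, motif_library = lib,
                   motif_id = 3)
  expect_identical(e1$activity > 0, e2$activity > 0)
  r <- cor(as.vector(e1$activity), as.vector(e2$activity))
  expect_gt(r, 0.99)
})

test_that("calcium forward model composes decay, baseline, drift and noise", {
  cfg <- sim_config(grid_shape = c(4, 4), noise_sd = 0,
                    drift_amplitude = 0, seed = 1)
  act <- array(0, c(4, 4, 10))
  act[2, 2, 3] <- 1                     # unit impulse at frame 3
  mov <- calcium_forward_model(act, cfg)
  tr <- mov$data[2, 2, ] / cfg$baseline_level - 1
  expect_equal(tr[3:6], 0.89^(0:3), tolerance = 1e-12)
  expect_equal(tr[1:2], c(0, 0))
  # zero activity, drift off: constant baseline
  flat <- calcium_forward_model(array(0, c(4, 4, 10)), cfg)
  expect_true(all(flat$data == cfg$baseline_level))
})

test_that("dF/F plus deconvolution exactly inverts the noiseless forward model", {
  cfg <- sim_config(grid_shape = c(40, 40), n_events = 12,
                    quiet_range_s = c(0.2, 0.6), noise_sd = 0,
                    drift_amplitude = 0, seed = 5)
  ses <- synthesize_session(cfg)
  b <- spontdyn:::movie_like(ses$movie,
                             array(cfg$baseline_level,
                                   dim(ses$movie$data)), "baseline")
  y <- deconvolve(dff(ses$movie, b), gamma = cfg$gamma)
  expect_lt(max(abs(y$data - ses$activity$data)), 1e-9)
})

test_that("session assembly respects counts, gaps and determinism", {
  cfg <- sim_config(grid_shape = c(40, 40), n_events = 29,
                    static_fraction = 0.069, wave_fraction = 0.5,
                    quiet_range_s = c(0.2, 0.5), seed = 13)
  ses <- synthesize_session(cfg)
  expect_equal(sum(ses$truth$kind == "static"), round(29 * 0.069))
  expect_equal(sum(ses$truth$kind == "wave"), round(29 * 0.5))
  # planted ranges are disjoint with at least one quiet frame between
  expect_true(all(diff(ses$truth$t_start) > 0))
  expect_true(all(ses$truth$t_start[-1] > ses$truth$t_end[-29] + 1))
  # identical config -> bitwise identical session
  ses2 <- synthesize_session(cfg)
  expect_identical(ses$movie$data, ses2$movie$data)
  expect_identical(ses$truth, ses2$truth)
  # empty session: pure baseline + noise, no truth rows
  cfg0 <- sim_config(grid_shape = c(8, 8), n_events = 0, noise_sd = 0,
                     drift_amplitude = 0, seed = 1)
  ses0 <- synthesize_session(cfg0)
  expect_equal(nrow(ses0$truth), 0)
  expect_true(all(ses0$movie$data == cfg0$baseline_level))
  # fixed session length too short for the events -> error
  cfgs <- sim_config(grid_shape = c(40, 40), n_events = 20,
                     quiet_range_s = c(1, 2), session_s = 3, seed = 1)
  expect_error(synthesize_session(cfgs), "session_s")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(static_fraction = 0.6, wave_fraction = 0.6),
               "static_fraction")
  expect_error(sim_config(wavelength_mm = 0.05), "Nyquist|pitch")
  expect_error(sim_config(gamma = 1.2), "gamma")
})
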