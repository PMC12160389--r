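test_that("propagation area uses a 9-iteration Chebyshev exclusion zone", {
  # all activity inside the onset footprint: PA = 0, static
  m <- array(FALSE, c(40, 40, 3))
  m[10:15, 10:15, ] <- TRUE
  g <- event_geometry(toy_event(m))
  apx <- pixel_area_mm2(46.9)
  expect_equal(g$pa_mm2, 0)
  expect_true(g$is_static)
  expect_equal(g$a_active_mm2, 36 * apx, tolerance = 1e-9)
  expect_equal(g$a_on_mm2, 36 * apx, tolerance = 1e-9)
  # one later pixel at Chebyshev distance 10 from the onset pixel:
  # outside the dilated mask, PA = one pixel area
  m2 <- array(FALSE, c(40, 40, 2))
  m2[20, 20, 1] <- TRUE
  m2[20, 30, 2] <- TRUE
  g2 <- event_geometry(toy_event(m2))
  expect_equal(g2$pa_mm2, pixel_area_mm2(46.9), tolerance = 1e-9)
  expect_false(g2$is_static)
  # at distance 9 it is inside the exclusion zone
  m3 <- array(FALSE, c(40, 40, 2))
  m3[20, 20, 1] <- TRUE
  m3[20, 29, 2] <- TRUE
  expect_true(event_geometry(toy_event(m3))$is_static)
  # PA is monotone nonincreasing in the dilation count
  fx <- mixed_session()
  e <- fx$ev[[which.max(fx$tab$n_frames)]]
  pas <- vapply(c(3, 6, 9, 12), function(k)
    event_geometry(e, n_dilate = k)$pa_mm2, numeric(1))
  expect_true(all(diff(pas) <= 0))
})

test_that("onset times are the first active frame in event-relative ms", {
  m <- array(FALSE, c(6, 6, 5))
  m[2, 2, 1:5] <- TRUE                  # onset-frame pixel
  m[3, 3, 4:5] <- TRUE                  # first active on event frame 4
  ot <- onset_times(toy_event(m))
  expect_equal(ot$t_on_ms[ot$row == 2 & ot$col == 2], 0)
  expect_equal(ot$t_on_ms[ot$row == 3 & ot$col == 3], 60)
})

test_that("wavefront fits recover planted waves and match a dense grid", {
  cfg <- sim_config(grid_shape = c(64, 64), wave_theta_deg = 90,
                    onset_jitter_ms = 0, seed = 1)
  e <- make_event("wave", cfg, seed = 3)
  ev <- toy_event(e$activity > 0, e$activity)
  fit <- fit_linear_wave(onset_times(ev), ev$roi)
  expect_lt(abs(fit$v_mm_s - 32) / 32, 0.05)
  dth <- abs((fit$theta_deg - 90 + 180) %% 360 - 180)
  expect_lt(dth, 5)
  expect_lte(fit$mse_ms2, (20 / 2)^2)   # within frame quantization
  expect_equal(fit$theta_axial_deg, fit$theta_deg %% 180)
  # refined optimum is at least as good as an exhaustive fine grid
  ot <- onset_times(ev)
  idx <- which(ev$roi, arr.ind = TRUE); ctr <- colMeans(idx)
  x <- (ot$col - ctr[2]) * 46.9 / 1000; y <- (ot$row - ctr[1]) * 46.9 / 1000
  dense <- Inf
  for (v in exp(seq(log(10), log(100), length.out = 60)))
    for (th in seq(0, 2 * pi, length.out = 181)) {
      proj <- (x * cos(th) + y * sin(th)) / v * 1000
      dense <- min(dense, mean((ot$t_on_ms - proj -
                                  mean(ot$t_on_ms - proj))^2))
    }
  expect_lte(fit$mse_ms2, dense + 1e-6)
})

test_that("wavefront fitting is scale- and rotation-equivariant", {
  set.seed(7)
  roi <- matrix(TRUE, 41, 41)
  idx <- expand.grid(row = seq(6, 36, by = 2), col = seq(6, 36, by = 2))
  x <- (idx$col - 21) * 46.9 / 1000; y <- (idx$row - 21) * 46.9 / 1000
  t_on <- (x * cos(0.5) + y * sin(0.5)) / 25 * 1000 +
    rnorm(nrow(idx), 0, 2)
  ons <- tibble::tibble(row = idx$row, col = idx$col, t_on_ms = t_on)
  f1 <- fit_linear_wave(ons, roi)
  # doubling all onset times halves the speed
  f2 <- fit_linear_wave(dplyr::mutate(ons, t_on_ms = 2 * t_on_ms), roi)
  expect_equal(f2$v_mm_s, f1$v_mm_s / 2, tolerance = 0.02)
  # rotating the pixel grid by 90 degrees rotates theta by 90
  ons90 <- tibble::tibble(row = idx$col, col = 42 - idx$row,
                          t_on_ms = t_on)
  f3 <- fit_linear_wave(ons90, roi)
  dth <- (f3$theta_deg - f1$theta_deg) %% 360
  expect_lt(abs(dth - 90), 3)    # (x, y) -> (-y, x) rotates theta by +90
  # identical onsets: degenerate, speed undefined
  fd <- fit_linear_wave(dplyr::mutate(ons, t_on_ms = 5), roi)
  expect_true(fd$degenerate)
  expect_true(is.na(fd$v_mm_s))
})

test_that("permutation test separates planted waves from shuffled ones", {
  fx <- mixed_session()
  waves <- fx$matched[fx$matched$kind == "wave" &
                        fx$matched$n_frames.x >= 5, ]
  ids <- head(waves$event_id.x, 8)
  sig <- vapply(ids, function(i)
    wave_significance(fx$ev[[i]], n_perm = 40,
                      seed = 100 + i)$significant, logical(1))
  expect_gte(mean(sig), 0.75)
  # frame-shuffled copies should almost never pass
  set.seed(77)
  sig_null <- vapply(head(ids, 6), function(i) {
    e <- fx$ev[[i]]
    e$masks <- e$masks[, , sample(dim(e$masks)[3]), drop = FALSE]
    wave_significance(e, n_perm = 40, seed = 200 + i)$significant
  }, logical(1))
  expect_lte(sum(sig_null), 1)
  # events under 5 frames are excluded, not failed
  short <- fx$ev[[which(fx$tab$n_frames == 2)[1]]]
  expect_true(is.na(wave_significance(short, n_perm = 10)$significant))
})

test_that("velocity ceiling is field-of-view size over frame interval", {
  expect_identical(velocity_ceiling(3, 20), 150)
  expect_identical(velocity_ceiling(6, 20), 300)
  expect_identical(velocity_ceiling(3, 40), 75)
  expect_error(velocity_ceiling(-1, 20))
})

test_that("axial statistics match closed-form circular results", {
  # maximal concentration: all angles equal
  s1 <- suppressWarnings(axial_direction_stats(rep(40, 30)))
  expect_lt(s1$rayleigh_p, 1e-6)
  expect_equal(s1$mean_axis_deg, 40, tolerance = 1e-6)
  expect_lt(s1$binomial_p, 1e-6)        # all 30 along one direction
  # uniform axial angles: no axis
  s2 <- axial_direction_stats(seq(0, 179, length.out = 36))
  expect_gt(s2$rayleigh_p, 0.05)
  expect_true(is.na(s2$binomial_p))
  # half at 30, half at 210: strong 30-degree axis, balanced directions
  s3 <- axial_direction_stats(rep(c(30, 210), each = 20))
  expect_lt(s3$rayleigh_p, 1e-6)
  expect_equal(s3$mean_axis_deg, 30, tolerance = 1e-6)
  expect_equal(s3$n_along, 20)
  expect_equal(s3$binomial_p, 1, tolerance = 1e-9)
  # doubled-angle resultant agrees with the direct formula
  th <- c(10, 50, 170, 20)
  phi <- 2 * (th %% 180) * pi / 180
  rbar <- sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
  s4 <- suppressWarnings(axial_direction_stats(th))
  expect_equal(s4$rayleigh_r, rbar, tolerance = 1e-12)
})

test_that("the per-event wave table flags exclusions coherently", {
  fx <- mixed_session()
  gw <- fit_event_waves(head(fx$ev, 12), n_perm = 20, seed = 4)
  expect_true(all(!gw$fitted[gw$is_static]))
  expect_true(all(is.na(gw$v_mm_s[!gw$fitted])))
  fitted <- gw[gw$fitted, ]
  expect_true(all(fitted$n_frames >= 5))
  expect_true(all(fitted$v_mm_s > 0))
  expect_true(all(fitted$theta_deg >= 0 & fitted$theta_deg < 360))
})
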