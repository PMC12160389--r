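test_that("difference-of-Gaussians band-pass removes DC and balances an impulse", {
  expect_true(all(abs(bandpass(matrix(5, 30, 30))) < 1e-10))
  f <- matrix(0, 31, 31); f[16, 16] <- 1
  bp <- bandpass(f)
  expect_gt(bp[16, 16], 0)
  expect_lt(min(bp[12:20, 12:20]), 0)       # negative surround
  expect_lt(abs(sum(bp)), 0.05 * bp[16, 16])  # DoG integrates to ~0
})

test_that("band-pass gain at the modular wavelength matches the analytic DoG transfer", {
  lam <- 0.69
  x_mm <- (1:96) * 46.9 / 1000
  f <- matrix(cos(2 * pi * x_mm / lam), 64, 96, byrow = TRUE)
  bp <- bandpass(f)
  ctr <- bp[20:44, 30:66]                   # avoid zero-padded edges
  gain <- sd(ctr) / sd(f[20:44, 30:66])
  H <- function(fq, s) exp(-2 * pi^2 * (s / 1000)^2 * fq^2)
  h_lam <- H(1 / lam, 23) - H(1 / lam, 194)
  expect_equal(gain, h_lam, tolerance = 0.05)
  # and within 3 dB of the passband peak
  fq <- seq(0.1, 8, by = 0.01)
  h_peak <- max(H(fq, 23) - H(fq, 194))
  expect_gt(gain, h_peak / sqrt(2))
  expect_error(bandpass(f, s_low_um = 200, s_high_um = 100), "s_low")
})

test_that("correlation maps equal brute-force per-pixel Pearson", {
  set.seed(4)
  fr <- array(rnorm(12 * 12 * 25), c(12, 12, 25))
  res <- suppressWarnings(correlation_map(fr, c(5, 7)))
  x <- matrix(fr, 144, 25)
  brute <- apply(x, 1, function(v) cor(x[5 + (7 - 1) * 12, ], v))
  expect_equal(as.vector(res$map), brute, tolerance = 1e-12)
  expect_equal(res$map[5, 7], 1)
  # alternating sign pattern: every pixel perfectly (anti)correlated
  pat <- matrix(rnorm(64), 8, 8)
  alt <- array(NA_real_, c(8, 8, 12))
  for (e in 1:12) alt[, , e] <- pat * (-1)^e
  m2 <- suppressWarnings(correlation_map(alt, c(3, 3)))
  expect_true(all(abs(abs(m2$map) - 1) < 1e-10))
  # zero-variance seed is an error
  z <- array(rnorm(64 * 5), c(8, 8, 5)); z[2, 2, ] <- 0
  expect_error(suppressWarnings(correlation_map(z, c(2, 2))),
               "zero variance")
})

test_that("identity transform reproduces the real correlation map", {
  roi <- matrix(TRUE, 21, 21)
  src <- spontdyn:::rotation_index(roi, 0, FALSE, FALSE)
  expect_identical(src, seq_len(21 * 21))
  # radially symmetric smooth frames are invariant under the surrogate
  # transforms up to nearest-neighbour rounding
  ctr <- 11
  r <- sqrt(outer((1:21 - ctr)^2, (1:21 - ctr)^2, `+`))
  droi <- r <= 9.5
  g1 <- exp(-(r - 4)^2 / 50); g2 <- exp(-(r - 8)^2 / 72)
  set.seed(6)
  fr <- array(NA_real_, c(21, 21, 30))
  for (e in 1:30) fr[, , e] <- rnorm(1) * g1 + rnorm(1) * g2
  real <- correlation_map(fr, c(ctr, ctr), droi)
  sur <- surrogate_ensemble(fr, c(ctr, ctr), droi, n_surrogates = 3,
                            seed = 2)
  for (s in sur) {
    ok <- !is.na(s$map) & !is.na(real$map)
    expect_gt(mean(ok[droi]), 0.8)
    expect_lt(quantile(abs(s$map[ok] - real$map[ok]), 0.9, names = FALSE),
              0.15)
  }
})

test_that("long-range p value counts surrogate medians at or above the real one", {
  mk_map <- function(peak) {
    r <- sqrt(outer((1:72 - 36)^2, (1:72 - 36)^2, `+`)) * 46.9 / 1000
    m <- exp(-3 * r)                                 # smooth seed falloff
    m[36, 68] <- peak                                # maximum at 1.5 mm
    m[36, 36] <- 1
    structure(list(map = m, seed_px = c(36, 36), n_events = 50),
              class = "correlation_result")
  }
  roi <- matrix(TRUE, 72, 72)
  real <- mk_map(0.9)
  lows <- lapply(1:20, function(i) mk_map(0.3))
  highs <- lapply(1:20, function(i) mk_map(0.95))
  expect_equal(long_range_significance(real, lows, roi)$p_value, 0)
  expect_equal(long_range_significance(real, highs, roi)$p_value, 1)
  # ROI too small to contain the band: no maxima -> undefined, not zero
  tiny <- structure(list(map = matrix(rnorm(100), 10, 10),
                         seed_px = c(5, 5), n_events = 50),
                    class = "correlation_result")
  out <- long_range_significance(tiny, lows[1:3],
                                 matrix(TRUE, 10, 10))
  expect_true(out$undefined)
  expect_true(is.na(out$p_value))
})

test_that("surrogate long-range false positives stay near the nominal 5%", {
  # frames with no systematic inter-relation, on a disk ROI (rotations
  # are isometries of the disk, so real and surrogate maps match in law)
  set.seed(31)
  ctr <- (64 + 1) / 2
  droi <- sqrt(outer((1:64 - ctr)^2, (1:64 - ctr)^2, `+`)) <= 64 * 0.48
  ps <- vapply(1:40, function(i) {
    fr <- array(NA_real_, c(64, 64, 24))
    for (e in 1:24)
      fr[, , e] <- make_modular_pattern(c(64, 64), 0.69, 46.9)
    real <- correlation_map(fr, c(32, 32), droi)
    sur <- surrogate_ensemble(fr, c(32, 32), droi, n_surrogates = 19,
                              seed = 1000 + i)
    long_range_significance(real, sur, droi)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 25)
  # nominal rate 1/20 under exchangeability: expect ~2 hits, tolerate 5
  expect_lte(sum(ps < 0.05), 5)
  expect_gt(mean(ps), 0.2)   # and p values spread over the unit range
})

test_that("planted long-range motif structure beats the surrogate ensemble", {
  fx <- motif_session()
  frames <- event_frame_stack(fx$ev, "max")
  ctr <- (48 + 1) / 2
  roi <- sqrt(outer((1:48 - ctr)^2, (1:48 - ctr)^2, `+`)) <= 48 * 0.48
  real <- correlation_map(frames, c(14, 14), roi)
  sur <- surrogate_ensemble(frames, c(14, 14), roi, n_surrogates = 40,
                            seed = 3)
  lr <- long_range_significance(real, sur, roi)
  expect_false(lr$undefined)
  expect_lte(lr$p_value, 0.05)
  # single-frame and summed-event maps are strongly positively related
  roi <- fx$ses$movie$roi
  fsum <- event_frame_stack(fx$ev, "sum")
  rs <- vapply(list(c(12, 12), c(12, 36), c(24, 24), c(36, 12),
                    c(36, 36)), function(sp) {
    m1 <- correlation_map(frames, sp, roi)$map
    m2 <- correlation_map(fsum, sp, roi)$map
    ok <- !is.na(m1) & !is.na(m2)
    cor(m1[ok], m2[ok])
  }, numeric(1))
  expect_gt(median(rs), 0.5)
})

test_that("wavelength is twice the first radial-autocorrelation minimum", {
  wl <- vapply(1:10, function(s)
    wavelength_frame(bandpass(make_modular_pattern(c(64, 64), 0.69,
                                                   seed = s))),
    numeric(1))
  expect_lt(abs(median(wl) - 0.69), 46.9 / 1000)
  # scale invariance of the normalized autocorrelation
  p <- bandpass(make_modular_pattern(c(64, 64), 0.69, seed = 3))
  expect_identical(wavelength_frame(p), wavelength_frame(5 * p))
  # no minimum inside the ROI -> NA
  ramp <- outer(1:20, 1:20, `+`) * 1.0
  expect_true(is.na(wavelength_frame(ramp)))
  # FFT profile's first minimum agrees with the direct-shift oracle
  pat <- make_modular_pattern(c(64, 64), 0.69, seed = 5)
  fftmin <- first_local_min_idx(spontdyn:::radial_autocorr(
    pat, matrix(TRUE, 64, 64))$r)
  brutemin <- first_local_min_idx(brute_radial_acf(pat, maxlag = 12))
  expect_lte(abs(fftmin - brutemin), 1)
})
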