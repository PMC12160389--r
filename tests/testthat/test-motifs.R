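test_that("fixed-duration selection keeps only 5-frame dynamic events", {
  fx <- mixed_session()
  sub <- select_fixed_duration(fx$ev)
  lens <- fx$tab$n_frames[match(sub$event_ids, fx$tab$event_id)]
  expect_true(all(lens == 5))
  statics <- fx$tab$event_id[fx$geom$is_static]
  expect_false(any(sub$event_ids %in% statics))
  expect_equal(dim(sub$frames)[2], 5)
  # 5 frames at 20 ms = 100 ms
  expect_true(all(fx$tab$duration_ms[match(sub$event_ids,
                                           fx$tab$event_id)] == 100))
})

test_that("PCA denoising reconstructs low-rank data and preserves identity", {
  set.seed(12)
  basis <- matrix(rnorm(10 * 200), 10, 200)
  scores <- matrix(rnorm(30 * 10), 30, 10)
  fr <- array(NA_real_, c(30, 5, 200))
  for (t in 1:5) fr[, t, ] <- scores %*% basis    # rank 10 per position
  sub <- structure(list(frames = fr), class = "motif_subset")
  v <- denoise_and_vectorize(sub, n_components = 20)
  expect_equal(v, cbind(fr[, 1, ], fr[, 2, ], fr[, 3, ], fr[, 4, ],
                        fr[, 5, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated events give identical vectors with r = 1
  fr[2, , ] <- fr[1, , ]
  v2 <- denoise_and_vectorize(structure(list(frames = fr),
                                        class = "motif_subset"), 20)
  expect_equal(cor(v2[1, ], v2[2, ]), 1, tolerance = 1e-12)
  # pairwise correlations equal brute-force Pearson on the vectors
  cm <- event_correlations(v2)
  expect_equal(cm, cor(t(v2)), tolerance = 1e-10)
  expect_true(isSymmetric(cm))
  expect_true(all(diag(cm) == 1))
})

test_that("the within-timestep null flags about 1% of structureless pairs", {
  set.seed(20)
  n_ev <- 60; npx <- 240
  means <- lapply(1:5, function(t) rnorm(npx))
  fr <- array(NA_real_, c(n_ev, 5, npx))
  for (t in 1:5)
    fr[, t, ] <- matrix(means[[t]], n_ev, npx, byrow = TRUE) +
      matrix(rnorm(n_ev * npx), n_ev)
  sub <- structure(list(frames = fr), class = "motif_subset")
  v <- denoise_and_vectorize(sub, n_components = 20)
  null <- within_timestep_null(v, n_perm = 150, seed = 8)
  cm <- event_correlations(v)
  frac <- mean(cm[lower.tri(cm)] > null$threshold)
  expect_gt(frac, 0.001)
  expect_lt(frac, 0.03)
  # determinism
  null2 <- within_timestep_null(v, n_perm = 150, seed = 8)
  expect_identical(null$threshold, null2$threshold)
  # single-permutation sanity path
  expect_no_error(within_timestep_null(v[1:12, ], n_perm = 1, seed = 1))
})

test_that("repeat counts and frequencies follow their definitions", {
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.9
  cm[1, 3] <- cm[3, 1] <- 0.9
  cm[2, 3] <- cm[3, 2] <- 0.9
  r <- repeats_and_frequency(cm, 0.5)
  expect_equal(r$repeats, c(2L, 2L, 2L))
  expect_equal(r$frequency, rep(2 / 3, 3))
  r2 <- repeats_and_frequency(cm, 0.95)
  expect_equal(r2$repeats, c(0L, 0L, 0L))
})

test_that("greedy clustering extracts blocks by repeat count and stops at 10", {
  n <- 55
  lab <- rep(1:3, c(30, 20, 5))
  cm <- outer(lab, lab, `==`) * 0.9
  diag(cm) <- 1
  cl <- greedy_cluster(cm, 0.5, min_cluster = 10)
  expect_length(cl, 2)
  expect_equal(lengths(cl), c(30L, 20L))
  expect_equal(cl[[1]], 1:30)
  # no above-threshold pair: no clusters; disjointness
  expect_length(greedy_cluster(diag(10), 0.5), 0)
  expect_equal(anyDuplicated(unlist(cl)), 0)
})

test_that("planted motifs are recovered as clusters with high adjusted Rand", {
  fx <- motif_session()
  lab <- spontdyn:::cluster_labels(fx$mc$clusters,
                                   length(fx$subset$events))
  keep <- !is.na(lab) & !is.na(fx$planted_id)
  expect_gt(adjusted_rand(fx$planted_id[keep], lab[keep]), 0.8)
  expect_gte(length(fx$mc$clusters), 3)
  # median repetition frequency reflects the planted 20 instances
  expect_gt(glance(fx$mc)$median_frequency, 0.1)
})

test_that("temporal coverage metrics match hand computation", {
  tc <- temporal_coverage(c(5, 25, 95), 100, bin_min = 10)
  expect_equal(tc$fr, 0.9)
  expect_equal(tc$fb, 3 / 10)
  tc2 <- temporal_coverage(c(0, 100), 100)
  expect_equal(tc2$fr, 1)
  tc3 <- temporal_coverage(c(12, 13, 14), 100)
  expect_equal(tc3$fb, 1 / 10)
  expect_lt(tc3$fr, 0.03)
})

test_that("silhouettes match the brute-force pairwise computation", {
  set.seed(15)
  v <- rbind(matrix(rnorm(20, 0), 10, 2),
             matrix(rnorm(20, 6), 10, 2))
  lab <- rep(1:2, each = 10)
  got <- clustering_quality(v, list(greedy = lab, same = lab))
  # brute force a_i / b_i
  d <- as.matrix(dist(v))
  sil <- vapply(1:20, function(i) {
    own <- lab == lab[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got$silhouette[1], mean(sil), tolerance = 1e-10)
  expect_equal(got$silhouette_diff_pct[2], 0)
  expect_gt(got$silhouette[1], 0.8)      # well-separated tight blobs
  # alternative clusterings at matched k are comparable on separable data
  alts <- cluster_alternatives(v, k = 2, seed = 3)
  q <- clustering_quality(v, c(list(greedy = lab), alts))
  expect_true(all(abs(q$silhouette_diff_pct) < 20))
  expect_error(clustering_quality(v, list(greedy = rep(1, 20))),
               "fewer than two")
})

test_that("frame shuffling destroys membership for ordered motifs only", {
  fx <- motif_session()
  fs <- frame_shuffle_control(fx$mc$vectors, fx$mc$clusters,
                              fx$mc$threshold, seed = 6)
  expect_lte(fs$retained_frac, 0.2)
  expect_equal(nrow(fs$per_cluster), length(fx$mc$clusters))
  # reproducible under the same seed
  fs2 <- frame_shuffle_control(fx$mc$vectors, fx$mc$clusters,
                               fx$mc$threshold, seed = 6)
  expect_identical(fs$retained_frac, fs2$retained_frac)
  # time-symmetric events (all frames identical) always survive: the
  # deranged vector is bitwise the original
  set.seed(30)
  pats <- matrix(rnorm(2 * 20), 2, 20)           # one pattern per cluster
  lab <- rep(1:2, each = 12)
  frame <- pats[lab, ] + 0.1 * matrix(rnorm(24 * 20), 24, 20)
  v_sym <- frame[, rep(1:20, 5)]                 # 5 identical frames each
  cl <- list(1:12, 13:24)
  fs3 <- frame_shuffle_control(v_sym, cl, threshold = 0.5,
                               n_positions = 5, seed = 2)
  expect_equal(fs3$retained_frac, 1)
})
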