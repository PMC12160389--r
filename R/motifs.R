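#' Select fixed-duration dynamic events
#'
#' The motif analysis compares events frame by frame, so it is restricted
#' to dynamic events (PA > 0) of exactly `n_frames` frames (5 frames =
#' 100 ms at 50 Hz). Each retained frame is band-pass filtered to
#' emphasize modular structure.
#'
#' @param events list of `spont_event` objects.
#' @param geometry optional precomputed [event_geometry()] table.
#' @param n_frames required event length (default 5).
#' @param dynamic_only keep only PA > 0 events (default TRUE).
#' @param s_low_um,s_high_um band-pass SDs, micrometers.
#' @return A `motif_subset`: list with `events` (the retained events),
#'   `frames` (n_events x n_frames x n_roi_px array of band-passed ROI
#'   activity), `event_ids`, `t_start_min` (initiation times in minutes),
#'   `roi`, and geometry columns.
#' @export
select_fixed_duration <- function(events, geometry = NULL, n_frames = 5,
                                  dynamic_only = TRUE,
                                  s_low_um = 23, s_high_um = 194) {
  if (is.null(geometry))
    geometry <- dplyr::bind_rows(lapply(events, event_geometry))
  len_ok <- vapply(events, event_n_frames, numeric(1)) == n_frames
  dyn_ok <- if (dynamic_only) !geometry$is_static else TRUE
  keep <- which(len_ok & dyn_ok)
  events <- events[keep]
  if (length(events) == 0)
    return(structure(list(events = list(), frames = NULL,
                          event_ids = integer(), t_start_min = numeric(),
                          roi = NULL), class = "motif_subset"))
  roi <- events[[1]]$roi
  npx <- sum(roi)
  frames <- array(NA_real_, c(length(events), n_frames, npx))
  for (i in seq_along(events)) {
    e <- events[[i]]
    for (t in seq_len(n_frames)) {
      bp <- bandpass(e$activity[, , t, drop = TRUE], roi, e$pitch_um,
                     s_low_um, s_high_um)
      frames[i, t, ] <- bp[roi]
    }
  }
  structure(list(
    events = events, frames = frames,
    event_ids = vapply(events, function(e) e$id, integer(1)),
    t_start_min = vapply(events, function(e)
      (e$t_start - 1) * e$frame_ms / 60000, numeric(1)),
    roi = roi), class = "motif_subset")
}

#' @export
print.motif_subset <- function(x, ...) {
  cat(sprintf("<motif_subset> %d events x %d frames x %d ROI px\n",
              length(x$events),
              if (is.null(x$frames)) 0 else dim(x$frames)[2],
              if (is.null(x$frames)) 0 else dim(x$frames)[3]))
  invisible(x)
}

#' PCA denoising and event vectorization
#'
#' Denoises the frame stack with a principal-component decomposition fit
#' per frame position across events (retaining the first `n_components`
#' components, 20 by default), then concatenates each event's reconstructed
#' frames into one vector. When fewer than `n_components + 1` events are
#' available, `n_events - 1` components are retained (with a message).
#'
#' @param subset a `motif_subset` from [select_fixed_duration()].
#' @param n_components components retained per frame position.
#' @return n_events x (n_frames * n_px) numeric matrix of event vectors.
#' @export
denoise_and_vectorize <- function(subset, n_components = 20) {
  fr <- subset$frames
  n_ev <- dim(fr)[1]; n_t <- dim(fr)[2]; npx <- dim(fr)[3]
  k <- min(n_components, n_ev - 1)
  if (k < n_components)
    inform(sprintf("only %d events: retaining %d components", n_ev, k))
  out <- matrix(NA_real_, n_ev, n_t * npx)
  for (t in seq_len(n_t)) {
    x <- fr[, t, ]
    ctr <- colMeans(x)
    pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
    rec <- pc$x[, seq_len(k), drop = FALSE] %*%
      t(pc$rotation[, seq_len(k), drop = FALSE])
    out[, (t - 1) * npx + seq_len(npx)] <- sweep(rec, 2, ctr, `+`)
  }
  out
}

# Pearson correlation between rows of a matrix
row_correlations <- function(x) {
  xs <- x - rowMeans(x)
  s <- sqrt(rowSums(xs^2))
  c_mat <- tcrossprod(xs / s)
  diag(c_mat) <- 1
  pmin(pmax(c_mat, -1), 1)
}

#' Event-event correlation matrix
#'
#' Pearson correlation between frame-concatenated event vectors, capturing
#' both spatial and temporal structure.
#'
#' @param vectors event-vector matrix from [denoise_and_vectorize()].
#' @return Symmetric n_events x n_events correlation matrix with unit
#'   diagonal.
#' @export
event_correlations <- function(vectors) row_correlations(vectors)

#' Within-timestep permutation threshold
#'
#' Null model for repeated spatiotemporal patterns that preserves the
#' generic rise-and-fall of activity within events: frame identity is
#' shuffled across events independently at each frame position (all first
#' frames permuted together, all second frames, ...), correlations are
#' recomputed, and the threshold is the pooled `percentile`-th percentile
#' of permuted off-diagonal values.
#'
#' @param vectors event-vector matrix (events x n_positions * n_px).
#' @param n_positions frames per event (default 5).
#' @param n_perm number of permutations (default 1000).
#' @param percentile pooled percentile defining the threshold (default 99).
#' @param seed RNG seed.
#' @return A list: `threshold`, `n_perm`, and `perm_quantiles` (a small set
#'   of reference quantiles of the pooled null).
#' @export
within_timestep_null <- function(vectors, n_positions = 5, n_perm = 1000,
                                 percentile = 99, seed = NULL) {
  n_ev <- nrow(vectors)
  npx <- ncol(vectors) / n_positions
  stopifnot(npx == round(npx))
  lower <- lower.tri(matrix(0, n_ev, n_ev))
  pool <- with_seed(seed, {
    vals <- vector("list", n_perm)
    for (p in seq_len(n_perm)) {
      perm <- vectors
      for (t in seq_len(n_positions)) {
        cols <- (t - 1) * npx + seq_len(npx)
        perm[, cols] <- perm[sample.int(n_ev), cols]
      }
      vals[[p]] <- row_correlations(perm)[lower]
    }
    unlist(vals)
  })
  list(threshold = quantile(pool, percentile / 100, names = FALSE),
       n_perm = n_perm,
       perm_quantiles = quantile(pool, c(0.5, 0.95, 0.99, 0.999)))
}

#' Repetition counts and frequencies
#'
#' An event's repetitions are the other events whose vector correlation
#' exceeds the permutation threshold; its frequency is that count divided
#' by the total number of events.
#'
#' @param corr_matrix matrix from [event_correlations()].
#' @param threshold correlation threshold from [within_timestep_null()].
#' @return Tibble: `event`, `repeats`, `frequency`.
#' @export
repeats_and_frequency <- function(corr_matrix, threshold) {
  n <- nrow(corr_matrix)
  off <- corr_matrix
  diag(off) <- -Inf
  reps <- rowSums(off > threshold)
  tibble(event = seq_len(n), repeats = as.integer(reps),
         frequency = reps / n)
}

#' Greedy motif clustering
#'
#' Iteratively extracts clusters of repeated events: the remaining event
#' with the most above-threshold partners seeds a cluster consisting of
#' itself and those partners; the cluster is removed and the procedure
#' repeats, stopping when the next cluster would hold fewer than
#' `min_cluster` events. Ties break to the lowest event index.
#'
#' @param corr_matrix event correlation matrix.
#' @param threshold correlation threshold.
#' @param min_cluster minimum events per retained cluster (default 10).
#' @return List of integer vectors of event indices (possibly empty).
#' @export
greedy_cluster <- function(corr_matrix, threshold, min_cluster = 10) {
  n <- nrow(corr_matrix)
  above <- corr_matrix > threshold
  diag(above) <- FALSE
  remaining <- rep(TRUE, n)
  clusters <- list()
  repeat {
    idx <- which(remaining)
    if (length(idx) == 0) break
    reps <- rowSums(above[idx, idx, drop = FALSE])
    seed_ev <- idx[which.max(reps)]           # first max = lowest index
    members <- c(seed_ev, idx[above[seed_ev, idx]])
    members <- sort(unique(members))
    if (length(members) < min_cluster) break
    clusters[[length(clusters) + 1]] <- members
    remaining[members] <- FALSE
  }
  clusters
}

#' Temporal coverage of a cluster
#'
#' Two complementary metrics of how a cluster's repetitions spread over the
#' session: the fractional range `Fr = (max(t) - min(t)) / t_total` of its
#' event initiation times, and the fraction of represented bins `Fb`, the
#' share of fixed 10-minute segments containing at least one cluster event.
#'
#' @param t_min event initiation times of the cluster, minutes.
#' @param t_total_min session duration, minutes.
#' @param bin_min bin width, minutes (default 10).
#' @return One-row tibble: `fr`, `fb`, `n_bins`.
#' @export
temporal_coverage <- function(t_min, t_total_min, bin_min = 10) {
  stopifnot(length(t_min) > 0, t_total_min > 0)
  n_bins <- ceiling(t_total_min / bin_min)
  occupied <- unique(pmin(floor(t_min / bin_min), n_bins - 1))
  tibble(fr = (max(t_min) - min(t_min)) / t_total_min,
         fb = length(occupied) / n_bins, n_bins = n_bins)
}

# label vector (NA = unclustered) from a cluster list
cluster_labels <- function(clusters, n) {
  lab <- rep(NA_integer_, n)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}

#' Silhouette comparison of clusterings
#'
#' Mean silhouette score of each clustering over its clustered events
#' (Euclidean distances between event vectors; unclustered events are
#' excluded), plus each alternative's silhouette difference relative to the
#' greedy clustering, in percent:
#' `100 * (s_greedy - s_method) / s_greedy`.
#'
#' @param vectors event-vector matrix.
#' @param clusterings named list of clusterings; each either a list of
#'   index vectors (as from [greedy_cluster()]) or an integer label vector
#'   with `NA` for unclustered events. Must contain a `greedy` entry for
#'   the percentage comparison.
#' @return Tibble: `method`, `silhouette`, `silhouette_diff_pct`.
#' @export
clustering_quality <- function(vectors, clusterings) {
  n <- nrow(vectors)
  sil_of <- function(cl) {
    lab <- if (is.list(cl)) cluster_labels(cl, n) else cl
    use <- which(!is.na(lab))
    if (length(unique(lab[use])) < 2)
      abort("silhouette undefined for fewer than two clusters")
    d <- dist(vectors[use, , drop = FALSE])
    mean(cluster::silhouette(lab[use], d)[, "sil_width"])
  }
  sc <- vapply(clusterings, sil_of, numeric(1))
  ref <- sc[["greedy"]] %||% NA_real_
  tibble(method = names(sc), silhouette = unname(sc),
         silhouette_diff_pct = 100 * (ref - unname(sc)) / ref)
}

#' Alternative clusterings with matched cluster count
#'
#' Hierarchical (Ward linkage on Euclidean distances) and k-means
#' clusterings of the event vectors with the same number of clusters as a
#' reference clustering, for the silhouette comparison.
#'
#' @param vectors event-vector matrix.
#' @param k number of clusters.
#' @param seed RNG seed (k-means initialization).
#' @return Named list of integer label vectors (`hierarchical`, `kmeans`).
#' @export
cluster_alternatives <- function(vectors, k, seed = NULL) {
  d <- dist(vectors)
  hc <- cutree(hclust(d, method = "ward.D2"), k = k)
  km <- with_seed(seed, kmeans(vectors, centers = k, nstart = 5)$cluster)
  list(hierarchical = as.integer(hc), kmeans = as.integer(km))
}

# one derangement of 1..n by seeded rejection sampling
derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Frame-shuffle cluster-membership control
#'
#' Verifies that clustering is sensitive to temporal order: each event's
#' frames are permuted by a derangement (every frame moves), the permuted
#' vector is correlated with each cluster's mean vector, and the event is
#' assigned to the best-matching cluster if that correlation exceeds the
#' threshold (else to a null cluster). Reports the share of events
#' retaining their original cluster.
#'
#' @param vectors original event-vector matrix.
#' @param clusters list from [greedy_cluster()].
#' @param threshold correlation threshold.
#' @param n_positions frames per event.
#' @param seed RNG seed.
#' @return A list: `retained_frac` overall, and `per_cluster` tibble
#'   (`cluster`, `n`, `retained_frac`).
#' @export
frame_shuffle_control <- function(vectors, clusters, threshold,
                                  n_positions = 5, seed = NULL) {
  if (length(clusters) == 0)
    return(list(retained_frac = NA_real_,
                per_cluster = tibble(cluster = integer(), n = integer(),
                                     retained_frac = numeric())))
  n <- nrow(vectors)
  npx <- ncol(vectors) / n_positions
  lab <- cluster_labels(clusters, n)
  centroids <- t(vapply(clusters, function(m)
    colMeans(vectors[m, , drop = FALSE]), numeric(ncol(vectors))))
  clustered <- which(!is.na(lab))
  assigned <- with_seed(seed, vapply(clustered, function(i) {
    ord <- derangement(n_positions)
    v <- numeric(ncol(vectors))
    for (t in seq_len(n_positions))
      v[(t - 1) * npx + seq_len(npx)] <-
        vectors[i, (ord[t] - 1) * npx + seq_len(npx)]
    r <- as.vector(cor(v, t(centroids)))
    if (max(r) > threshold) which.max(r) else NA_integer_
  }, integer(1)))
  retained <- !is.na(assigned) & assigned == lab[clustered]
  per <- dplyr::bind_rows(lapply(seq_along(clusters), function(k) {
    ii <- lab[clustered] == k
    tibble(cluster = k, n = sum(ii), retained_frac = mean(retained[ii]))
  }))
  list(retained_frac = mean(retained), per_cluster = per)
}

#' Full motif-clustering analysis
#'
#' Chains vectorization, the permutation null, repetition counting, greedy
#' clustering, and temporal coverage into one result object.
#'
#' @param subset a `motif_subset`.
#' @param t_total_min session duration in minutes.
#' @param n_components,n_perm,percentile,min_cluster,bin_min stage
#'   parameters (see the individual functions).
#' @param seed RNG seed.
#' @return A `motif_clustering` object: list with `vectors`,
#'   `corr_matrix`, `threshold`, `repeats` (tibble), `clusters`,
#'   `coverage` (per-cluster tibble with Fr/Fb), `t_start_min`,
#'   `t_total_min`.
#' @export
cluster_motifs <- function(subset, t_total_min, n_components = 20,
                           n_perm = 1000, percentile = 99,
                           min_cluster = 10, bin_min = 10, seed = NULL) {
  vectors <- denoise_and_vectorize(subset, n_components)
  n_positions <- dim(subset$frames)[2]
  null <- within_timestep_null(vectors, n_positions, n_perm, percentile,
                               seed = seed)
  cm <- event_correlations(vectors)
  reps <- repeats_and_frequency(cm, null$threshold)
  clusters <- greedy_cluster(cm, null$threshold, min_cluster)
  coverage <- if (length(clusters) > 0)
    dplyr::bind_rows(lapply(seq_along(clusters), function(k)
      dplyr::mutate(
        temporal_coverage(subset$t_start_min[clusters[[k]]], t_total_min,
                          bin_min),
        cluster = k, n_events = length(clusters[[k]]),
        .before = 1)))
  else tibble(cluster = integer(), n_events = integer(), fr = numeric(),
              fb = numeric(), n_bins = integer())
  structure(list(vectors = vectors, corr_matrix = cm,
                 threshold = null$threshold, repeats = reps,
                 clusters = clusters, coverage = coverage,
                 t_start_min = subset$t_start_min,
                 t_total_min = t_total_min, n_positions = n_positions),
            class = "motif_clustering")
}

#' @export
print.motif_clustering <- function(x, ...) {
  cat(sprintf(
    "<motif_clustering> %d events, threshold r = %.3f, %d clusters (%s)\n",
    nrow(x$corr_matrix), x$threshold, length(x$clusters),
    paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.motif_clustering <- function(x, ...) {
  lab <- cluster_labels(x$clusters, nrow(x$corr_matrix))
  dplyr::mutate(x$repeats, cluster = lab, t_start_min = x$t_start_min)
}

#' @export
glance.motif_clustering <- function(x, ...) {
  tibble(n_events = nrow(x$corr_matrix), threshold = x$threshold,
         n_clusters = length(x$clusters),
         clustered_frac = mean(!is.na(cluster_labels(
           x$clusters, nrow(x$corr_matrix)))),
         median_frequency = median(x$repeats$frequency))
}
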