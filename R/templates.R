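#' Collect frames from short events
#'
#' Pools every frame of all events lasting `max_duration_ms` or shorter
#' (inclusive), tagged by event and frame position, as candidates for
#' template-pattern extraction.
#'
#' @param events list of `spont_event` objects.
#' @param max_duration_ms maximum event duration (default 200 ms).
#' @return A `frame_pool`: list with `info` (tibble: `event_id`,
#'   `rel_frame`, `abs_frame`), `frames` (rows x cols x n array of
#'   deconvolved activity), `masks` (matching active-pixel masks), `roi`,
#'   `pitch_um`, `frame_ms`.
#' @export
collect_frames <- function(events, max_duration_ms = 200) {
  keep <- vapply(events, function(e)
    event_n_frames(e) * e$frame_ms <= max_duration_ms, logical(1))
  events <- events[keep]
  if (length(events) == 0)
    return(structure(list(info = tibble(event_id = integer(),
                                        rel_frame = integer(),
                                        abs_frame = integer()),
                          frames = NULL, masks = NULL, roi = NULL),
                     class = "frame_pool"))
  info <- dplyr::bind_rows(lapply(events, function(e)
    tibble(event_id = e$id, rel_frame = seq_len(event_n_frames(e)),
           abs_frame = e$t_start + seq_len(event_n_frames(e)) - 1L)))
  e1 <- events[[1]]
  d <- dim(e1$masks)[1:2]
  frames <- array(NA_real_, c(d, nrow(info)))
  masks <- array(FALSE, c(d, nrow(info)))
  k <- 0L
  for (e in events) for (t in seq_len(event_n_frames(e))) {
    k <- k + 1L
    frames[, , k] <- e$activity[, , t]
    masks[, , k] <- e$masks[, , t]
  }
  structure(list(info = info, frames = frames, masks = masks,
                 roi = e1$roi, pitch_um = e1$pitch_um,
                 frame_ms = e1$frame_ms),
            class = "frame_pool")
}

#' @export
print.frame_pool <- function(x, ...) {
  cat(sprintf("<frame_pool> %d frames from %d events\n", nrow(x$info),
              length(unique(x$info$event_id))))
  invisible(x)
}

#' Fit a multi-Gaussian template to a frame
#'
#' Models a frame's activity as a sum of elliptical (axis-aligned) 2-D
#' Gaussians, one per connected active component (8-connectivity, capped
#' at `max_k` largest), fit by Levenberg-Marquardt least squares from
#' moment-based initialization. On fit failure the moment-initialized
#' Gaussians are returned, flagged.
#'
#' @param frame activity matrix.
#' @param mask logical active-pixel mask selecting the components.
#' @param roi logical ROI (`NULL`: all pixels).
#' @param max_k maximum Gaussian components (default 10).
#' @param max_sd_px upper bound on component SDs, pixels. Modules are a
#'   few hundred micrometers across, so SDs are bounded at the module
#'   scale (default 3 px ~ 140 um at 46.9 um pitch) to stop the fit from
#'   absorbing background into one broad component.
#' @return A `gauss_template`: list with `pattern` (fitted values on the
#'   grid, 0 outside ROI), `params` (tibble: `amp`, `row0`, `col0`,
#'   `sd_row`, `sd_col` in pixels), `converged`.
#' @export
fit_template <- function(frame, mask, roi = NULL, max_k = 10,
                         max_sd_px = 3) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(frame), ncol(frame))
  lab <- .label_components8(mask & roi)
  sizes <- tabulate(lab)
  if (length(sizes) == 0 || max(sizes) == 0)
    abort("frame has no active component")
  comps <- order(sizes, decreasing = TRUE)[seq_len(min(max_k,
                                                       sum(sizes > 0)))]
  init <- dplyr::bind_rows(lapply(comps, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    w <- pmax(frame[lab == k], 1e-9)
    w <- w / sum(w)
    r0 <- sum(idx[, 1] * w); c0 <- sum(idx[, 2] * w)
    tibble(amp = max(frame[lab == k]), row0 = r0, col0 = c0,
           sd_row = min(max(sqrt(sum(w * (idx[, 1] - r0)^2)), 0.7),
                        max_sd_px),
           sd_col = min(max(sqrt(sum(w * (idx[, 2] - c0)^2)), 0.7),
                        max_sd_px))
  }))
  g <- expand.grid(row = seq_len(nrow(frame)), col = seq_len(ncol(frame)))
  in_roi <- as.vector(roi)
  model_vec <- function(p) {
    # p: K x 5 parameters flattened column-wise
    K <- length(p) / 5
    pm <- matrix(p, K, 5)
    v <- numeric(nrow(g))
    for (k in seq_len(K))
      v <- v + pm[k, 1] *
        exp(-((g$row - pm[k, 2])^2 / (2 * pm[k, 4]^2) +
              (g$col - pm[k, 3])^2 / (2 * pm[k, 5]^2)))
    v
  }
  jac_vec <- function(p) {
    K <- length(p) / 5
    pm <- matrix(p, K, 5)
    J <- matrix(0, nrow(g), length(p))
    for (k in seq_len(K)) {
      dr <- g$row - pm[k, 2]; dc <- g$col - pm[k, 3]
      e <- exp(-(dr^2 / (2 * pm[k, 4]^2) + dc^2 / (2 * pm[k, 5]^2)))
      J[, k] <- e
      J[, K + k] <- pm[k, 1] * e * dr / pm[k, 4]^2
      J[, 2 * K + k] <- pm[k, 1] * e * dc / pm[k, 5]^2
      J[, 3 * K + k] <- pm[k, 1] * e * dr^2 / pm[k, 4]^3
      J[, 4 * K + k] <- pm[k, 1] * e * dc^2 / pm[k, 5]^3
    }
    J
  }
  target <- as.vector(frame)
  target[!in_roi] <- 0
  p0 <- as.vector(as.matrix(init))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0,
      fn = function(p) model_vec(abs_sd(p, max_sd_px)) - target,
      jac = function(p) jac_vec(abs_sd(p, max_sd_px)),
      control = minpack.lm::nls.lm.control(maxiter = 50)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p_hat <- if (converged) abs_sd(fit$par, max_sd_px) else p0
  K <- length(p_hat) / 5
  pm <- matrix(p_hat, K, 5)
  pattern <- matrix(model_vec(p_hat), nrow(frame), ncol(frame))
  pattern[!roi] <- 0
  structure(list(
    pattern = pattern,
    params = tibble(amp = pm[, 1], row0 = pm[, 2], col0 = pm[, 3],
                    sd_row = pm[, 4], sd_col = pm[, 5]),
    converged = converged), class = "gauss_template")
}

# keep SDs positive and bounded during optimization
abs_sd <- function(p, max_sd_px = 3) {
  K <- length(p) / 5
  pm <- matrix(p, K, 5)
  pm[, 4] <- pmin(pmax(abs(pm[, 4]), 0.3), max_sd_px)
  pm[, 5] <- pmin(pmax(abs(pm[, 5]), 0.3), max_sd_px)
  as.vector(pm)
}

#' @export
print.gauss_template <- function(x, ...) {
  cat(sprintf("<gauss_template> %d component(s)%s\n", nrow(x$params),
              if (x$converged) "" else " (moment fallback)"))
  invisible(x)
}

#' Template matching threshold
#'
#' The minimum Pearson correlation between a template and copies of itself
#' translated by up to one standard deviation (the largest fitted
#' component SD) in x-y space; frames must correlate at least this
#' strongly with the template to join its group.
#'
#' @param template a `gauss_template`.
#' @param roi logical ROI (`NULL`: all pixels).
#' @return Scalar threshold r (at most 1; the zero shift is included).
#' @export
template_threshold <- function(template, roi = NULL) {
  pat <- template$pattern
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pat), ncol(pat))
  sd_max <- max(template$params$sd_row, template$params$sd_col)
  r_px <- floor(sd_max)
  shifts <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  shifts <- shifts[sqrt(shifts$dr^2 + shifts$dc^2) <= sd_max, ]
  nr <- nrow(pat); nc <- ncol(pat)
  rs <- vapply(seq_len(nrow(shifts)), function(i) {
    dr <- shifts$dr[i]; dc <- shifts$dc[i]
    sh <- matrix(0, nr, nc)
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    sh[r1, c1] <- pat[r1 - dr, c1 - dc]
    suppressWarnings(cor(pat[roi], sh[roi]))
  }, numeric(1))
  min(rs, na.rm = TRUE)
}

#' Greedy template grouping
#'
#' Assigns events to template patterns: iteratively the template with the
#' most events having at least one frame above its threshold claims those
#' events (one frame per event, the best-correlated one); claimed events
#' and the used template are removed and the procedure repeats for up to
#' `top_k` groups. Groups with fewer than `min_members` events are
#' dropped.
#'
#' @param pool a `frame_pool`.
#' @param templates list of `gauss_template` objects.
#' @param thresholds per-template thresholds (default: computed).
#' @param top_k groups to extract (default 7).
#' @param min_members minimum events per retained group (default 15).
#' @return List of `template_group` objects: each a list with `template`,
#'   `threshold`, `members` (tibble: `event_id`, `pool_index`,
#'   `rel_frame`, `abs_frame`, `r`), `group_rank`.
#' @export
greedy_group <- function(pool, templates, thresholds = NULL, top_k = 7,
                         min_members = 15) {
  if (is.null(thresholds))
    thresholds <- vapply(templates, template_threshold,
                         numeric(1), roi = pool$roi)
  n_fr <- nrow(pool$info)
  fm <- matrix(pool$frames, prod(dim(pool$frames)[1:2]), n_fr)[pool$roi, ,
                                                               drop = FALSE]
  r_mat <- vapply(templates, function(tp)
    suppressWarnings(as.vector(cor(tp$pattern[pool$roi], fm))),
    numeric(n_fr))                     # frames x templates
  ev_left <- unique(pool$info$event_id)
  tp_left <- seq_along(templates)
  groups <- list()
  while (length(groups) < top_k && length(tp_left) > 0 &&
         length(ev_left) > 0) {
    counts <- vapply(tp_left, function(k) {
      hit <- r_mat[, k] > thresholds[k] & pool$info$event_id %in% ev_left
      length(unique(pool$info$event_id[hit]))
    }, numeric(1))
    if (max(counts) == 0) break
    k <- tp_left[which.max(counts)]
    hit <- which(r_mat[, k] > thresholds[k] &
                   pool$info$event_id %in% ev_left)
    mem <- tibble(event_id = pool$info$event_id[hit], pool_index = hit,
                  rel_frame = pool$info$rel_frame[hit],
                  abs_frame = pool$info$abs_frame[hit],
                  r = r_mat[hit, k])
    mem <- dplyr::slice_max(dplyr::group_by(mem, .data$event_id),
                            order_by = .data$r, n = 1, with_ties = FALSE)
    mem <- dplyr::ungroup(mem)
    groups[[length(groups) + 1]] <- structure(
      list(template = templates[[k]], threshold = thresholds[k],
           members = mem, group_rank = length(groups) + 1L),
      class = "template_group")
    ev_left <- setdiff(ev_left, mem$event_id)
    tp_left <- setdiff(tp_left, k)
  }
  keep <- vapply(groups, function(g)
    nrow(g$members) >= min_members, logical(1))
  if (sum(keep) < top_k)
    inform(sprintf("only %d group(s) with >= %d members", sum(keep),
                   min_members))
  groups[keep]
}

#' @export
print.template_group <- function(x, ...) {
  cat(sprintf("<template_group #%d> %d members, threshold r = %.3f\n",
              x$group_rank, nrow(x$members), x$threshold))
  invisible(x)
}

#' Build templates and groups from a frame pool
#'
#' Fits a multi-Gaussian template to every pooled frame and greedily
#' groups events by template match.
#'
#' @param pool a `frame_pool` from [collect_frames()].
#' @param top_k,min_members see [greedy_group()].
#' @param max_k maximum Gaussian components per template.
#' @return List of `template_group` objects.
#' @export
build_template_groups <- function(pool, top_k = 7, min_members = 15,
                                  max_k = 10) {
  usable <- which(apply(pool$masks, 3, any))
  templates <- lapply(usable, function(i)
    fit_template(pool$frames[, , i], pool$masks[, , i], pool$roi,
                 max_k = max_k))
  sub_pool <- pool
  sub_pool$info <- pool$info[usable, ]
  sub_pool$frames <- pool$frames[, , usable, drop = FALSE]
  sub_pool$masks <- pool$masks[, , usable, drop = FALSE]
  greedy_group(sub_pool, templates, top_k = top_k,
               min_members = min_members)
}

#' Trajectory decodability of template groups
#'
#' Quantifies how long group identity (defined at the template frame,
#' t = 0) remains decodable from instantaneous activity: at each time
#' offset, the session frames at (template frame + offset) are projected
#' onto the first `n_pc` principal components fitted at that offset only,
#' groups are size-matched by subsampling, and a radial-basis SVM is
#' scored by stratified `k_folds`-fold cross-validation. A subsample is
#' significant when its accuracy exceeds the 95th percentile of its own
#' label-shuffled accuracies; an offset is significant when at least 95%
#' of subsamples are.
#'
#' @param groups list of `template_group` objects.
#' @param movie deconvolved-stage [pixel_movie()] (whole session; frames at
#'   nonzero offsets are taken from the continuous movie whether or not
#'   inside an event).
#' @param offsets_ms vector of offsets (default -2000..2000 in frame
#'   steps).
#' @param n_pc principal components per offset (default 8).
#' @param n_subsample size-matched subsamples per offset (default 100).
#' @param n_shuffle label shuffles per subsample (default 100).
#' @param k_folds cross-validation folds (default 5).
#' @param seed RNG seed.
#' @return An `accuracy_curve`: tibble with one row per offset
#'   (`offset_ms`, `accuracy` = mean over subsamples, `frac_significant`,
#'   `significant`, `n_per_group`, `exhausted`), of class
#'   `accuracy_curve`.
#' @export
trajectory_decoding <- function(groups, movie,
                                offsets_ms = seq(-2000, 2000, by = 20),
                                n_pc = 8, n_subsample = 100,
                                n_shuffle = 100, k_folds = 5,
                                seed = NULL) {
  stopifnot(length(groups) >= 2)
  nt <- n_frames(movie)
  roi_v <- as.vector(movie$roi)
  pm <- as_pixel_matrix(movie)[roi_v, , drop = FALSE]
  labels_all <- rep(seq_along(groups),
                    vapply(groups, function(g) nrow(g$members), integer(1)))
  t0 <- unlist(lapply(groups, function(g) g$members$abs_frame))
  rows <- with_seed(seed, lapply(offsets_ms, function(off) {
    fr <- t0 + round(off / movie$frame_ms)
    ok <- fr >= 1 & fr <= nt
    lab <- labels_all[ok]
    per_group <- table(factor(lab, levels = seq_along(groups)))
    m <- min(per_group)
    if (m < k_folds)
      return(tibble(offset_ms = off, accuracy = NA_real_,
                    frac_significant = NA_real_, significant = NA,
                    n_per_group = as.integer(m), exhausted = TRUE))
    x <- t(pm[, fr[ok], drop = FALSE])
    pc <- prcomp(x, center = TRUE, scale. = FALSE,
                 rank. = min(n_pc, ncol(x), nrow(x) - 1))
    scores <- pc$x
    accs <- numeric(n_subsample)
    sig <- logical(n_subsample)
    for (s in seq_len(n_subsample)) {
      sel <- unlist(lapply(seq_along(groups), function(g)
        sample(which(lab == g), m)))
      acc <- svm_cv_accuracy(scores[sel, , drop = FALSE], lab[sel],
                             k_folds)
      null <- vapply(seq_len(n_shuffle), function(i)
        svm_cv_accuracy(scores[sel, , drop = FALSE], sample(lab[sel]),
                        k_folds), numeric(1))
      accs[s] <- acc
      sig[s] <- acc > quantile(null, 0.95, names = FALSE)
    }
    tibble(offset_ms = off, accuracy = mean(accs),
           frac_significant = mean(sig),
           significant = mean(sig) >= 0.95,
           n_per_group = as.integer(m), exhausted = FALSE)
  }))
  structure(dplyr::bind_rows(rows), class = c("accuracy_curve",
                                              class(tibble())))
}

# stratified k-fold cross-validated RBF-SVM accuracy
svm_cv_accuracy <- function(x, y, k_folds = 5) {
  y <- factor(y)
  folds <- integer(length(y))
  for (g in levels(y)) {
    ii <- sample(which(y == g))
    folds[ii] <- rep_len(seq_len(k_folds), length(ii))
  }
  acc <- vapply(seq_len(k_folds), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = 1, scale = FALSE)
    mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc, na.rm = TRUE)
}
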