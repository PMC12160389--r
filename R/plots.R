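#' Plot a correlation map
#'
#' Raster view of a seed-point correlation map with the seed marked.
#'
#' @param object a `correlation_result`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  df <- matrix_to_df(object$map, "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::annotate("point", x = object$seed_px[2], y = object$seed_px[1],
                      shape = 4, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("Seed correlation map (%d events)",
                                  object$n_events))
}

#' Plot a decoding accuracy curve
#'
#' Classification accuracy of template-group identity against time offset
#' from the template frame, with significant offsets marked.
#'
#' @param object an `accuracy_curve` from [trajectory_decoding()].
#' @param chance optional chance level to draw (e.g. 1 / n_groups).
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.accuracy_curve <- function(object, chance = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$offset_ms,
                                        .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[which(df$significant %in% TRUE), ],
                        color = "#b2182b", size = 1.5) +
    ggplot2::labs(x = "Offset from template frame (ms)",
                  y = "Classification accuracy")
  if (!is.null(chance))
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = 2)
  p
}

#' Plot a motif correlation matrix
#'
#' Event-event correlations ordered by cluster, with cluster boundaries.
#'
#' @param object a `motif_clustering`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.motif_clustering <- function(object, ...) {
  lab <- cluster_labels(object$clusters, nrow(object$corr_matrix))
  ord <- order(is.na(lab), lab)
  cm <- object$corr_matrix[ord, ord]
  df <- matrix_to_df(cm, "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "event (cluster order)", y = "event (cluster order)",
                  title = sprintf("%d clusters, threshold r = %.2f",
                                  length(object$clusters),
                                  object$threshold))
}

#' Plot fitted wave directions
#'
#' Rose diagram of significant-wave propagation directions.
#'
#' @param waves tibble from [fit_event_waves()].
#' @param binwidth_deg histogram bin width, degrees.
#' @return A ggplot object.
#' @export
plot_wave_directions <- function(waves, binwidth_deg = 20) {
  df <- waves[waves$significant %in% TRUE & !is.na(waves$theta_deg), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$theta_deg)) +
    ggplot2::geom_histogram(binwidth = binwidth_deg, boundary = 0,
                            fill = "grey40", color = "white") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, 45)) +
    ggplot2::labs(x = "Propagation direction (deg)", y = "waves")
}

matrix_to_df <- function(m, value = "value") {
  df <- tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    v = as.vector(m))
  names(df)[3] <- value
  df[!is.na(df[[value]]), ]
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
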