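#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into a long tibble
#'
#' @param x an `nmx_trajectory`.
#' @param frames optional frame subset.
#' @param ... unused.
#' @return tibble with `time`, `bead`, `x`, `y`, `z`, `nucleolar`.
#' @export
tidy.nmx_trajectory <- function(x, frames = NULL, ...) {
  if (is.null(frames)) frames <- seq_len(dim(x$positions)[1])
  n <- dim(x$positions)[2]
  nuc <- x$topology$nucleolar_mask
  times <- x$times
  dplyr::bind_rows(lapply(frames, function(f) {
    p <- frame_positions(x, f)
    tibble::tibble(time = times[f], bead = seq_len(n), x = p[, 1],
                   y = p[, 2], z = p[, 3], nucleolar = nuc)
  }))
}

#' @export
glance.nmx_trajectory <- function(x, ...) {
  tibble::tibble(n_beads = dim(x$positions)[2],
                 n_frames = dim(x$positions)[1],
                 total_time = x$params$total_time, mu = x$params$mu,
                 n_link_events = nrow(x$link_log),
                 seed = x$params$seed)
}

#' Tidy a distance map into pair rows
#' @param x an `nmx_distmap`.
#' @param ... unused.
#' @return tibble with `i`, `j`, `distance` (upper triangle).
#' @export
tidy.nmx_distmap <- function(x, ...) {
  up <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(i = up[, 1], j = up[, 2], distance = x$matrix[up])
}

#' Tidy a partition into (bead, layer, label) rows
#' @param x an `nmx_partition`.
#' @param ... unused.
#' @export
tidy.nmx_partition <- function(x, ...) {
  tibble::tibble(bead = rep(seq_len(x$n_nodes), x$n_layers),
                 layer = rep(seq_len(x$n_layers), each = x$n_nodes),
                 label = as.vector(x$labels))
}

#' @export
glance.nmx_partition <- function(x, ...) {
  tibble::tibble(Q = x$Q, gamma = x$gamma, omega = x$omega,
                 n_nodes = x$n_nodes, n_layers = x$n_layers,
                 n_communities = length(unique(as.vector(x$labels))),
                 seed = x$seed)
}

#' Heatmap of a pairwise-distance map
#' @param object an `nmx_distmap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nmx_distmap <- function(object, ...) {
  d <- tidy(object)
  d2 <- d; names(d2)[1:2] <- c("j", "i")
  ggplot2::ggplot(dplyr::bind_rows(d, d2),
                  ggplot2::aes(.data$i, .data$j, fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "distance (nm)",
                                  direction = -1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bead", y = "bead",
                  title = paste(object$kind, "pairwise-distance map"))
}

#' Mixing statistics versus the crosslink timescale
#'
#' Plots the four mixing statistics against mu (log scale), one facet per
#' statistic, from a tibble such as [mixing_sweep()] or the `mixing`
#' element of [run_experiment()] output.
#'
#' @param mixing tibble with columns `mu`, the four statistic columns, and
#'   optionally `level`.
#' @return a ggplot.
#' @export
plot_mixing_curves <- function(mixing) {
  long <- tidyr::pivot_longer(
    mixing,
    cols = c("interaction_fraction", "mean_interaction_number",
             "mean_waiting_time", "mean_interaction_duration"),
    names_to = "statistic", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$mu, .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = expression(mu ~ "(s)"), y = NULL)
  if ("level" %in% names(long))
    p <- p + ggplot2::aes(colour = .data$level)
  p
}

#' Cluster lifetime versus mean size scatter
#' @param clusters tibble from [cluster_lifetimes()] (optionally with a
#'   `mu` column for faceting).
#' @return a ggplot.
#' @export
plot_cluster_stability <- function(clusters) {
  p <- ggplot2::ggplot(clusters,
                       ggplot2::aes(.data$mean_size, .data$lifetime)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "mean cluster size (beads)",
                  y = "cluster lifetime (s)")
  if ("mu" %in% names(clusters))
    p <- p + ggplot2::facet_wrap(~mu, labeller = ggplot2::label_both)
  p
}

#' Maximum intensity projection raster
#' @param object an `nmx_image_stack`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nmx_image_stack <- function(object, ...) {
  m <- object$mip
  d <- tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                      intensity = as.vector(m))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}
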