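#' Weighted gene-interaction adjacency from a distance map
#'
#' Edge weights decay exponentially with distance and vanish at or beyond the
#' threshold: `A_ij = exp(-s_decay * X_ij)` when `X_ij < d_star`, and 0
#' otherwise (the boundary is excluded). The diagonal is zero.
#'
#' @param map an `nmx_distmap` or plain symmetric distance matrix (nm).
#' @param d_star distance threshold, nm.
#' @param s_decay decay rate, 1/nm; defaults to `1/d_star` so weights decay
#'   by e across the threshold scale.
#' @return a symmetric numeric matrix with entries in `[0, 1]`.
#' @export
#' @examples
#' x <- matrix(c(0, 50, 50, 0), 2)
#' adjacency_from_distances(x, d_star = 100, s_decay = 0.01)
adjacency_from_distances <- function(map, d_star = 325,
                                     s_decay = 1 / d_star) {
  stopifnot(d_star > 0, s_decay >= 0)
  x <- if (inherits(map, "nmx_distmap")) map$matrix else map
  a <- exp(-s_decay * x)
  a[x >= d_star] <- 0
  diag(a) <- 0
  a
}

#' Build a temporal gene-interaction network from a trajectory
#'
#' Partitions the saved frames into non-overlapping windows of `delta`
#' frames, computes the time-averaged distance map of each window first, and
#' then applies the exponential-threshold rule to that averaged map (the
#' order matters: averaging the distances precedes the nonlinearity, which
#' differs in general from averaging per-frame adjacencies).
#'
#' @param trajectory an `nmx_trajectory`.
#' @param delta window width in frames (10 frames of 0.1 s = 1-second
#'   layers).
#' @param d_star,s_decay see [adjacency_from_distances()].
#' @param n_windows cap on the number of layers (default: as many as fit).
#' @param burn_in seconds discarded from the start of the trajectory before
#'   the first window.
#' @param beads optional bead subset (indices or `"nucleolar"`).
#' @return an object of class `nmx_temporal_network`: a layered edge list
#'   (tibble with `i`, `j`, `layer`, `weight`) plus metadata (`n_nodes`,
#'   `n_layers`, `delta`, `window_seconds`, `d_star`, `s_decay`).
#' @export
build_temporal_network <- function(trajectory, delta = 10, d_star = 325,
                                   s_decay = 1 / d_star, n_windows = Inf,
                                   burn_in = 0, beads = "nucleolar") {
  idx <- select_beads(trajectory, beads)
  n_frames <- dim(trajectory$positions)[1]
  skip <- sum(trajectory$times < burn_in)
  total <- floor((n_frames - skip) / delta)
  T_layers <- min(total, n_windows)
  if (T_layers < 1) stop("trajectory too short for one window of ", delta,
                         " frames")
  ei <- list(); ej <- list(); es <- list(); ew <- list()
  for (s in seq_len(T_layers)) {
    frames <- skip + ((s - 1) * delta + 1):(s * delta)
    y <- time_averaged_map(trajectory, frames, beads = idx)
    a <- adjacency_from_distances(y, d_star, s_decay)
    up <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    ei[[s]] <- up[, 1]; ej[[s]] <- up[, 2]
    es[[s]] <- rep.int(s, nrow(up)); ew[[s]] <- a[up]
  }
  edges <- tibble::tibble(i = unlist(ei), j = unlist(ej),
                          layer = unlist(es), weight = unlist(ew))
  structure(list(edges = edges, n_nodes = length(idx), n_layers = T_layers,
                 delta = delta,
                 window_seconds = delta * trajectory$params$save_interval,
                 d_star = d_star, s_decay = s_decay, beads = idx),
            class = "nmx_temporal_network")
}

#' Assemble a temporal network from a list of adjacency (or distance)
#' matrices
#'
#' Entry point for externally supplied data, e.g. distance maps derived from
#' real Hi-C: give one symmetric matrix per time window.
#'
#' @param mats list of symmetric matrices. If `from_distances` is TRUE they
#'   are distance maps and the exponential-threshold rule is applied first.
#' @param from_distances logical.
#' @param d_star,s_decay threshold parameters used when `from_distances`.
#' @param window_seconds layer duration in seconds (metadata).
#' @return an `nmx_temporal_network`.
#' @export
temporal_network_from_matrices <- function(mats, from_distances = FALSE,
                                           d_star = 325,
                                           s_decay = 1 / d_star,
                                           window_seconds = 1) {
  stopifnot(length(mats) >= 1)
  n <- nrow(mats[[1]])
  ei <- list(); ej <- list(); es <- list(); ew <- list()
  for (s in seq_along(mats)) {
    a <- mats[[s]]
    stopifnot(nrow(a) == n, ncol(a) == n)
    if (from_distances) a <- adjacency_from_distances(a, d_star, s_decay)
    up <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    ei[[s]] <- up[, 1]; ej[[s]] <- up[, 2]
    es[[s]] <- rep.int(s, nrow(up)); ew[[s]] <- a[up]
  }
  edges <- tibble::tibble(i = unlist(ei), j = unlist(ej),
                          layer = unlist(es), weight = unlist(ew))
  structure(list(edges = edges, n_nodes = n, n_layers = length(mats),
                 delta = NA_integer_, window_seconds = window_seconds,
                 d_star = if (from_distances) d_star else NA_real_,
                 s_decay = if (from_distances) s_decay else NA_real_,
                 beads = seq_len(n)),
            class = "nmx_temporal_network")
}

#' Materialize one layer of a temporal network as a dense matrix
#' @param network an `nmx_temporal_network`.
#' @param layer layer index.
#' @return symmetric n x n matrix.
#' @export
layer_matrix <- function(network, layer) {
  e <- network$edges[network$edges$layer == layer, ]
  a <- matrix(0, network$n_nodes, network$n_nodes)
  a[cbind(e$i, e$j)] <- e$weight
  a[cbind(e$j, e$i)] <- e$weight
  a
}

#' @export
print.nmx_temporal_network <- function(x, ...) {
  cat("<nmx_temporal_network>", x$n_nodes, "nodes x", x$n_layers,
      "layers;", nrow(x$edges), "edges; d* =", x$d_star, "nm\n")
  invisible(x)
}

#' Export the layered edge list as TSV
#' @param network an `nmx_temporal_network`.
#' @param path file path.
#' @export
write_layers_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
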