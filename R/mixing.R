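#' Interaction and waiting intervals of one pair series
#'
#' Decomposes a boolean interaction series (one bead pair over frames or
#' layers) into maximal true-runs (interactions) and the gaps between
#' consecutive runs (waits). Gaps at the start or end of the series are
#' censored: their full extent is unobserved, so they are flagged and
#' excluded from waiting-time averages.
#'
#' @param series logical vector (TRUE = interacting / co-membered).
#' @param step_seconds duration of one series element.
#' @return a tibble with columns `type` (`"interaction"` or `"wait"`),
#'   `start`, `end` (element indices, inclusive), `duration` (seconds) and
#'   `censored`.
#' @export
#' @examples
#' pair_interaction_intervals(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
#'                            step_seconds = 0.1)
pair_interaction_intervals <- function(series, step_seconds = 0.1) {
  stopifnot(length(series) >= 1, is.logical(series))
  r <- rle(series)
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  type <- ifelse(r$values, "interaction", "wait")
  censored <- !r$values & (seq_len(n) == 1L | seq_len(n) == n)
  out <- tibble::tibble(type = type, start = starts, end = ends,
                        duration = r$lengths * step_seconds,
                        censored = censored)
  out[!(out$type == "wait" & out$duration == 0), ]
}

# Streaming run/gap statistics for a pairs x time boolean process.
# `next_frame(f)` must return a logical vector over pairs for frame f.
# Waiting times pool all completed (uncensored) gaps across pairs; runs are
# all counted, including censored ones at the series ends.
stream_pair_stats <- function(n_pairs, n_frames, n_beads, next_frame,
                              step_seconds) {
  ever <- logical(n_pairs)
  had_run <- logical(n_pairs)
  prev <- logical(n_pairs)
  gap_len <- integer(n_pairs)
  n_runs <- numeric(1)
  true_frames <- 0
  closed_gap_frames <- 0
  n_closed_gaps <- 0
  sum_degree <- 0
  for (f in seq_len(n_frames)) {
    b <- next_frame(f)
    ever <- ever | b
    starts <- b & !prev
    n_runs <- n_runs + sum(starts)
    true_frames <- true_frames + sum(b)
    closing <- starts & had_run
    closed_gap_frames <- closed_gap_frames + sum(gap_len[closing])
    n_closed_gaps <- n_closed_gaps + sum(closing)
    gap_len[b] <- 0L
    gap_len[!b] <- gap_len[!b] + 1L
    had_run <- had_run | b
    prev <- b
    sum_degree <- sum_degree + 2 * sum(b) / n_beads
  }
  tibble::tibble(
    interaction_fraction = mean(ever),
    mean_interaction_number = sum_degree / n_frames,
    mean_waiting_time = if (n_closed_gaps > 0)
      closed_gap_frames / n_closed_gaps * step_seconds else NA_real_,
    mean_interaction_duration = if (n_runs > 0)
      true_frames / n_runs * step_seconds else NA_real_,
    n_pairs = n_pairs, n_steps = n_frames, step_seconds = step_seconds)
}

#' Gene-mixing summary statistics
#'
#' The four mixing statistics over all unordered nucleolar bead pairs, at
#' either of two levels. At the *bead* level a pair interacts in a frame
#' when its distance is below `d_star` (100 nm); at the *community* level a
#' pair "communicates" in a layer when both beads carry the same community
#' label. Statistics: (A) fraction of pairs interacting at least once;
#' (B) mean number of simultaneous interaction partners per bead, averaged
#' over time and beads (community level: average co-members, i.e. community
#' size minus one); (C) mean waiting time between consecutive interactions
#' of a pair (censored end-gaps excluded, all completed gaps pooled);
#' (D) mean duration of an interaction run.
#'
#' @param x an `nmx_trajectory` (bead level) or `nmx_partition` (community
#'   level).
#' @param level `"bead"` or `"community"`; inferred from `x` by default.
#' @param d_star interaction distance threshold in nm (bead level).
#' @param beads bead subset for the bead level (default `"nucleolar"`).
#' @param frames optional frame subset (bead level), e.g. to drop burn-in.
#' @return a one-row tibble with the four statistics plus bookkeeping
#'   columns (`level`, `n_pairs`, `n_steps`, `step_seconds`).
#' @export
mixing_summary <- function(x, level = NULL, d_star = 100,
                           beads = "nucleolar", frames = NULL) {
  if (is.null(level))
    level <- if (inherits(x, "nmx_partition")) "community" else "bead"
  level <- match.arg(level, c("bead", "community"))
  if (level == "bead") {
    stopifnot(inherits(x, "nmx_trajectory"))
    idx <- select_beads(x, beads)
    n <- length(idx)
    if (n < 2) stop("need at least 2 beads")
    if (is.null(frames)) frames <- seq_len(dim(x$positions)[1])
    out <- stream_pair_stats(
      n_pairs = n * (n - 1) / 2, n_frames = length(frames), n_beads = n,
      next_frame = function(f) {
        d <- stats::dist(frame_positions(x, frames[f])[idx, , drop = FALSE])
        as.vector(d) < d_star
      },
      step_seconds = x$params$save_interval)
    out$level <- "bead"
    out$d_star <- d_star
  } else {
    stopifnot(inherits(x, "nmx_partition"))
    lab <- x$labels
    n <- nrow(lab)
    if (n < 2) stop("need at least 2 beads")
    pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
    out <- stream_pair_stats(
      n_pairs = nrow(pr), n_frames = ncol(lab), n_beads = n,
      next_frame = function(s) lab[pr[, 1], s] == lab[pr[, 2], s],
      step_seconds = x$window_seconds)
    out$level <- "community"
    out$d_star <- NA_real_
  }
  out
}

#' Lifetime and size of detected clusters
#'
#' Community-level bookkeeping for a temporal partition: for every community
#' label, the lifetime is the span from its first to its last populated
#' layer (inclusive) converted to seconds, and the mean size is its member
#' count averaged over the layers in which it is populated.
#'
#' @param assignment an `nmx_partition`.
#' @param window_seconds seconds per layer; defaults to the value stored in
#'   the partition.
#' @return a tibble with one row per community: `community`, `first_layer`,
#'   `last_layer`, `lifetime` (s), `mean_size`, `max_size`, `n_layers`
#'   (populated layers).
#' @export
cluster_lifetimes <- function(assignment,
                              window_seconds = assignment$window_seconds) {
  lab <- assignment$labels
  d <- tibble::tibble(label = as.vector(lab),
                      layer = rep(seq_len(ncol(lab)), each = nrow(lab)))
  sizes <- dplyr::count(d, .data$label, .data$layer)
  out <- dplyr::summarise(
    dplyr::group_by(sizes, .data$label),
    first_layer = min(.data$layer), last_layer = max(.data$layer),
    mean_size = mean(.data$n), max_size = max(.data$n),
    n_layers = dplyr::n(), .groups = "drop")
  out$lifetime <- (out$last_layer - out$first_layer + 1) * window_seconds
  dplyr::rename(out[, c("label", "first_layer", "last_layer", "lifetime",
                        "mean_size", "max_size", "n_layers")],
                community = "label")
}

#' Per-community persistence probability
#'
#' For each community and layer transition, the fraction of member beads
#' whose label is unchanged in the next layer; aggregated per community by
#' pooling beads over all transitions (the probability that a randomly
#' selected member bead keeps its label in the next window).
#'
#' @param assignment an `nmx_partition` with at least 2 layers.
#' @return a tibble with `community`, `persistence`, `mean_size`,
#'   `n_observations` (pooled member-transitions).
#' @export
persistence_probability <- function(assignment) {
  lab <- assignment$labels
  if (ncol(lab) < 2) stop("need at least 2 layers")
  T_layers <- ncol(lab)
  cur <- as.vector(lab[, -T_layers, drop = FALSE])
  nxt <- as.vector(lab[, -1, drop = FALSE])
  kept <- cur == nxt
  d <- tibble::tibble(community = cur, kept = kept)
  pers <- dplyr::summarise(dplyr::group_by(d, .data$community),
                           persistence = mean(.data$kept),
                           n_observations = dplyr::n(), .groups = "drop")
  dplyr::left_join(pers,
                   cluster_lifetimes(assignment)[, c("community",
                                                     "mean_size")],
                   by = "community")
}

#' Sweep mixing statistics over the crosslink timescale
#'
#' Runs scaled nucleolar simulations across a mu grid and seeds and returns
#' the four bead-level (and optionally community-level) mixing statistics
#' for each run, the experiment behind the non-monotone mixing curves.
#'
#' @param mu_values numeric vector of kinetic timescales (s).
#' @param seeds integer vector of seeds.
#' @param n_beads,total_time scaled-run dimensions.
#' @param d_star bead-level interaction threshold (nm).
#' @param community_level also compute community-level statistics (builds a
#'   temporal network and runs community detection per run).
#' @param burn_in seconds discarded from the start of each run.
#' @param delta,d_star_network,gamma,omega community-detection parameters.
#' @param ... passed to [simulate_nucleolus()].
#' @return a tibble keyed by (`mu`, `seed`, `level`) with the four mixing
#'   statistics.
#' @export
mixing_sweep <- function(mu_values, seeds = 1:5, n_beads = 120,
                         total_time = 60, d_star = 100,
                         community_level = FALSE, burn_in = 10,
                         delta = 10, d_star_network = 325, gamma = 10,
                         omega = 1, ...) {
  rows <- list()
  for (mu in mu_values) {
    for (sd_ in seeds) {
      traj <- simulate_nucleolus(n_beads = n_beads, mu = mu,
                                 total_time = total_time, seed = sd_, ...)
      keep <- which(traj$times >= burn_in)
      bead <- mixing_summary(traj, level = "bead", d_star = d_star,
                             frames = keep)
      bead$mu <- mu; bead$seed <- sd_
      rows[[length(rows) + 1]] <- bead
      if (community_level) {
        net <- build_temporal_network(traj, delta = delta,
                                      d_star = d_star_network)
        part <- optimize_louvain(net, gamma = gamma, omega = omega,
                                 seed = sd_)
        comm <- mixing_summary(part)
        comm$mu <- mu; comm$seed <- sd_
        rows[[length(rows) + 1]] <- comm
      }
    }
  }
  dplyr::bind_rows(rows)
}
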