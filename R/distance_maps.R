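#' Pairwise-distance maps (Hi-C analogue)
#'
#' A distance map is the symmetric N x N matrix of Euclidean bead-bead
#' distances (nm), the quantity that Hi-C contact counts decay with.
#' Three kinds are supported: the instantaneous map X(t) of a single saved
#' frame, the time-averaged map Y(tau) (entrywise mean of X over a window of
#' frames) and the population-averaged map Z(t) (entrywise mean over
#' replicate simulations at a fixed time).
#'
#' @name distance_maps
NULL

new_distmap <- function(m, kind, time_ref, n_sources, beads) {
  structure(list(matrix = m, kind = kind, time_ref = time_ref,
                 n_sources = n_sources, beads = beads),
            class = "nmx_distmap")
}

#' @export
print.nmx_distmap <- function(x, ...) {
  cat("<nmx_distmap>", x$kind, "map of", nrow(x$matrix), "beads (",
      x$n_sources, "source frame(s))\n")
  invisible(x)
}

select_beads <- function(trajectory, beads) {
  if (is.null(beads)) seq_len(dim(trajectory$positions)[2])
  else if (identical(beads, "nucleolar")) which(trajectory$topology$nucleolar_mask)
  else beads
}

#' Instantaneous pairwise-distance map
#'
#' @param trajectory an `nmx_trajectory`.
#' @param t time on the saved grid (seconds); alternatively give `frame`.
#' @param frame saved frame index (1-based).
#' @param beads optional bead subset: indices or `"nucleolar"`.
#' @return an `nmx_distmap` of kind `"instantaneous"`.
#' @export
#' @examples
#' traj <- simulate_nucleolus(n_beads = 12, mu = 0.1, total_time = 1, seed = 1)
#' m <- instantaneous_map(traj, t = 0.5)
#' isSymmetric(m$matrix)
instantaneous_map <- function(trajectory, t = NULL, frame = NULL,
                              beads = NULL) {
  if (is.null(frame)) frame <- frame_at_time(trajectory, t)
  idx <- select_beads(trajectory, beads)
  pos <- frame_positions(trajectory, frame)[idx, , drop = FALSE]
  m <- as.matrix(stats::dist(pos))
  dimnames(m) <- NULL
  new_distmap(m, "instantaneous", trajectory$times[frame], 1L, idx)
}

#' Time-averaged pairwise-distance map
#'
#' @param trajectory an `nmx_trajectory`.
#' @param frames integer vector of saved frame indices (the window tau).
#' @inheritParams instantaneous_map
#' @return an `nmx_distmap` of kind `"time_averaged"`.
#' @export
time_averaged_map <- function(trajectory, frames, beads = NULL) {
  stopifnot(length(frames) >= 1)
  idx <- select_beads(trajectory, beads)
  acc <- NULL
  for (f in frames) {
    m <- as.matrix(stats::dist(frame_positions(trajectory, f)[idx, ,
                                                              drop = FALSE]))
    acc <- if (is.null(acc)) m else acc + m
  }
  m <- acc / length(frames)
  dimnames(m) <- NULL
  new_distmap(m, "time_averaged", range(trajectory$times[frames]),
              length(frames), idx)
}

#' Population-averaged pairwise-distance map
#'
#' Entrywise mean of instantaneous maps at a fixed time across replicate
#' simulations (different seeds, identical topology and time grid).
#'
#' @param trajectories list of `nmx_trajectory` objects.
#' @inheritParams instantaneous_map
#' @return an `nmx_distmap` of kind `"population_averaged"`.
#' @export
population_averaged_map <- function(trajectories, t, beads = NULL) {
  stopifnot(length(trajectories) >= 1)
  n <- vapply(trajectories, function(x) dim(x$positions)[2], integer(1))
  if (length(unique(n)) != 1)
    stop("trajectories must share a topology")
  maps <- lapply(trajectories, instantaneous_map, t = t, beads = beads)
  m <- Reduce(`+`, lapply(maps, `[[`, "matrix")) / length(maps)
  new_distmap(m, "population_averaged", t, length(maps), maps[[1]]$beads)
}

#' Histogram of pairwise distances with mode localization
#'
#' Bins the upper triangle of a distance map into fixed-width bins and finds
#' local maxima of the smoothed histogram (3-bin moving average), the
#' "multimodality signal" used to diagnose clustering. The lowest-distance
#' mode of a rigid-regime snapshot sits near the intra-cluster bead spacing.
#'
#' @param map an `nmx_distmap` or a plain symmetric matrix.
#' @param binwidth bin width in nm.
#' @param max_distance histogram range end; defaults to the largest distance.
#' @return a tibble with `mid` (bin centre), `count`, `density`, `smooth`
#'   (moving-average density) and `is_mode`.
#' @export
distance_histogram <- function(map, binwidth = 10, max_distance = NULL) {
  m <- if (inherits(map, "nmx_distmap")) map$matrix else map
  d <- m[upper.tri(m)]
  if (is.null(max_distance)) max_distance <- max(d) + binwidth
  breaks <- seq(0, max_distance + binwidth, by = binwidth)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  dens <- h$counts / sum(h$counts) / binwidth
  k <- length(dens)
  sm <- (c(dens[1], dens[-k]) + dens + c(dens[-1], dens[k])) / 3
  is_mode <- rep(FALSE, k)
  for (i in seq_len(k)) {
    lo <- if (i > 1) sm[i - 1] else -Inf
    hi <- if (i < k) sm[i + 1] else -Inf
    is_mode[i] <- sm[i] > 0 && sm[i] >= lo && sm[i] > hi
  }
  # a flat-topped run counts once (leftmost bin)
  for (i in seq_len(k - 1))
    if (is_mode[i] && is_mode[i + 1]) is_mode[i + 1] <- FALSE
  tibble::tibble(mid = h$mids, count = h$counts, density = dens,
                 smooth = sm, is_mode = is_mode)
}

#' Location of the lowest-distance histogram mode
#'
#' @inheritParams distance_histogram
#' @return bin centre (nm) of the first local maximum.
#' @export
lowest_distance_mode <- function(map, binwidth = 10, max_distance = NULL) {
  h <- distance_histogram(map, binwidth, max_distance)
  modes <- h$mid[h$is_mode]
  if (length(modes) == 0) return(NA_real_)
  min(modes)
}

#' Count prominent modes of a pairwise-distance histogram
#'
#' Counts local maxima of the smoothed histogram that are both tall enough
#' (relative to the tallest mode) and separated from already-counted modes
#' by a valley that dips well below them, so small wiggles on a slope are
#' not counted as modes.
#'
#' @inheritParams distance_histogram
#' @param min_height discard modes whose smoothed density is below this
#'   fraction of the tallest mode.
#' @param min_prominence required relative dip of the separating valley: a
#'   candidate counts only if the smoothed density between it and every
#'   already-counted mode drops below `(1 - min_prominence)` times the
#'   candidate height.
#' @return number of prominent local maxima.
#' @export
n_histogram_modes <- function(map, binwidth = 10, max_distance = NULL,
                              min_height = 0.05, min_prominence = 0.3) {
  h <- distance_histogram(map, binwidth, max_distance)
  peak <- max(h$smooth)
  cand <- which(h$is_mode & h$smooth >= min_height * peak)
  if (length(cand) == 0) return(0L)
  cand <- cand[order(-h$smooth[cand])]
  counted <- cand[1]
  for (k in cand[-1]) {
    ok <- TRUE
    for (m in counted) {
      rng <- if (k < m) k:m else m:k
      if (min(h$smooth[rng]) > (1 - min_prominence) * h$smooth[k]) {
        ok <- FALSE
        break
      }
    }
    if (ok) counted <- c(counted, k)
  }
  length(counted)
}

#' Export a distance map to CSV
#' @param map an `nmx_distmap`.
#' @param path file path.
#' @export
write_distmap_csv <- function(map, path) {
  utils::write.csv(map$matrix, path, row.names = FALSE)
  invisible(path)
}
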