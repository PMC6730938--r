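#' Initialize a simulation configuration
#'
#' Places tethered chain ends on their wall sites and fills in interior beads
#' with a random-walk bridge between the chain's end points (a plain random
#' walk when an end is untethered), projecting every bead into the nuclear
#' sphere.
#'
#' @param topology an [genome_topology()] object.
#' @param params a [sim_params()] object.
#' @param seed integer seed; defaults to `params$seed`.
#' @return a list with `positions` (N x 3 matrix, nm), `tethered` (logical),
#'   and the `topology`/`params` used.
#' @export
init_configuration <- function(topology, params, seed = params$seed) {
  stopifnot(inherits(topology, "nmx_topology"), inherits(params, "nmx_params"))
  R <- params$nucleus_radius
  L0 <- params$contour_length
  N <- topology$n_beads
  pos <- matrix(0, N, 3)
  tethered <- rep(FALSE, N)
  # start near the equilibrium bond extension so the chain begins in a
  # locally relaxed (not compressed) state
  step_len <- min(0.75 * L0,
                  sqrt(2 * params$persistence_scale * L0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (k in seq_len(nrow(topology$chains))) {
    f <- topology$chains$first_bead[k]; l <- topology$chains$last_bead[k]
    n <- l - f + 1L
    ts <- topology$chains$tether_start[k]; te <- topology$chains$tether_end[k]
    a <- if (!is.na(ts)) topology$tether_sites[ts, ] * R else
      runif_sphere(R * 0.9)
    b <- if (!is.na(te)) topology$tether_sites[te, ] * R else NA
    if (!anyNA(b) && n > 1) {
      if (sqrt(sum((b - a)^2)) > (n - 1) * L0)
        stop("chain ", k, " too long to span its tether sites at L0 = ", L0)
    }
    walk <- matrix(0, n, 3)
    walk[1, ] <- a
    if (n > 1) {
      steps <- matrix(stats::rnorm(3 * (n - 1)), n - 1, 3)
      steps <- steps / sqrt(rowSums(steps^2)) * step_len
      walk[-1, ] <- matrix(a, n - 1, 3, byrow = TRUE) +
        apply(steps, 2, cumsum)
      if (!anyNA(b)) {
        # bridge correction so the last bead lands on its tether site
        corr <- (b - walk[n, ])
        wgt <- (seq_len(n) - 1) / (n - 1)
        walk <- walk + outer(wgt, corr)
      }
    }
    # project interior beads inside the sphere
    r <- sqrt(rowSums(walk^2))
    too_far <- r > R
    if (any(too_far))
      walk[too_far, ] <- walk[too_far, ] * (R / r[too_far])
    pos[f:l, ] <- walk
    if (!is.na(ts)) tethered[f] <- TRUE
    if (!is.na(te)) tethered[l] <- TRUE
  }
  list(positions = pos, tethered = tethered, topology = topology,
       params = params)
}

runif_sphere <- function(r) {
  v <- stats::rnorm(3)
  u <- stats::runif(1)^(1 / 3)
  v / sqrt(sum(v^2)) * r * u
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate the deterministic forces on a configuration
#'
#' Sum of wormlike-chain (Marko-Siggia) spring forces between chain
#' neighbours and crosslinked pairs, soft excluded-volume repulsion between
#' beads closer than twice the repulsion radius, and an inward wall restoring
#' force on beads outside the nuclear sphere. The same compiled kernel drives
#' the integrator.
#'
#' @param positions N x 3 matrix of bead positions (nm).
#' @param params a [sim_params()] object.
#' @param springs integer matrix of backbone spring pairs (1-based); defaults
#'   to none.
#' @param links integer matrix of crosslinked pairs (1-based); defaults to
#'   none.
#' @return N x 3 matrix of forces (drag units: nm/s).
#' @export
#' @examples
#' p <- sim_params(mu = 0.1, total_time = 1)
#' x <- rbind(c(0, 0, 0), c(150, 0, 0))
#' compute_forces(x, p, links = rbind(c(1, 2)))
compute_forces <- function(positions, params, springs = NULL, links = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (any(!is.finite(positions))) stop("non-finite bead position")
  empty <- matrix(integer(0), 0, 2)
  springs <- if (is.null(springs)) empty else
    matrix(as.integer(springs), ncol = 2)
  links <- if (is.null(links)) empty else matrix(as.integer(links), ncol = 2)
  cpp_forces(positions, springs, links, unclass(params))
}

#' Simulate a trajectory of the crosslinking bead-spring model
#'
#' Runs the full Brownian-dynamics loop: force evaluation, overdamped
#' Euler-Maruyama update with spherical confinement, two-state activity
#' kinetics for nucleolar beads, and greedy proximity matching of crosslinks,
#' saving a frame every `save_interval` seconds. Fully reproducible from
#' `params$seed`.
#'
#' @param topology an [genome_topology()] object.
#' @param params a [sim_params()] object.
#' @param log_activity record every completed activity-state duration
#'   (useful for kinetic parameter recovery; off by default).
#' @return an object of class `nmx_trajectory` with elements `times` (saved
#'   grid, s), `positions` (frames x beads x 3 array, nm), `topology`,
#'   `params`, `link_log` (tibble of crosslink events; `t_broken` is `NA`
#'   for links still present at the end) and optionally `activity_log`.
#' @export
#' @examples
#' topo <- nucleolus_topology(20)
#' p <- sim_params(mu = 0.09, total_time = 1, nucleus_radius = 400, seed = 7)
#' traj <- simulate_chromatin(topo, p)
#' dim(traj$positions)
simulate_chromatin <- function(topology, params, log_activity = FALSE) {
  stopifnot(inherits(topology, "nmx_topology"), inherits(params, "nmx_params"))
  init <- init_configuration(topology, params)
  springs <- topology_springs(topology)
  if (is.null(springs)) springs <- matrix(integer(0), 0, 2)
  chain_of <- chain_index(topology$chains, topology$n_beads)
  res <- cpp_simulate(init$positions, init$tethered, topology$nucleolar_mask,
                      as.integer(chain_of), springs - 1L, unclass(params),
                      params$total_time, params$save_interval,
                      params$seed, log_activity)
  link_log <- tibble::as_tibble(res$link_log)
  act <- if (log_activity) tibble::as_tibble(res$activity_log) else NULL
  structure(list(times = res$times, positions = res$positions,
                 topology = topology, params = params,
                 tethered = init$tethered,
                 link_log = link_log, activity_log = act,
                 final_active = res$final_active),
            class = "nmx_trajectory")
}

#' Simulate a scaled nucleolar chain
#'
#' Convenience driver for the scaled preset: a single wall-tethered chain of
#' crosslink-competent beads. The default nucleus radius scales with the
#' cube root of the bead number so the ambient bead density stays fixed
#' across chain lengths, calibrated so that the rigid regime (mu = 0.09)
#' self-organizes into several tight, well-separated clusters whose
#' intra-cluster distance mode sits near 50 nm.
#'
#' @param n_beads chain length.
#' @param mu kinetic timescale, seconds.
#' @param total_time simulated seconds.
#' @param seed integer seed.
#' @param nucleus_radius nm; default scales with bead number to keep density
#'   comparable across chain lengths.
#' @param log_activity record completed activity-state durations.
#' @param ... further arguments passed to [sim_params()].
#' @return an `nmx_trajectory`.
#' @export
simulate_nucleolus <- function(n_beads = 200, mu = 0.09, total_time = 300,
                               seed = 1L,
                               nucleus_radius = 1780 * (n_beads / 200)^(1 / 3),
                               log_activity = FALSE, ...) {
  topo <- nucleolus_topology(n_beads)
  p <- sim_params(mu = mu, total_time = total_time,
                  nucleus_radius = nucleus_radius, seed = seed, ...)
  simulate_chromatin(topo, p, log_activity = log_activity)
}

#' @export
print.nmx_trajectory <- function(x, ...) {
  cat("<nmx_trajectory>", dim(x$positions)[1], "frames x",
      dim(x$positions)[2], "beads; mu =", x$params$mu, "s;",
      nrow(x$link_log), "crosslink events\n")
  invisible(x)
}

# positions of one saved frame as an N x 3 matrix
frame_positions <- function(trajectory, frame) {
  p <- trajectory$positions
  matrix(p[frame, , ], dim(p)[2], 3)
}

# saved-grid frame index for a time point (error if off-grid)
frame_at_time <- function(trajectory, t) {
  idx <- which(abs(trajectory$times - t) < 1e-9)
  if (length(idx) != 1)
    stop("t = ", t, " is not on the saved time grid")
  idx
}

#' Reference greedy crosslink matcher
#'
#' Pure-R statement of the matching rule used at every step of the
#' simulation: among unlinked, active, non-adjacent nucleolar bead pairs
#' closer than `d_link`, links form greedily in ascending distance order
#' (ties broken by bead index), each bead participating in at most one link.
#' Exposed for inspection and as an executable specification; the compiled
#' integrator applies the identical rule.
#'
#' @param positions N x 3 matrix.
#' @param active logical vector: crosslink-competent right now.
#' @param linked logical vector: already in a crosslink.
#' @param d_link capture radius, nm.
#' @param adjacent function(i, j) returning TRUE for chain neighbours;
#'   defaults to consecutive indices.
#' @return integer matrix of newly formed pairs (possibly 0 rows).
#' @export
match_crosslink_pairs <- function(positions, active,
                                  linked = rep(FALSE, nrow(positions)),
                                  d_link = 90,
                                  adjacent = function(i, j) abs(i - j) <= 1) {
  N <- nrow(positions)
  cand <- which(active & !linked)
  pairs <- NULL
  if (length(cand) >= 2) {
    cmb <- utils::combn(cand, 2)
    d <- sqrt(rowSums((positions[cmb[1, ], , drop = FALSE] -
                      positions[cmb[2, ], , drop = FALSE])^2))
    keep <- d < d_link & !mapply(adjacent, cmb[1, ], cmb[2, ])
    if (any(keep)) {
      ord <- order(d[keep], cmb[1, keep], cmb[2, keep])
      ii <- cmb[1, keep][ord]; jj <- cmb[2, keep][ord]
      used <- rep(FALSE, N)
      sel <- logical(length(ii))
      for (k in seq_along(ii)) {
        if (!used[ii[k]] && !used[jj[k]]) {
          sel[k] <- TRUE
          used[ii[k]] <- TRUE; used[jj[k]] <- TRUE
        }
      }
      pairs <- cbind(ii[sel], jj[sel])
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("bead_i", "bead_j")
  pairs
}
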