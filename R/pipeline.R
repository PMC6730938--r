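#' Configuration for a full crosslink-timescale experiment
#'
#' Bundles every stage's parameters for [run_experiment()]: the mu grid
#' (default log-spaced over the studied range 0.09-90 s), seeds, scaled-run
#' dimensions, the two interaction thresholds (100 nm for bead mixing,
#' 325 nm for network construction), community-detection parameters and
#' imaging options. All values are echoed verbatim into the results bundle.
#'
#' @param mu_grid kinetic timescales to sweep (s).
#' @param seeds integer seeds (one simulation per mu x seed cell).
#' @param n_beads,total_time scaled nucleolar run dimensions.
#' @param burn_in seconds discarded before computing statistics.
#' @param delta frames per network layer.
#' @param d_star_mixing bead-level interaction threshold, nm.
#' @param d_star_network network edge threshold, nm.
#' @param gamma,omega community-detection parameters.
#' @param imaging an [imaging_params()] object or NULL to skip imaging.
#' @param out_dir optional directory: write one TSV per statistic.
#' @param ... extra arguments to [simulate_nucleolus()].
#' @return a list of class `nmx_config`.
#' @export
experiment_config <- function(mu_grid = 10^seq(log10(0.09), log10(90),
                                               length.out = 13),
                              seeds = 1:3, n_beads = 120, total_time = 60,
                              burn_in = 10, delta = 10,
                              d_star_mixing = 100, d_star_network = 325,
                              gamma = 10, omega = 1,
                              imaging = imaging_params(), out_dir = NULL,
                              ...) {
  stopifnot(all(mu_grid > 0), length(seeds) >= 1)
  structure(list(mu_grid = mu_grid, seeds = as.integer(seeds),
                 n_beads = n_beads, total_time = total_time,
                 burn_in = burn_in, delta = delta,
                 d_star_mixing = d_star_mixing,
                 d_star_network = d_star_network, gamma = gamma,
                 omega = omega, imaging = imaging, out_dir = out_dir,
                 sim_extra = list(...)),
            class = "nmx_config")
}

#' Run the full pipeline over a mu sweep
#'
#' For every (mu, seed) cell: simulate a scaled nucleolar chain, then chain
#' the analysis stages — bead-level mixing statistics, temporal network,
#' community detection, community-level mixing, cluster lifetime and
#' persistence summaries, distance-histogram mode, and (optionally)
#' simulated-microscope timelapse statistics. Failures in a cell are
#' recorded and the sweep continues. Fully reproducible from the seeds; no
#' stage mutates an upstream artifact.
#'
#' @param config an [experiment_config()].
#' @return a list of class `nmx_results`: tibbles `mixing` (bead and
#'   community level), `clusters`, `histogram_modes`, `imaging`, `errors`,
#'   and the echoed `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "nmx_config"))
  mixing <- list(); clusters <- list(); modes <- list(); imaging <- list()
  errors <- list()
  for (mu in config$mu_grid) {
    for (sd_ in config$seeds) {
      key <- sprintf("mu=%g seed=%d", mu, sd_)
      res <- tryCatch({
        traj <- do.call(simulate_nucleolus,
                        c(list(n_beads = config$n_beads, mu = mu,
                               total_time = config$total_time, seed = sd_),
                          config$sim_extra))
        keep <- which(traj$times >= config$burn_in)
        bead <- mixing_summary(traj, level = "bead",
                               d_star = config$d_star_mixing, frames = keep)
        bead$mu <- mu; bead$seed <- sd_
        net <- build_temporal_network(traj, delta = config$delta,
                                      d_star = config$d_star_network,
                                      burn_in = config$burn_in)
        part <- optimize_louvain(net, gamma = config$gamma,
                                 omega = config$omega, seed = sd_)
        comm <- mixing_summary(part)
        comm$mu <- mu; comm$seed <- sd_
        cl <- dplyr::left_join(
          cluster_lifetimes(part),
          persistence_probability(part)[, c("community", "persistence")],
          by = "community")
        cl$mu <- mu; cl$seed <- sd_; cl$Q <- part$Q
        snap <- instantaneous_map(traj, frame = dim(traj$positions)[1],
                                  beads = "nucleolar")
        md <- tibble::tibble(mu = mu, seed = sd_,
                             lowest_mode_nm = lowest_distance_mode(snap),
                             n_modes = n_histogram_modes(snap))
        im <- NULL
        if (!is.null(config$imaging)) {
          im <- timelapse_image_stats(traj, config$imaging,
                                      burn_in = config$burn_in)
          im$mu <- mu; im$seed <- sd_
        }
        list(bead = bead, comm = comm, cl = cl, md = md, im = im)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- tibble::tibble(mu = mu, seed = sd_,
                                        message = conditionMessage(res))
      } else {
        mixing[[paste(key, "b")]] <- res$bead
        mixing[[paste(key, "c")]] <- res$comm
        clusters[[key]] <- res$cl
        modes[[key]] <- res$md
        if (!is.null(res$im)) imaging[[key]] <- res$im
      }
    }
  }
  out <- structure(list(mixing = dplyr::bind_rows(mixing),
                        clusters = dplyr::bind_rows(clusters),
                        histogram_modes = dplyr::bind_rows(modes),
                        imaging = dplyr::bind_rows(imaging),
                        errors = dplyr::bind_rows(errors),
                        config = config),
                   class = "nmx_results")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("mixing", "clusters", "histogram_modes", "imaging")) {
      if (nrow(out[[nm]]) > 0)
        utils::write.table(out[[nm]],
                           file.path(config$out_dir,
                                     paste0(nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out
}

#' @export
print.nmx_results <- function(x, ...) {
  cat("<nmx_results>", length(unique(x$mixing$mu)), "mu values x",
      length(x$config$seeds), "seeds;", nrow(x$errors), "failed cells\n")
  invisible(x)
}

#' Export per-frame bead positions as CSV
#'
#' @param trajectory an `nmx_trajectory`.
#' @param path file path.
#' @param frames frame subset (default all).
#' @export
write_positions_csv <- function(trajectory, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(dim(trajectory$positions)[1])
  rows <- lapply(frames, function(f) {
    p <- frame_positions(trajectory, f)
    data.frame(time = trajectory$times[f], bead = seq_len(nrow(p)),
               x = p[, 1], y = p[, 2], z = p[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
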