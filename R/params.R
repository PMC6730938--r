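#' Simulation parameters for the bead-spring crosslinking model
#'
#' Collects every physical and numerical parameter of the Brownian-dynamics
#' simulator. The single biological tuning parameter is `mu`, the kinetic
#' timescale (seconds) of the crosslink-competent ("active") bead state:
#' an active bead stays active for a duration drawn from N(mu, (mu/5)^2) and,
#' once inactive, re-activates after a duration drawn from N(mu/9, (mu/45)^2),
#' so beads are active ~90% of the time and the mean crosslink lifetime is
#' governed by mu alone.
#'
#' Lengths are in nanometres, times in seconds. Energies are expressed in
#' units where the drag coefficient is 1, so `kT` equals the free-bead
#' diffusivity D in nm^2/s; the default `kT = 16667` makes a free bead
#' diffuse (100 nm)^2 per 0.1 s.
#'
#' @param mu kinetic timescale of crosslink activity, seconds (> 0).
#' @param total_time simulated time in seconds.
#' @param d_link crosslink capture radius in nm: two active, unlinked,
#'   non-adjacent nucleolar beads closer than this form a crosslink.
#' @param nucleus_radius radius of the spherical nuclear domain, nm.
#' @param dt integrator step, seconds; must be smaller than `save_interval`.
#' @param save_interval spacing of saved frames, seconds.
#' @param kT thermal energy in drag units (nm^2/s); equals the free-bead
#'   diffusivity.
#' @param drag isotropic Stokes drag coefficient (sets the unit of force).
#' @param contour_length contour length L0 of one backbone wormlike-chain
#'   spring, nm. Neighbour beads can never separate beyond L0.
#' @param persistence_scale stiffness scale Lp of the backbone Marko-Siggia
#'   spring force (kT/Lp prefactor), nm. Smaller values give stiffer
#'   springs; the default keeps chain neighbours at ~150 nm, outside the
#'   crosslink capture radius, so crosslinks reflect genuine spatial
#'   contacts.
#' @param link_contour_length,link_persistence_scale the same two scales for
#'   the crosslink spring. The default link spring is much stiffer than the
#'   backbone: a crosslinked pair is pulled to the excluded-volume contact
#'   distance (~50 nm) well within one crosslink lifetime, which makes
#'   transient contacts sticky when the inactive period is short.
#' @param max_extension extension ratio at which the diverging Marko-Siggia
#'   force is capped, keeping the integrator stable.
#' @param repulsion_radius soft excluded-volume radius, nm; beads closer than
#'   twice this repel.
#' @param repulsion_strength linear soft-repulsion spring constant (1/s in
#'   drag units).
#' @param wall_strength restoring-force constant pulling beads outside the
#'   nucleus back inside (1/s); beads are additionally projected onto the
#'   sphere after every step.
#' @param on_mean,on_sd,off_mean,off_sd activity-duration distribution
#'   parameters; default to the mu-scaled values above and rarely need
#'   changing.
#' @param seed integer seed controlling all randomness of a simulation.
#'
#' @return an object of class `nmx_params` (a validated list).
#' @export
#' @examples
#' p <- sim_params(mu = 0.09, total_time = 10)
#' p$on_mean / p$off_mean  # active:inactive mean ratio of 9
sim_params <- function(mu,
                       total_time,
                       d_link = 90,
                       nucleus_radius = 1000,
                       dt = 1e-4,
                       save_interval = 0.1,
                       kT = 100^2 / (6 * 0.1),
                       drag = 1,
                       contour_length = 200,
                       persistence_scale = 150,
                       link_contour_length = 200,
                       link_persistence_scale = 0.4,
                       max_extension = 0.97,
                       repulsion_radius = 50,
                       repulsion_strength = 300,
                       wall_strength = 1e4,
                       on_mean = mu,
                       on_sd = mu / 5,
                       off_mean = mu / 9,
                       off_sd = mu / 45,
                       seed = 1L) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu > 0)
  stopifnot(d_link > 0, nucleus_radius > 0, total_time > 0)
  stopifnot(dt > 0, save_interval > 0, dt < save_interval)
  stopifnot(contour_length > 0, persistence_scale > 0,
            link_contour_length > 0, link_persistence_scale > 0,
            repulsion_radius > 0, kT >= 0, drag > 0,
            max_extension > 0, max_extension < 1)
  p <- list(mu = mu, on_mean = on_mean, on_sd = on_sd,
            off_mean = off_mean, off_sd = off_sd,
            d_link = d_link, nucleus_radius = nucleus_radius,
            dt = dt, save_interval = save_interval, total_time = total_time,
            kT = kT, drag = drag, contour_length = contour_length,
            persistence_scale = persistence_scale,
            link_contour_length = link_contour_length,
            link_persistence_scale = link_persistence_scale,
            max_extension = max_extension,
            repulsion_radius = repulsion_radius,
            repulsion_strength = repulsion_strength,
            wall_strength = wall_strength,
            seed = as.integer(seed))
  structure(p, class = "nmx_params")
}

#' @export
print.nmx_params <- function(x, ...) {
  cat("<nmx_params> mu =", x$mu, "s, total_time =", x$total_time,
      "s, dt =", x$dt, "s\n")
  cat("  d_link =", x$d_link, "nm, nucleus radius =", x$nucleus_radius,
      "nm, seed =", x$seed, "\n")
  invisible(x)
}
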