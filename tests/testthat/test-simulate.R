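# Simulator contracts: initialization, force law, free diffusion, activity
# kinetics, crosslink matching and trajectory invariants.

test_that("tethered chain ends sit exactly on the wall, interior beads
           inside the sphere", {
  topo <- nucleolus_topology(2)
  p2 <- sim_params(mu = 0.1, total_time = 1, nucleus_radius = 90)
  init <- init_configuration(topo, p2, seed = 3)
  r <- sqrt(rowSums(init$positions^2))
  expect_equal(r, c(90, 90))
  expect_true(all(init$tethered))

  p <- sim_params(mu = 0.1, total_time = 1, nucleus_radius = 500)
  topo2 <- nucleolus_topology(50)
  init2 <- init_configuration(topo2, p, seed = 3)
  r2 <- sqrt(rowSums(init2$positions^2))
  expect_equal(r2[c(1, 50)], c(500, 500))
  expect_true(all(r2 <= 500 + 1e-9))
})

test_that("full-genome preset initializes 2803 beads inside the nucleus", {
  topo <- yeast_genome_topology()
  expect_equal(topo$n_beads, 2803L)
  expect_equal(nrow(topo$chains), 32L)
  expect_equal(sum(topo$nucleolar_mask), 361L)
  nuc <- which(topo$nucleolar_mask)
  expect_true(all(diff(nuc) == 1))
  p <- sim_params(mu = 0.09, total_time = 1)
  init <- init_configuration(topo, p, seed = 1)
  expect_true(all(sqrt(rowSums(init$positions^2)) <= 1000 + 1e-9))
})

test_that("an over-stretched chain raises a configuration error", {
  topo <- nucleolus_topology(3)
  p <- sim_params(mu = 0.1, total_time = 1, nucleus_radius = 500,
                  contour_length = 100)
  # 2 springs x 100 nm cannot span the 1000 nm diameter
  expect_error(init_configuration(topo, p, seed = 1), "too long")
})

test_that("initialization and simulation are bitwise deterministic under a
           fixed seed", {
  topo <- nucleolus_topology(20)
  p <- sim_params(mu = 0.09, total_time = 1, nucleus_radius = 400,
                  seed = 11)
  i1 <- init_configuration(topo, p)
  i2 <- init_configuration(topo, p)
  expect_identical(i1$positions, i2$positions)
  t1 <- simulate_chromatin(topo, p)
  t2 <- simulate_chromatin(topo, p)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$link_log, t2$link_log)
})

test_that("force evaluation matches hand evaluation of the Marko-Siggia
           law and is Newton-symmetric", {
  p <- sim_params(mu = 0.1, total_time = 1, persistence_scale = 10,
                  contour_length = 200, link_persistence_scale = 10,
                  link_contour_length = 200)
  # two linked beads at 150 nm: u = 0.75
  pos <- rbind(c(0, 0, 0), c(150, 0, 0))
  f <- compute_forces(pos, p, links = rbind(c(1, 2)))
  f_hand <- (p$kT / 10) * (0.25 / (1 - 0.75)^2 - 0.25 + 0.75)
  expect_equal(f[1, 1], f_hand)        # pulled toward +x
  expect_equal(f[2, 1], -f_hand)
  expect_equal(f[1, ], -f[2, ])
  expect_equal(f[, 2], c(0, 0)); expect_equal(f[, 3], c(0, 0))

  # co-located pair: zero-force extension of the spring
  pos0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  f0 <- compute_forces(pos0, p, springs = rbind(c(1, 2)))
  expect_equal(f0, matrix(0, 2, 3))

  # isolated bead at the origin
  expect_equal(compute_forces(matrix(0, 1, 3), p), matrix(0, 1, 3))

  # soft repulsion: linear in overlap below 2 * repulsion_radius
  pos_r <- rbind(c(0, 0, 0), c(40, 0, 0))
  fr <- compute_forces(pos_r, p)
  ov <- 2 * p$repulsion_radius - 40
  expect_equal(fr[1, 1], -p$repulsion_strength * ov)
  expect_equal(fr[2, 1], p$repulsion_strength * ov)

  # wall restoring force points inward for a bead outside the sphere
  pos_w <- matrix(c(p$nucleus_radius + 10, 0, 0), 1, 3)
  fw <- compute_forces(pos_w, p)
  expect_equal(fw[1, 1], -p$wall_strength * 10)

  expect_error(compute_forces(matrix(c(NaN, 0, 0), 1, 3), p),
               "non-finite")
})

test_that("a free bead diffuses with MSD = 6 D t", {
  chains <- data.frame(first_bead = 1L, last_bead = 1L,
                       tether_start = NA_integer_, tether_end = NA_integer_)
  topo <- genome_topology(chains, FALSE, rbind(c(0, 0, 1)))
  msd <- vapply(1:100, function(s) {
    p <- sim_params(mu = 0.1, total_time = 1, nucleus_radius = 1e6,
                    save_interval = 0.5, seed = s)
    traj <- simulate_chromatin(topo, p)
    sum((traj$positions[3, 1, ] - traj$positions[1, 1, ])^2)
  }, numeric(1))
  D <- sim_params(mu = 0.1, total_time = 1)$kT
  expected <- 6 * D * 1
  se <- sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - expected), 3 * se)
  # and the calibration: ~(100 nm)^2 over 0.1 s
  expect_equal(6 * D * 0.1, 100^2)
})

test_that("zero temperature and no forces leave positions unchanged", {
  chains <- data.frame(first_bead = 1L, last_bead = 1L,
                       tether_start = NA_integer_, tether_end = NA_integer_)
  topo <- genome_topology(chains, FALSE, rbind(c(0, 0, 1)))
  p <- sim_params(mu = 0.1, total_time = 0.5, kT = 0, nucleus_radius = 1e6,
                  seed = 2)
  traj <- simulate_chromatin(topo, p)
  expect_equal(traj$positions[1, 1, ],
               traj$positions[dim(traj$positions)[1], 1, ])
})

test_that("logged activity durations recover the mu-scaled distributions", {
  traj <- cached_sim("act19", simulate_nucleolus(
    n_beads = 40, mu = 0.19, total_time = 30, seed = 4,
    log_activity = TRUE))
  act <- traj$activity_log
  on <- act$duration[act$was_active]
  off <- act$duration[!act$was_active]
  expect_gt(length(on), 1000)
  se_on <- sd(on) / sqrt(length(on))
  expect_lt(abs(mean(on) - 0.19), 3 * se_on)
  # sd recovery: SE of a normal SD estimate is sd / sqrt(2 n)
  expect_lt(abs(sd(on) - 0.19 / 5), 3 * sd(on) / sqrt(2 * length(on)))
  se_off <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - 0.19 / 9), 3 * se_off)
  # long-run active fraction: mu / (mu + mu/9) = 0.9
  frac_active <- sum(on) / (sum(on) + sum(off))
  expect_lt(abs(frac_active - 0.9), 0.02)
})

test_that("greedy matcher follows ascending-distance hand traces", {
  # d(A,B) = 50, d(B,C) = 60, d(A,C) = 200, capture 90: only {A,B} links
  pos <- rbind(c(0, 0, 0), c(50, 0, 0), c(106.3, 20, 0))
  pos[3, ] <- pos[2, ] + c(59.9, 0, 0) + c(0, 2, 0)
  active <- rep(TRUE, 3)
  pairs <- match_crosslink_pairs(pos, active, d_link = 90,
                                 adjacent = function(i, j) FALSE)
  expect_equal(nrow(pairs), 1)
  expect_equal(unname(pairs[1, ]), c(1L, 2L))
  # adjacent chain neighbours never link
  pos2 <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(nrow(match_crosslink_pairs(pos2, c(TRUE, TRUE),
                                          d_link = 90)), 0)
  # inactive beads never link
  expect_equal(nrow(match_crosslink_pairs(pos, c(TRUE, FALSE, TRUE),
                                          d_link = 90,
                                          adjacent = function(i, j) FALSE)),
               0)
  # linked beads are skipped
  expect_equal(nrow(match_crosslink_pairs(pos, active,
                                          linked = c(TRUE, TRUE, FALSE),
                                          d_link = 90,
                                          adjacent = function(i, j) FALSE)),
               0)
})

test_that("trajectory invariants hold on a scaled run: confinement, link
           legality, chain connectivity, frame grid", {
  traj <- cached_sim("inv09", simulate_nucleolus(
    n_beads = 60, mu = 0.09, total_time = 10, seed = 6))
  R <- traj$params$nucleus_radius
  n_frames <- dim(traj$positions)[1]
  expect_equal(n_frames, 101)
  expect_equal(diff(traj$times), rep(0.1, 100), tolerance = 1e-9)
  # confinement at every saved frame
  r <- sqrt(traj$positions[, , 1]^2 + traj$positions[, , 2]^2 +
            traj$positions[, , 3]^2)
  expect_true(all(r <= R + 1e-6))
  # tethered ends stay on the wall
  expect_true(all(abs(r[, 1] - R) < 1e-6))
  expect_true(all(abs(r[, 60] - R) < 1e-6))
  # chain connectivity: neighbour separations never exceed L0
  L0 <- traj$params$contour_length
  sep <- sqrt((traj$positions[, 1:59, 1] - traj$positions[, 2:60, 1])^2 +
              (traj$positions[, 1:59, 2] - traj$positions[, 2:60, 2])^2 +
              (traj$positions[, 1:59, 3] - traj$positions[, 2:60, 3])^2)
  expect_true(all(sep <= L0))
  # link log legality: nucleolar, non-adjacent, intervals ordered, and one
  # link per bead at a time
  ll <- traj$link_log
  expect_true(all(abs(ll$bead_i - ll$bead_j) > 1))
  closed <- !is.na(ll$t_broken)
  expect_true(all(ll$t_broken[closed] > ll$t_formed[closed]))
  ll$t_end <- ifelse(is.na(ll$t_broken), Inf, ll$t_broken)
  for (b in unique(c(ll$bead_i, ll$bead_j))) {
    iv <- ll[ll$bead_i == b | ll$bead_j == b, ]
    iv <- iv[order(iv$t_formed), ]
    if (nrow(iv) > 1)
      expect_true(all(iv$t_formed[-1] >= iv$t_end[-nrow(iv)] - 1e-12))
  }
})

test_that("mean link lifetime tracks the activity timescale", {
  traj9 <- cached_sim("inv09", simulate_nucleolus(
    n_beads = 60, mu = 0.09, total_time = 10, seed = 6))
  traj90 <- cached_sim("inv90", simulate_nucleolus(
    n_beads = 60, mu = 0.9, total_time = 10, seed = 6))
  life <- function(tr) {
    ll <- tr$link_log
    mean(ll$t_broken[!is.na(ll$t_broken)] -
         ll$t_formed[!is.na(ll$t_broken)])
  }
  # lifetimes are bounded by the remaining active durations of the two
  # endpoints, so they scale (sub-linearly) with mu
  expect_gt(life(traj90), 3 * life(traj9))
  expect_lt(life(traj9), 0.09)
})
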