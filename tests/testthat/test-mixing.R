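# Interval extraction and the four mixing statistics, against hand traces
# and a brute-force oracle on scripted distances.

test_that("interval extraction follows the run-length hand trace", {
  iv <- pair_interaction_intervals(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                                   step_seconds = 0.1)
  runs <- iv[iv$type == "interaction", ]
  expect_equal(runs$duration, c(0.2, 0.1))
  waits <- iv[iv$type == "wait", ]
  expect_equal(nrow(waits), 1)
  expect_equal(waits$duration, 0.3)
  expect_false(waits$censored)

  # all-false: no interactions, no usable waits
  iv0 <- pair_interaction_intervals(rep(FALSE, 5), 0.1)
  expect_equal(sum(iv0$type == "interaction"), 0)
  expect_true(all(iv0$censored[iv0$type == "wait"]))

  # all-true: one interaction spanning the series, zero waits
  iv1 <- pair_interaction_intervals(rep(TRUE, 7), 0.1)
  expect_equal(nrow(iv1), 1)
  expect_equal(iv1$type, "interaction")
  expect_equal(iv1$duration, 0.7)

  # leading and trailing gaps are censored, interior gaps are not
  iv2 <- pair_interaction_intervals(c(FALSE, TRUE, FALSE, TRUE, FALSE), 0.1)
  waits2 <- iv2[iv2$type == "wait", ]
  expect_equal(waits2$censored, c(TRUE, FALSE, TRUE))
})

test_that("interaction + waiting + censored time conserves the series
           duration", {
  set.seed(8)
  for (rep in 1:20) {
    s <- runif(50) < 0.4
    iv <- pair_interaction_intervals(s, 0.1)
    expect_equal(sum(iv$duration), 5, tolerance = 1e-9)
  }
})

test_that("bead-level summary matches hand computation on scripted
           positions", {
  # 3 beads on a line; only pair (1,2) ever comes below d* = 100
  arr <- array(0, c(4, 3, 3))
  x2 <- c(80, 120, 90, 80)           # bead 2's x over 4 frames
  for (f in 1:4) {
    arr[f, 2, 1] <- x2[f]
    arr[f, 3, 1] <- 500
  }
  traj <- structure(list(times = seq(0, 0.3, 0.1), positions = arr,
                         topology = nucleolus_topology(3),
                         params = sim_params(mu = 0.1, total_time = 1)),
                    class = "nmx_trajectory")
  mx <- mixing_summary(traj, level = "bead", d_star = 100)
  expect_equal(mx$interaction_fraction, 1 / 3)
  # pair (1,2) series: T F T T -> runs 0.1 and 0.2 s; one wait 0.1 s
  expect_equal(mx$mean_interaction_duration, 0.15)
  expect_equal(mx$mean_waiting_time, 0.1)
  # degree: frames with the pair interacting contribute 2 edges over 3 beads
  expect_equal(mx$mean_interaction_number, mean(c(2, 0, 2, 2) / 3))
})

test_that("bead-level summary agrees with an rle-based brute force on a
           simulated run", {
  traj <- cached_sim("inv09", simulate_nucleolus(
    n_beads = 60, mu = 0.09, total_time = 10, seed = 6))
  mx <- mixing_summary(traj, level = "bead", d_star = 100)
  # brute force over all pairs
  n <- 60; frames <- dim(traj$positions)[1]
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  series <- matrix(FALSE, nrow(pr), frames)
  for (f in seq_len(frames)) {
    d <- as.matrix(dist(frame_positions(traj, f)))
    series[, f] <- d[pr] < 100
  }
  durs <- c(); waits <- c(); nruns <- 0; truet <- 0
  for (k in seq_len(nrow(pr))) {
    iv <- pair_interaction_intervals(series[k, ], 0.1)
    runs <- iv[iv$type == "interaction", ]
    nruns <- nruns + nrow(runs); truet <- truet + sum(runs$duration)
    w <- iv[iv$type == "wait" & !iv$censored, ]
    waits <- c(waits, w$duration)
  }
  expect_equal(mx$interaction_fraction, mean(rowSums(series) > 0))
  expect_equal(mx$mean_interaction_duration, truet / nruns)
  expect_equal(mx$mean_waiting_time, mean(waits))
  expect_equal(mx$mean_interaction_number,
               mean(colSums(series) * 2 / n))
})

test_that("community-level summary on a static one-cluster assignment", {
  labels <- matrix(1L, 5, 4)
  part <- structure(list(labels = labels, Q = 1, gamma = 10, omega = 1,
                         window_seconds = 1, n_nodes = 5, n_layers = 4,
                         seed = 1L),
                    class = "nmx_partition")
  mx <- mixing_summary(part)
  expect_equal(mx$interaction_fraction, 1)
  expect_true(is.na(mx$mean_waiting_time))      # no gaps ever
  expect_equal(mx$mean_interaction_number, 4)   # k - 1 co-members
  expect_equal(mx$mean_interaction_duration, 4) # one run x 4 windows x 1 s
})

test_that("cluster lifetimes and sizes follow the layer bookkeeping", {
  # one community populated in layers 3..7 of 8, 1-s windows
  labels <- matrix(10L + seq_len(6), 6, 8)   # default: everyone distinct
  labels[1:3, 3:7] <- 99L
  part <- structure(list(labels = labels, Q = 0, gamma = 10, omega = 1,
                         window_seconds = 1, n_nodes = 6, n_layers = 8,
                         seed = 1L),
                    class = "nmx_partition")
  cl <- cluster_lifetimes(part)
  row99 <- cl[cl$community == 99, ]
  expect_equal(row99$lifetime, 5)
  expect_equal(row99$mean_size, 3)
  # a singleton label present in one layer only
  single <- cl[cl$community == 11, ]
  expect_equal(single$lifetime, 8)   # label 11 present every layer here
  # static partition: every community lives the full span
  static <- structure(list(labels = matrix(rep(1:2, 3), 6, 4), Q = 0,
                           gamma = 10, omega = 1, window_seconds = 1,
                           n_nodes = 6, n_layers = 4, seed = 1L),
                      class = "nmx_partition")
  expect_true(all(cluster_lifetimes(static)$lifetime == 4))
})

test_that("persistence probability matches hand traces", {
  # fully static labels: persistence 1
  static <- structure(list(labels = matrix(rep(1:2, 3), 6, 4), Q = 0,
                           gamma = 10, omega = 1, window_seconds = 1,
                           n_nodes = 6, n_layers = 4, seed = 1L),
                      class = "nmx_partition")
  expect_true(all(persistence_probability(static)$persistence == 1))

  # completely reshuffled labels: persistence 0
  labels <- matrix(0L, 4, 3)
  for (s in 1:3) labels[, s] <- (s - 1) * 4 + 1:4
  resh <- structure(list(labels = labels, Q = 0, gamma = 10, omega = 1,
                         window_seconds = 1, n_nodes = 4, n_layers = 3,
                         seed = 1L),
                    class = "nmx_partition")
  expect_true(all(persistence_probability(resh)$persistence == 0))

  # 1 of 4 members departs at each transition (another joins, keeping the
  # community at 4 members): persistence (3 + 3) / (4 + 4) = 0.75
  lab <- matrix(5L, 5, 3)
  lab[5, 1] <- 8L                       # bead 5 joins community 5 at layer 2
  lab[1, 2] <- 6L; lab[1, 3] <- 6L      # bead 1 departs after layer 1
  lab[2, 3] <- 7L                       # bead 2 departs after layer 2
  dep <- structure(list(labels = lab, Q = 0, gamma = 10, omega = 1,
                        window_seconds = 1, n_nodes = 5, n_layers = 3,
                        seed = 1L),
                   class = "nmx_partition")
  p5 <- persistence_probability(dep)
  expect_equal(p5$persistence[p5$community == 5], 0.75)
})

test_that("interaction fraction is non-decreasing in d_star", {
  traj <- cached_sim("inv09", simulate_nucleolus(
    n_beads = 60, mu = 0.09, total_time = 10, seed = 6))
  f <- vapply(c(50, 100, 200, 400), function(d)
    mixing_summary(traj, level = "bead", d_star = d)$interaction_fraction,
    numeric(1))
  expect_true(all(diff(f) >= 0))
})
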