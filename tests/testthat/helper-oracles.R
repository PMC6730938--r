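# Shared helpers: set-partition enumeration (exhaustive modularity oracle),
# a brute-force single-layer modularity evaluator written independently of
# the package's multilayer evaluator, and a memoized cache of simulations
# shared across test files.

# all set partitions of 1..n as integer label vectors (canonical form)
enumerate_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in enumerate_partitions(n - 1)) {
    k <- max(p)
    for (lab in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, lab)
  }
  out
}

# independent single-layer modularity: dense loop over ordered pairs
brute_modularity_single <- function(A, labels, gamma = 1) {
  n <- nrow(A)
  k <- rowSums(A)
  two_m <- sum(k)
  q <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (labels[i] == labels[j])
        q <- q + A[i, j] - gamma * k[i] * k[j] / two_m
  q / two_m
}

# independent multilayer modularity: dense loops, straight off the formula
brute_modularity_multi <- function(layers, labels, gamma, omega) {
  n <- nrow(layers[[1]]); T_ <- length(layers)
  k <- sapply(layers, rowSums)                      # n x T
  two_m <- colSums(k)
  num <- 0
  for (s in seq_len(T_)) {
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (labels[i, s] == labels[j, s]) {
          num <- num + layers[[s]][i, j]
          if (two_m[s] > 0)
            num <- num - gamma * k[i, s] * k[j, s] / two_m[s]
        }
    for (r in seq_len(T_))
      if (abs(s - r) == 1)
        for (i in seq_len(n))
          if (labels[i, s] == labels[i, r]) num <- num + omega
  }
  two_mu <- sum(two_m) + 2 * omega * n * (T_ - 1)
  num / two_mu
}

# memoized small simulations reused across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr),
                                               envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# independent Otsu oracle: exhaustive scan over all split points of the
# 256-bin histogram, class statistics recomputed with plain loops
brute_otsu <- function(image, n_bins = 256) {
  v <- as.vector(image)
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  counts <- integer(n_bins)
  for (x in v) {
    b <- max(1L, min(n_bins, findInterval(x, breaks, all.inside = TRUE)))
    counts[b] <- counts[b] + 1L
  }
  best <- -Inf
  best_k <- 1L
  for (k in seq_len(n_bins - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  breaks[best_k + 1]
}
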