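#' Genome topology for the bead-spring model
#'
#' Describes how beads are organized into chains (chromosome arms), which
#' beads belong to the nucleolus (and may therefore crosslink), and where
#' chain ends are tethered on the nuclear wall. Each bead represents a 5 kbp
#' chromosome domain by default.
#'
#' @param chains a data frame with one row per chain and columns
#'   `first_bead`, `last_bead` (1-based, contiguous, partitioning
#'   `1:n_beads`), `tether_start`, `tether_end` (row indices into
#'   `tether_sites`, or `NA` for an untethered end).
#' @param nucleolar_mask logical vector, one entry per bead; must be a single
#'   contiguous run inside one chain (the rDNA array).
#' @param tether_sites numeric matrix of unit vectors (rows), the directions
#'   of the wall-anchoring sites; they are scaled by the nucleus radius at
#'   initialization.
#' @param bead_bp base pairs represented by one bead.
#'
#' @return an object of class `nmx_topology`.
#' @export
genome_topology <- function(chains, nucleolar_mask, tether_sites,
                            bead_bp = 5000) {
  chains <- as.data.frame(chains)
  stopifnot(all(c("first_bead", "last_bead", "tether_start", "tether_end")
                %in% names(chains)))
  n_beads <- max(chains$last_bead)
  covered <- unlist(Map(seq, chains$first_bead, chains$last_bead))
  if (length(covered) != n_beads || anyDuplicated(covered) ||
      !setequal(covered, seq_len(n_beads)))
    stop("chains must partition bead indices 1..n_beads")
  stopifnot(length(nucleolar_mask) == n_beads, is.logical(nucleolar_mask))
  nuc <- which(nucleolar_mask)
  if (length(nuc) > 0) {
    if (any(diff(nuc) != 1))
      stop("nucleolar beads must form one contiguous run")
    chain_of <- chain_index(chains, n_beads)
    if (length(unique(chain_of[nuc])) != 1)
      stop("nucleolar beads must lie within a single chain")
  }
  tether_sites <- as.matrix(tether_sites)
  stopifnot(ncol(tether_sites) == 3)
  # normalize site directions
  tether_sites <- tether_sites / sqrt(rowSums(tether_sites^2))
  structure(list(n_beads = n_beads, chains = chains,
                 nucleolar_mask = nucleolar_mask,
                 tether_sites = tether_sites, bead_bp = bead_bp),
            class = "nmx_topology")
}

chain_index <- function(chains, n_beads) {
  out <- integer(n_beads)
  for (k in seq_len(nrow(chains)))
    out[chains$first_bead[k]:chains$last_bead[k]] <- k
  out
}

#' Scaled nucleolar-chain topology
#'
#' A desk-scale surrogate for the full-genome nucleolus: a single chain of
#' crosslink-competent beads with both ends tethered at antipodal points of
#' the nuclear wall. All beads are nucleolar.
#'
#' @param n_beads chain length in beads (the full rDNA array has 361).
#' @return an `nmx_topology`.
#' @export
#' @examples
#' topo <- nucleolus_topology(120)
#' sum(topo$nucleolar_mask)
nucleolus_topology <- function(n_beads = 200) {
  stopifnot(n_beads >= 2)
  chains <- data.frame(first_bead = 1L, last_bead = as.integer(n_beads),
                       tether_start = 1L, tether_end = 2L)
  sites <- rbind(c(0, 0, 1), c(0, 0, -1))
  genome_topology(chains, rep(TRUE, n_beads), sites)
}

# Approximate S. cerevisiae karyotype: chromosome and centromere positions in
# kb (reference assembly; the rDNA repeat array is inserted separately).
yeast_karyotype <- function() {
  data.frame(
    chr = 1:16,
    size_kb = c(230, 813, 317, 1532, 577, 270, 1091, 563, 440, 746, 667,
                1078, 924, 784, 1091, 948),
    cen_kb = c(151, 238, 114, 450, 152, 149, 497, 106, 356, 436, 440,
               151, 268, 629, 327, 556))
}

#' Full yeast-genome topology preset
#'
#' All 16 chromosomes resolved into 5 kbp beads arranged on 32 arms. Each arm
#' is a chain tethered at both ends: the centromere end to a site in the
#' centromere cluster near one pole, the telomere end to one of six telomere
#' sites. The nucleolus is a contiguous block of 361 beads (the rDNA array)
#' on the right arm of chromosome XII. Arm lengths follow the standard yeast
#' karyotype rounded to 5 kb, padded so the preset contains exactly 2803
#' beads in total.
#'
#' @return an `nmx_topology` with 2803 beads, 32 chains and 361 nucleolar
#'   beads.
#' @export
yeast_genome_topology <- function() {
  kar <- yeast_karyotype()
  left <- pmax(2L, as.integer(round(kar$cen_kb / 5)))
  right <- pmax(2L, as.integer(round((kar$size_kb - kar$cen_kb) / 5)))
  rdna <- 361L
  pad <- 2803L - (sum(left) + sum(right) + rdna)
  left[4] <- left[4] + pad  # absorb rounding residual in the largest chromosome
  # centromere cluster sites near the north pole, telomere sites spread below
  cen_sites <- t(vapply(1:16, function(k) {
    a <- 2 * pi * k / 16
    c(sin(0.25) * cos(a), sin(0.25) * sin(a), cos(0.25))
  }, numeric(3)))
  tel_sites <- t(vapply(1:6, function(k) {
    a <- 2 * pi * k / 6
    c(sin(2.3) * cos(a), sin(2.3) * sin(a), cos(2.3))
  }, numeric(3)))
  sites <- rbind(cen_sites, tel_sites)

  first <- integer(0); last <- integer(0); ts <- integer(0); te <- integer(0)
  pos <- 1L
  n_arm <- 0L
  for (k in 1:16) {
    for (arm in 1:2) {
      len <- if (arm == 1) left[k] else right[k]
      if (k == 12 && arm == 2) len <- len + rdna
      n_arm <- n_arm + 1L
      first <- c(first, pos); last <- c(last, pos + len - 1L)
      ts <- c(ts, k)                          # centromere-cluster site
      te <- c(te, 16L + (n_arm - 1L) %% 6L + 1L)  # one of six telomere sites
      pos <- pos + len
    }
  }
  n_beads <- pos - 1L
  mask <- rep(FALSE, n_beads)
  # rDNA block: inside chr XII right arm (chain 24), after the first
  # non-nucleolar stretch
  arm12r <- 24L
  offset <- first[arm12r] + right[12] %/% 2L
  mask[offset:(offset + rdna - 1L)] <- TRUE
  chains <- data.frame(first_bead = first, last_bead = last,
                       tether_start = ts, tether_end = te)
  genome_topology(chains, mask, sites)
}

#' @export
print.nmx_topology <- function(x, ...) {
  cat("<nmx_topology>", x$n_beads, "beads,", nrow(x$chains), "chain(s),",
      sum(x$nucleolar_mask), "nucleolar\n")
  invisible(x)
}

# backbone springs (pairs of consecutive beads within a chain), 1-based
topology_springs <- function(topology) {
  out <- lapply(seq_len(nrow(topology$chains)), function(k) {
    f <- topology$chains$first_bead[k]; l <- topology$chains$last_bead[k]
    if (l > f) cbind(f:(l - 1L), (f + 1L):l) else NULL
  })
  do.call(rbind, out)
}
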