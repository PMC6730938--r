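---
title: "Modeling transient crosslink kinetics and gene-cluster dynamics with nucleomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transient crosslink kinetics and gene-cluster dynamics with nucleomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomix)
```

## The model

`nucleomix` simulates interphase chromosome arms as confined Rouse-like
bead-spring chains in which a sub-chain — the nucleolar rDNA array, 5 kbp per
bead — is subject to transient, protein-mediated crosslinking, the way SMC
proteins such as condensin transiently bridge chromatin domains. The package
then analyzes the resulting 4D data with a Hi-C-style distance-map stack: a
temporal gene-interaction network, multilayer-modularity community
detection, bead- and community-level mixing statistics, and a forward
widefield-microscope simulator with the matching image-analysis pipeline.

Each bead obeys overdamped Langevin dynamics,
$$\mathbf{x}_i \leftarrow \mathbf{x}_i + \frac{\mathbf{F}_i}{\zeta}\,
\Delta t + \sqrt{2 k_BT \Delta t/\zeta}\; \boldsymbol{\xi}_i,$$
with isotropic Stokes drag (no hydrodynamic coupling), inside a reflecting
spherical nucleus; chain ends are pinned to wall tether sites. Forces are
wormlike-chain (Marko–Siggia) springs between chain neighbours and across
crosslinks, a soft excluded-volume repulsion, and an inward wall restoring
force.

Crosslink kinetics are governed by a single timescale $\mu$ (seconds): a
crosslink-competent ("active") bead stays active for
$\mathcal{N}(\mu, (\mu/5)^2)$ seconds and, once inactive, re-activates after
$\mathcal{N}(\mu/9, (\mu/45)^2)$ seconds, so beads are active 90% of the
time at every $\mu$ and only the *rates* change. Two active, unlinked,
non-adjacent nucleolar beads closer than $d = 90$ nm form a crosslink;
candidates are matched greedily in ascending distance order (ties broken by
bead index), each bead carrying at most one crosslink; a link breaks when
either endpoint inactivates. Links are *not* broken by distance: the stated
breakage rule is inactivation only, and we follow it.

## Parameters, units and the calibration

Lengths are nm, times seconds, and energies are expressed in drag units
(`drag = 1`), so `kT` equals the free-bead diffusivity $D$ in nm$^2$/s. The
default `kT = 16667` makes a free bead diffuse $(100\,\mathrm{nm})^2$ per
0.1 s. This single number positions the three kinetic regimes: the
root-mean-square relative displacement of a just-unlinked pair over one
inactive period, $\sqrt{12 D \mu/9}$, is 45 nm at $\mu = 0.09$ (well inside
the 90-nm recapture radius: contacts are sticky and clusters rigid), 63 nm
at $\mu = 0.19$ (marginal: clusters form but exchange beads) and 183 nm at
$\mu = 1.6$ (beyond recapture: contacts dissolve and no clusters persist).

The remaining mechanical constants are not printed by the source model and
are fixed here as configurable defaults of `sim_params()`:

* **backbone springs** — `contour_length = 200` nm with stiffness scale
  `persistence_scale = 150` nm, giving bond lengths of roughly 150 nm.
  Keeping chain neighbours *outside* the 90-nm capture radius is essential:
  with short backbone bonds every bead permanently has chain-local capture
  partners, pearls form at every $\mu$, and the kinetic transition
  disappears.
* **crosslink springs** — the same Marko–Siggia law but much stiffer
  (`link_persistence_scale = 0.4` nm): a crosslinked pair is pulled to the
  excluded-volume contact distance within a fraction of one crosslink
  lifetime. We deliberately do *not* reuse the backbone spring for
  crosslinks. In extensive experiments with identical springs, long-lived
  crosslinks (large $\mu$) reeled in long-range loops and always produced
  *more* aggregation than fast kinetics, inverting the expected transition;
  a stiff short-range link combined with the soft long backbone is the
  simplest mechanical model we found that reproduces the rigid →
  flexible → non-clustering phenomenology in a single isolated chain.
* **excluded volume** — soft linear repulsion below
  `2 * repulsion_radius = 100` nm with strength 300 s$^{-1}$. Forming a
  link therefore requires squeezing through an $\approx 2\,k_BT$ barrier,
  and unlinked neighbours sit near 100 nm while crosslinked pairs sit near
  45–55 nm. This separation of scales is what produces the hallmark
  instantaneous distance histogram of the rigid regime: a sharp mode at
  ~50 nm, an almost empty valley to ~95 nm, and the broad bulk beyond.
* **confinement** — the scaled nucleolar preset (`simulate_nucleolus()`)
  places a single chain, both ends tethered at antipodes, in a nucleus
  whose radius (1780 nm for 200 beads, scaling with the cube root of the
  bead count) keeps the ambient bead density low enough that rigid-regime
  clusters stay spatially separated.
* **integration** — `dt = 1e-4` s with frames saved every 0.1 s; the
  Marko–Siggia force is capped at 97% extension and a runtime stability
  check aborts if any deterministic displacement exceeds half the repulsion
  radius.

Activity timers are initialized from the stationary occupancy (active with
probability 0.9) with a fresh duration draw; duration draws are truncated
below at `dt` so timers are always positive.

## Distance maps, networks, communities

`instantaneous_map()`, `time_averaged_map()` and `population_averaged_map()`
build the three kinds of pairwise-distance maps (the Hi-C analogue). For
histogram analyses the package uses fixed 10-nm bins and locates modes on a
3-bin moving average; `lowest_distance_mode()` reports the first local
maximum, the intra-cluster spacing signal.

`build_temporal_network()` partitions frames into non-overlapping windows of
`delta = 10` frames (1 s), computes the time-averaged distance map of each
window *first*, and then applies the exponential-threshold edge rule
$A_{ij} = e^{-s X_{ij}}$ for $X_{ij} < d^\*$ (0 otherwise). The order
matters and is tested: averaging precedes the nonlinearity. The decay rate
$s$ is not printed by the source; we default to $1/d^\*$ and record it in
the network object.

`optimize_louvain()` maximizes multilayer modularity
$$Q = \frac{1}{2\mu_{\mathrm{norm}}}\sum_{ijsr}\Big[\big(A_{ijs} -
\gamma\,\tfrac{k_{is}k_{js}}{2m_s}\big)\delta_{sr} +
\omega\,\delta_{ij}C_{sr}\Big]\,\delta(c_{is}, c_{jr}),$$
with neighbour-layer coupling $C_{sr} = 1$ iff $|s - r| = 1$, by a
Louvain-type procedure over node-layer pairs: seeded greedy move phases
(every accepted move is validated against full re-evaluation in the tests),
graph aggregation, and iterated refinement of the finest-level labels until
$Q$ stops improving. The normalization prefactor is written
$\mu_{\mathrm{norm}}$ throughout the code because the symbol would otherwise
collide with the kinetic timescale. Community identity across layers is
read directly off the shared labels — the interlayer coupling makes labels
persistent, so no post-hoc matching step exists. On every toy small enough
to enumerate, the optimizer attains the exhaustive-search optimum; defaults
$\gamma = 10$, $\omega = 1$ follow the community-detection settings used for
cluster-stability analyses, and `parameter_sweep()` assesses robustness by
stability across adjacent grid points (a plain grid sweep deliberately
replaces convex-hull parameter selection, which is out of scope).

## Mixing statistics

A bead pair "interacts" while its distance is below $d^\* = 100$ nm
(frame resolution, 0.1 s); at the community level two beads "communicate"
while they share a label (layer resolution, 1 s). One boolean interval
engine underlies both: maximal true-runs are interactions, the gaps between
consecutive runs are waits, and gaps censored by the series ends are
excluded from waiting-time averages (pairs that never interact contribute
no waits, not infinite ones). The four statistics are the fraction of pairs
with at least one interaction, the mean number of simultaneous partners per
bead, the pooled mean waiting time, and the mean run duration. Waiting
times pool all completed gaps across pairs rather than averaging per-pair
means; the interval tibble from `pair_interaction_intervals()` lets a user
do either. `cluster_lifetimes()` and `persistence_probability()` summarize
each community's lifespan (first to last populated layer), time-averaged
size, and the probability that a member bead keeps its label in the next
window.

## The microscope simulator and image pipeline

`render_microscope_stack()` deposits a unit-amplitude 3D Gaussian PSF
(defaults 125 nm lateral / 300 nm axial — widefield-like; the source does
not print PSF widths) for every nucleolar bead on a 55 × 55-pixel,
7-plane voxel grid (64.8-nm pixels, 200-nm z-steps) centred on the
nucleolar centroid, then collapses it to a maximum intensity projection.
`synth_image_fixture()` generates the synthetic stand-in for experimental
nucleolar z-stacks (spots in a disk plus Gaussian read noise) with its
ground truth attached.

The analysis chain mirrors the classic MATLAB pipeline: a 256-bin Otsu
threshold (`otsu_threshold()`, tested against an exhaustive between-class
variance scan), min-max normalization, suprathreshold pixel count times
$0.0648^2$ µm² for the area, the *population* standard deviation of
re-normalized suprathreshold pixels (one convention had to be picked; it is
recorded here), and `count_clusters()`: blind Richardson–Lucy deconvolution
initialized with a 5 × 5 Gaussian kernel (10 iterations — the source count
is unstated), two rounds of background subtraction with the Otsu threshold
recomputed in the second round (switchable via `recompute_threshold`),
8-connected regional-maxima detection with plateaus counted once through
connected components.

## What the synthetic generator does and does not emulate

The scaled preset is a desk-scale surrogate: one wall-tethered nucleolar
chain of 100–361 beads for a few hundred seconds, rather than the full 2803
-bead genome for 20 minutes. It reproduces: the stochastic two-state
crosslink kinetics exactly as specified; rigid, well-separated ~10-20-bead
clusters at $\mu = 0.09$ whose community labels persist for hundreds of
seconds; the ~50-nm intra-cluster distance mode with its empty valley; the
loss of that mode under time averaging at $\mu = 0.19$ and under population
averaging at every $\mu$; and a waiting-time minimum in the flexible
regime.

It does **not** reproduce everything the full-genome system shows, and
passing tests should be read accordingly:

* There is no surrounding genome. The 2400 non-nucleolar beads of the full
  system crowd and entangle the rDNA, freezing rigid clusters in place and
  compacting the nucleolus into a crescent. In the isolated chain, clusters
  diffuse and occasionally merge, so the interaction *fraction* does not
  peak as sharply in the flexible regime, and whole-nucleolus compaction
  (the image-area trend) is weak.
* Long-lived crosslinks at $\mu \gtrsim 1$ hold bonded pairs inside
  $d^\* = 100$ nm for seconds at a time; pooled interaction durations
  therefore do not decrease monotonically with $\mu$ in the surrogate even
  though large-scale clustering does dissolve.
* Hydrodynamics is bare Stokes drag; no loop extrusion, sister chromatids
  or cell-cycle stages other than G1.

## Numerical and design choices

* All randomness flows through one integer seed per simulation
  (initialization uses R's RNG, the compiled integrator a xoshiro256++
  stream seeded from the same integer); identical seeds reproduce
  trajectories bit for bit.
* Greedy ascending-distance matching breaks ties deterministically by bead
  index.
* The Verlet neighbour list uses a 30-nm skin and is rebuilt when any bead
  has moved half the skin.
* Degenerate inputs error early: constant images cannot be thresholded or
  normalized, empty masks yield zero area with a warning, chains whose
  tether sites are farther apart than their contour length are rejected at
  initialization.
* Problem sizes used in the shipped checks: rigid-regime runs use 200
  beads for 400 s (100 s burn-in, 300 analyzed 1-s windows, three seeds);
  the $\mu$-sweep uses 100 beads for 120 s with five seeds; population
  averages use ten replicates of 60 s. These sizes were chosen as the
  smallest at which the cluster statistics stabilize.

## Known limitations

The mechanical constants are a calibration, not measurements; the package
exposes every one of them in `sim_params()` so other regimes can be
explored. The full-genome preset (`yeast_genome_topology()`, 2803 beads on
32 tethered arms with the 361-bead rDNA block) is supported by the data
model and initializer but is not exercised at production scale by the
shipped checks. Community detection at $\gamma = 10$, $\omega = 1$ on an
isolated chain yields many singleton labels for beads between clusters;
cluster-level summaries therefore treat communities of at least two beads
as clusters.
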