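#' Imaging parameters for the forward microscope simulator
#'
#' Geometry of the widefield acquisition that the simulator emulates:
#' 64.8 nm pixels, 7 z-planes at 200 nm steps, 55 x 55 pixel crops and a 3D
#' Gaussian point spread function. PSF widths default to widefield-like
#' values (125 nm lateral, 300 nm axial).
#'
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param z_planes number of z planes.
#' @param z_step_nm axial plane spacing, nm.
#' @param crop image side length in pixels (odd, centred).
#' @param psf_sigma_lateral,psf_sigma_axial Gaussian PSF widths, nm.
#' @param timepoints number of snapshots in a timelapse.
#' @return an object of class `nmx_imaging_params`.
#' @export
imaging_params <- function(pixel_size_um = 0.0648, z_planes = 7,
                           z_step_nm = 200, crop = 55,
                           psf_sigma_lateral = 125, psf_sigma_axial = 300,
                           timepoints = 22) {
  stopifnot(pixel_size_um > 0, z_planes >= 1, z_step_nm > 0, crop >= 3,
            crop %% 2 == 1, psf_sigma_lateral > 0, psf_sigma_axial > 0,
            timepoints >= 1)
  structure(list(pixel_size_um = pixel_size_um, z_planes = z_planes,
                 z_step_nm = z_step_nm, crop = crop,
                 psf_sigma_lateral = psf_sigma_lateral,
                 psf_sigma_axial = psf_sigma_axial,
                 timepoints = timepoints),
            class = "nmx_imaging_params")
}

new_image_stack <- function(stack, params, provenance) {
  structure(list(stack = stack, mip = apply(stack, c(1, 2), max),
                 params = params, provenance = provenance),
            class = "nmx_image_stack")
}

#' @export
print.nmx_image_stack <- function(x, ...) {
  d <- dim(x$stack)
  cat("<nmx_image_stack>", d[1], "x", d[2], "pixels x", d[3], "planes (",
      x$provenance, ")\n")
  invisible(x)
}

#' Render a simulated microscope stack from a trajectory snapshot
#'
#' Every nucleolar bead deposits a unit-amplitude 3D Gaussian point spread
#' function sampled on the voxel grid; the stack is then collapsed into a
#' maximum intensity projection. The field of view is centred on the
#' centroid of the nucleolar beads (or an explicit `center`). Deterministic.
#'
#' @param trajectory an `nmx_trajectory`.
#' @param t snapshot time on the saved grid (or give `frame`).
#' @param frame saved frame index.
#' @param params an [imaging_params()] object.
#' @param center optional length-3 centre of the field of view, nm.
#' @return an `nmx_image_stack` with elements `stack` (crop x crop x
#'   z_planes array) and `mip` (crop x crop matrix).
#' @export
render_microscope_stack <- function(trajectory, t = NULL, frame = NULL,
                                    params = imaging_params(),
                                    center = NULL) {
  if (is.null(frame)) frame <- frame_at_time(trajectory, t)
  idx <- which(trajectory$topology$nucleolar_mask)
  pos <- frame_positions(trajectory, frame)[idx, , drop = FALSE]
  if (is.null(center)) center <- colMeans(pos)
  n_px <- params$crop
  px <- params$pixel_size_um * 1000
  half <- (n_px - 1) / 2
  xs <- (seq_len(n_px) - 1 - half) * px + center[1]
  ys <- (seq_len(n_px) - 1 - half) * px + center[2]
  zh <- (params$z_planes - 1) / 2
  zs <- (seq_len(params$z_planes) - 1 - zh) * params$z_step_nm + center[3]
  sl2 <- 2 * params$psf_sigma_lateral^2
  sa2 <- 2 * params$psf_sigma_axial^2
  stack <- array(0, c(n_px, n_px, params$z_planes))
  for (b in seq_len(nrow(pos))) {
    gx <- exp(-(xs - pos[b, 1])^2 / sl2)
    gy <- exp(-(ys - pos[b, 2])^2 / sl2)
    gz <- exp(-(zs - pos[b, 3])^2 / sa2)
    if (max(gx) * max(gy) * max(gz) < 1e-8) next  # far outside the field
    lat <- outer(gx, gy)
    for (p in seq_len(params$z_planes))
      stack[, , p] <- stack[, , p] + lat * gz[p]
  }
  new_image_stack(stack, params, "simulated")
}

#' Otsu threshold of an image
#'
#' The threshold maximizing the between-class intensity variance over a
#' 256-bin histogram; the mask marks pixels at or above the threshold.
#'
#' @param image numeric matrix or array.
#' @param n_bins histogram resolution.
#' @return list with `threshold` (intensity value) and `mask` (logical,
#'   same shape as `image`).
#' @export
#' @examples
#' img <- matrix(c(rep(0, 8), rep(1, 8)), 4)
#' otsu_threshold(img)$threshold
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: no separable intensity classes")
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(v, breaks, all.inside = TRUE),
                               1L), n_bins), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[n_bins]; total_m <- m[n_bins]
  # split after bin k: class 0 = bins 1..k, class 1 = rest
  k <- seq_len(n_bins - 1)
  w0 <- w[k]; w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  mu0 <- m[k] / w0; mu1 <- (total_m - m[k]) / w1
  bcv[valid] <- (w0 * w1)[valid] * (mu0 - mu1)[valid]^2
  kbest <- which.max(bcv)
  thr <- breaks[kbest + 1]
  list(threshold = thr, mask = image >= thr)
}

#' Min-max intensity normalization
#'
#' Subtracts the minimum and divides by the maximum of the remaining values
#' so the considered region spans exactly `[0, 1]`; idempotent. When a mask
#' is given, only pixels inside the mask are considered (and returned);
#' pixels outside are set to zero.
#'
#' @param image numeric matrix or array.
#' @param mask optional logical mask of the considered region.
#' @return normalized object of the same shape.
#' @export
normalize_intensities <- function(image, mask = NULL) {
  if (is.null(mask)) {
    lo <- min(image); hi <- max(image)
    if (hi <= lo) stop("constant region cannot be normalized")
    (image - lo) / (hi - lo)
  } else {
    v <- image[mask]
    lo <- min(v); hi <- max(v)
    if (hi <= lo) stop("constant region cannot be normalized")
    out <- image
    out[mask] <- (v - lo) / (hi - lo)
    out[!mask] <- 0
    out
  }
}

#' Nucleolar signal area
#'
#' Number of suprathreshold pixels converted to square micrometres with the
#' pixel area (0.0648^2 um^2 by default).
#'
#' @param mip maximum intensity projection (matrix).
#' @param threshold intensity threshold (e.g. from [otsu_threshold()]).
#' @param pixel_size_um lateral pixel size.
#' @return area in um^2.
#' @export
#' @examples
#' nucleolar_area(matrix(1, 10, 10), threshold = 0.5)  # 100 px
nucleolar_area <- function(mip, threshold, pixel_size_um = 0.0648) {
  n <- sum(mip >= threshold)
  if (n == 0) warning("empty mask: area is 0")
  n * pixel_size_um^2
}

#' Standard deviation of the normalized suprathreshold signal
#'
#' Pixels below the threshold are discarded, the survivors are re-normalized
#' to `[0, 1]`, and the population standard deviation of the normalized
#' values is returned.
#'
#' @inheritParams nucleolar_area
#' @return population SD (scalar).
#' @export
normalized_signal_std <- function(mip, threshold) {
  v <- mip[mip >= threshold]
  if (length(v) < 2) stop("fewer than 2 suprathreshold pixels")
  v <- normalize_intensities(v)
  sqrt(mean((v - mean(v))^2))
}

# 3x3 grayscale max filter (8-connectivity) via shifted copies
max_filter3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  out <- matrix(-Inf, H, W)
  for (dx in 0:2)
    for (dy in 0:2)
      out <- pmax(out, pad[(1 + dx):(H + dx), (1 + dy):(W + dy)])
  out
}

#' Count fluorescent clusters in a maximum intensity projection
#'
#' The spot-counting pipeline applied to normalized projections: blind
#' Richardson-Lucy deconvolution initialized with a 5 x 5 Gaussian kernel
#' (fixed iteration count), two rounds of background subtraction (Otsu
#' threshold, sub-threshold pixels zeroed; the threshold is recomputed in
#' the second round by default), then 8-connected regional-maxima detection
#' and a connected-component count of the maxima map.
#'
#' @param mip matrix; normalized to `[0, 1]` internally if needed.
#' @param iterations Richardson-Lucy iterations.
#' @param kernel_sigma sigma (pixels) of the initial 5 x 5 Gaussian kernel.
#' @param recompute_threshold recompute the Otsu threshold in the second
#'   background-subtraction round (default) or reuse the first.
#' @return list with `count` (integer) and `peaks` (tibble of `row`, `col`
#'   pixel coordinates, one per cluster).
#' @export
count_clusters <- function(mip, iterations = 10, kernel_sigma = 1,
                           recompute_threshold = TRUE) {
  empty <- list(count = 0L,
                peaks = tibble::tibble(row = integer(0), col = integer(0)))
  if (max(mip) <= min(mip)) return(empty)
  img <- normalize_intensities(mip)
  k <- gaussian_kernel(5, kernel_sigma)
  img <- cpp_rl_blind(img, k, as.integer(iterations))$image
  thr1 <- otsu_threshold(img)$threshold
  img[img < thr1] <- 0
  if (max(img) <= min(img)) return(empty)
  thr2 <- if (recompute_threshold) otsu_threshold(img)$threshold else thr1
  img[img < thr2] <- 0
  if (max(img) <= 0) return(empty)
  cand <- img == max_filter3(img) & img > 0
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n == 0) return(empty)
  peaks <- tibble::tibble(
    row = as.integer(round(tapply(row(lab)[lab > 0], lab[lab > 0], mean))),
    col = as.integer(round(tapply(col(lab)[lab > 0], lab[lab > 0], mean))))
  list(count = as.integer(n), peaks = peaks)
}

gaussian_kernel <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Synthetic image-stack fixture
#'
#' A synthetic stand-in for experimental nucleolar (CDC14-GFP-like) z-stacks:
#' a 7-plane 55 x 55 stack with `n_spots` Gaussian spots placed inside a
#' disk around the image centre (the bright nucleolar blob) plus Gaussian
#' read noise, clipped at zero. The ground-truth spot list is attached.
#'
#' @param n_spots number of spots (>= 0).
#' @param spot_sigma_px lateral spot width, pixels.
#' @param noise_sd Gaussian read-noise SD (intensity units; spot amplitude
#'   is 1).
#' @param seed integer seed.
#' @param params an [imaging_params()] object.
#' @param disk_radius_px placement disk radius.
#' @param min_separation_px minimal centre-to-centre spot distance.
#' @param path optional file path: write the stack as a float TIFF.
#' @return an `nmx_image_stack` with a `truth` tibble (`row`, `col`,
#'   `plane`) attached.
#' @export
synth_image_fixture <- function(n_spots, spot_sigma_px = 1.8,
                                noise_sd = 0.01, seed = 1L,
                                params = imaging_params(),
                                disk_radius_px = 15,
                                min_separation_px = 0, path = NULL) {
  stopifnot(n_spots >= 0)
  n_px <- params$crop
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ctr <- (n_px + 1) / 2
  pts <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(pts) < n_spots && guard < 10000) {
    guard <- guard + 1
    r <- disk_radius_px * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    p <- c(ctr + r * cos(a), ctr + r * sin(a))
    if (nrow(pts) == 0 ||
        min(sqrt(rowSums((pts - matrix(p, nrow(pts), 2,
                                       byrow = TRUE))^2))) >=
          min_separation_px)
      pts <- rbind(pts, p)
  }
  planes <- if (n_spots > 0)
    sample(seq_len(params$z_planes), nrow(pts), replace = TRUE,
           prob = stats::dnorm(seq_len(params$z_planes),
                               (params$z_planes + 1) / 2, 1.2))
    else integer(0)
  stack <- array(0, c(n_px, n_px, params$z_planes))
  if (nrow(pts) > 0) {
    xs <- seq_len(n_px)
    for (b in seq_len(nrow(pts))) {
      gx <- exp(-(xs - pts[b, 1])^2 / (2 * spot_sigma_px^2))
      gy <- exp(-(xs - pts[b, 2])^2 / (2 * spot_sigma_px^2))
      gz <- exp(-(seq_len(params$z_planes) - planes[b])^2 / (2 * 1.0^2))
      lat <- outer(gx, gy)
      for (p in seq_len(params$z_planes))
        stack[, , p] <- stack[, , p] + lat * gz[p]
    }
  }
  if (noise_sd > 0)
    stack <- pmax(stack + array(stats::rnorm(length(stack), 0, noise_sd),
                                dim(stack)), 0)
  out <- new_image_stack(stack, params, "fixture")
  out$truth <- tibble::tibble(row = pts[, 1], col = pts[, 2],
                              plane = planes)
  if (!is.null(path)) write_stack_tiff(out, path)
  out
}

#' Write / read an image stack as multi-page float TIFF
#' @param stack an `nmx_image_stack` (or plain array for writing).
#' @param path TIFF file path.
#' @return `read_stack_tiff` returns an `nmx_image_stack` with provenance
#'   `"imported"`.
#' @export
write_stack_tiff <- function(stack, path) {
  a <- if (inherits(stack, "nmx_image_stack")) stack$stack else stack
  pages <- lapply(seq_len(dim(a)[3]), function(p) a[, , p])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param params an [imaging_params()] describing the acquisition.
#' @export
read_stack_tiff <- function(path, params = imaging_params()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) a[, , p] <- pages[[p]]
  new_image_stack(a, params, "imported")
}

#' Full image-analysis report for one stack
#'
#' Applies the analysis pipeline to a stack or TIFF file: maximum intensity
#' projection, Otsu threshold, suprathreshold area, raw and normalized
#' signal SD, and the deconvolution-based cluster count.
#'
#' @param x an `nmx_image_stack`, a matrix (already a MIP), or a TIFF path.
#' @param params an [imaging_params()].
#' @return one-row tibble: `area_um2`, `signal_sd_raw`,
#'   `signal_sd_normalized`, `n_clusters`, `threshold`.
#' @export
analyze_image_stack <- function(x, params = imaging_params()) {
  if (is.character(x)) x <- read_stack_tiff(x, params)
  mip <- if (inherits(x, "nmx_image_stack")) x$mip else x
  if (inherits(x, "nmx_image_stack")) params <- x$params
  if (max(mip) <= min(mip))
    return(tibble::tibble(area_um2 = 0, signal_sd_raw = 0,
                          signal_sd_normalized = NA_real_, n_clusters = 0L,
                          threshold = NA_real_))
  norm <- normalize_intensities(mip)
  thr <- otsu_threshold(norm)$threshold
  tibble::tibble(
    area_um2 = nucleolar_area(norm, thr, params$pixel_size_um),
    signal_sd_raw = stats::sd(as.vector(mip)),
    signal_sd_normalized = normalized_signal_std(norm, thr),
    n_clusters = count_clusters(norm)$count,
    threshold = thr)
}

#' Timelapse image statistics for a trajectory
#'
#' Renders `timepoints` evenly spaced snapshots of a trajectory through the
#' microscope simulator and analyses each, the simulated analogue of a
#' timelapse acquisition.
#'
#' @param trajectory an `nmx_trajectory`.
#' @param params an [imaging_params()].
#' @param burn_in seconds discarded at the start.
#' @return tibble with one row per timepoint (columns as
#'   [analyze_image_stack()] plus `t`).
#' @export
timelapse_image_stats <- function(trajectory, params = imaging_params(),
                                  burn_in = 0) {
  times <- trajectory$times[trajectory$times >= burn_in]
  pick <- times[unique(round(seq(1, length(times),
                                 length.out = params$timepoints)))]
  rows <- lapply(pick, function(t) {
    st <- render_microscope_stack(trajectory, t = t, params = params)
    r <- analyze_image_stack(st)
    r$t <- t
    r
  })
  dplyr::bind_rows(rows)
}
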