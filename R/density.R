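#' Large-vessel mask from an SVP en-face angiogram
#'
#' Smooths the en-face decorrelation image with a truncated Gaussian
#' window (default 20 x 20 px, sigma = 5 px), thresholds at an SSADA
#' decorrelation value of 0.12, and keeps only 8-connected components
#' larger than `min_size` pixels (default 50: a 50-pixel component is
#' removed, a 51-pixel one retained). Masked columns are excluded from
#' capillary-density measurement at all depths.
#'
#' @param svp_enface en-face decorrelation matrix (SVP slab projection).
#' @param window smoothing window side length in px.
#' @param sigma Gaussian sigma in px.
#' @param threshold decorrelation threshold.
#' @param min_size components with `size <= min_size` are removed.
#' @return object of class `large_vessel_mask`: logical matrix `mask`
#'   plus the parameters.
#' @export
build_large_vessel_mask <- function(svp_enface, window = 20, sigma = 5,
                                    threshold = 0.12, min_size = 50) {
  stopifnot(is.matrix(svp_enface))
  if (length(svp_enface) == 0 || max(svp_enface) == 0) {
    mask <- matrix(FALSE, nrow(svp_enface), ncol(svp_enface))
  } else {
    k <- gaussian_kernel(window, sigma)
    sm <- EBImage::filter2(svp_enface, k, boundary = 0)
    bin <- sm > threshold
    lab <- label_components8(bin)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes > min_size)
      mask <- matrix(lab %in% keep, nrow(bin), ncol(bin))
    } else {
      mask <- bin
    }
  }
  structure(list(mask = mask,
                 params = list(window = window, sigma = sigma,
                               threshold = threshold, min_size = min_size)),
            class = "large_vessel_mask")
}

#' @export
print.large_vessel_mask <- function(x, ...) {
  cat(sprintf("<large_vessel_mask> %d / %d px masked (window %d, sigma %g, thr %.2f, min size %d)\n",
              sum(x$mask), length(x$mask), x$params$window, x$params$sigma,
              x$params$threshold, x$params$min_size))
  invisible(x)
}

window_columns <- function(volume, center, window) {
  xs <- x_coords(volume); ys <- y_coords(volume)
  ix <- which(abs(xs - center[1]) <= window[1] / 2 + 1e-9)
  iy <- which(abs(ys - center[2]) <= window[2] / 2 + 1e-9)
  if (!length(ix) || !length(iy) ||
      center[1] - window[1] / 2 < min(xs) - 1e-9 ||
      center[1] + window[1] / 2 > max(xs) + 1e-9 ||
      center[2] - window[2] / 2 < min(ys) - 1e-9 ||
      center[2] + window[2] / 2 > max(ys) + 1e-9)
    stop("sampling window falls outside the grid")
  list(ix = ix, iy = iy)
}

#' Depth-resolved capillary density profile
#'
#' Counts flow pixels at each depth plane inside a transverse sampling
#' window (default 0.1 x 0.8 mm) and divides by the number of pixels,
#' after removing columns under the large-vessel mask. Planes with no
#' contributing pixels are flagged absent (NA), not zero. A flow pixel is
#' one with decorrelation above `flow_threshold` (0 after projection
#' resolution, which already applied the noise cut).
#'
#' @param volume a PR-resolved (and, for cross-subject work, flattened and
#'   depth-normalized) [octa_volume()].
#' @param sample_center `c(x_mm, y_mm)` window center.
#' @param region_label one of `"peripapillary"`, `"parafoveal"`,
#'   `"perifoveal"`, `"peripheral"` (free text allowed).
#' @param mask optional [build_large_vessel_mask()] output.
#' @param window window dims `c(x_mm, y_mm)`.
#' @param flow_threshold binarization cut for non-PR inputs.
#' @return object of class `depth_density_profile`: data.frame with
#'   columns `z`, `density`, `n`, plus attributes.
#' @export
depth_density_profile <- function(volume, sample_center,
                                  region_label = "unspecified",
                                  mask = NULL, window = c(0.1, 0.8),
                                  flow_threshold = 0) {
  w <- window_columns(volume, sample_center, window)
  use <- matrix(TRUE, length(w$ix), length(w$iy))
  if (!is.null(mask)) use <- !mask$mask[w$ix, w$iy, drop = FALSE]
  n_use <- sum(use)
  d <- dim(volume)
  dens <- rep(NA_real_, d[3]); n <- integer(d[3])
  for (z in seq_len(d[3])) {
    sl <- volume$decorrelation[w$ix, w$iy, z, drop = FALSE]
    dim(sl) <- dim(use)
    if (n_use > 0) {
      dens[z] <- sum(sl[use] > flow_threshold) / n_use
      n[z] <- n_use
    }
  }
  out <- data.frame(z = seq_len(d[3]), density = dens, n = n)
  structure(out, class = c("depth_density_profile", "data.frame"),
            region = region_label, center = sample_center, window = window)
}

#' Cross-sectional super-voxel density map
#'
#' Tiles a cross-sectional slab along the maculopapillary axis with
#' super-voxels (default 0.1 x 0.8 x 0.01 mm in x, y, z) and reports the
#' fraction of the super-voxel occupied by flow voxels.
#'
#' @param volume PR-resolved [octa_volume()].
#' @param y_center swath center in mm (default the fovea's y).
#' @param supervoxel dims `c(x_mm, y_mm, z_mm)`.
#' @param flow_threshold binarization cut.
#' @return object of class `cross_section_density_map`: matrix (x bins by
#'   z bins) with bin centres in attributes.
#' @export
cross_section_density_map <- function(volume, y_center = NULL,
                                      supervoxel = c(0.1, 0.8, 0.01),
                                      flow_threshold = 0) {
  if (is.null(y_center))
    y_center <- tryCatch(landmark(volume, "fovea")[2], error = function(e) 0)
  xs <- x_coords(volume); ys <- y_coords(volume)
  iy <- which(abs(ys - y_center) <= supervoxel[2] / 2 + 1e-9)
  if (!length(iy)) stop("swath outside the grid")
  d <- dim(volume)
  dz_mm <- volume$spacing[3] / 1e3
  xbin <- floor((xs - min(xs)) / supervoxel[1]) + 1L
  zbin <- floor(((seq_len(d[3]) - 1) * dz_mm) / supervoxel[3]) + 1L
  nxb <- max(xbin); nzb <- max(zbin)
  acc <- matrix(0, nxb, nzb); cnt <- matrix(0, nxb, nzb)
  for (z in seq_len(d[3])) {
    sl <- volume$decorrelation[, iy, z, drop = FALSE] > flow_threshold
    rowflow <- rowSums(matrix(sl, d[1], length(iy)))
    acc[, zbin[z]] <- acc[, zbin[z]] +
      as.vector(tapply(rowflow, xbin, sum))
    cnt[, zbin[z]] <- cnt[, zbin[z]] +
      as.vector(tapply(rep(length(iy), d[1]), xbin, sum))
  }
  m <- acc / pmax(cnt, 1)
  xc <- as.vector(tapply(xs, xbin, mean))
  zc <- as.vector(tapply((seq_len(d[3]) - 0.5) * dz_mm, zbin, mean))
  structure(m, class = "cross_section_density_map", x_mm = xc, z_mm = zc,
            supervoxel = supervoxel)
}

#' Transverse per-plexus density profiles
#'
#' For each plexus slab, takes the en-face maximum flow projection over
#' the slab's full thickness and reports the suprathreshold pixel
#' fraction inside a swath window (default 0.7 mm wide in y, stepped
#' every 0.05 mm in x) as a function of distance from the disc edge along
#' the maculopapillary axis. Large vessels are included (no mask), so
#' values run higher than the single-plane capillary densities.
#'
#' @param volume PR-resolved [octa_volume()].
#' @param layers [layer_model()] used to resolve the slabs.
#' @param specs list of [slab_spec()]; default the four plexuses.
#' @param step,swath sampling step and swath width in mm.
#' @param flow_threshold binarization cut.
#' @return data.frame with columns `plexus`, `ecc_mm` (distance from the
#'   disc edge), `x_mm`, `density`.
#' @export
transverse_density_profile <- function(volume, layers, specs = NULL,
                                       step = 0.05, swath = 0.7,
                                       flow_threshold = 0) {
  stopifnot(step > 0, swath > 0)
  if (is.null(specs)) specs <- standard_plexus_specs()[c("RPCP", "SVP",
                                                         "ICP", "DCP")]
  edge <- tryCatch(landmark(volume, "disc_edge"),
                   error = function(e) c(min(x_coords(volume)), 0))
  xs <- x_coords(volume); ys <- y_coords(volume)
  iy <- which(abs(ys - edge[2]) <= swath / 2 + 1e-9)
  if (!length(iy)) stop("swath outside the grid")
  xq <- seq(max(edge[1], min(xs)), max(xs), by = step)
  out <- list()
  for (spec in specs) {
    band <- resolve_slab(spec, layers)
    ef <- project_flow_max(volume, band)
    img <- ef$image[, iy, drop = FALSE]
    dens <- vapply(xq, function(x0) {
      ix <- which(abs(xs - x0) <= step / 2 + 1e-9)
      if (!length(ix)) return(NA_real_)
      mean(img[ix, , drop = FALSE] > flow_threshold)
    }, numeric(1))
    out[[spec$name]] <- data.frame(plexus = spec$name, ecc_mm = xq - edge[1],
                                   x_mm = xq, density = dens)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("transverse_profile", "data.frame")
  attr(res, "step") <- step; attr(res, "swath") <- swath
  res
}

#' Coefficient of variation of repeated density measurements
#'
#' Sample SD (n - 1 denominator) over the mean, as a percentage — the
#' within-visit repeatability metric.
#'
#' @param densities numeric vector of >= 2 repeated measurements with a
#'   positive mean.
#' @return CoV in percent.
#' @export
repeatability_cov <- function(densities) {
  densities <- as.numeric(densities)
  if (length(densities) < 2) stop("need at least 2 repeated measurements")
  m <- mean(densities)
  if (m <= 0) stop("mean of repeated measurements must be positive")
  100 * stats::sd(densities) / m
}
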