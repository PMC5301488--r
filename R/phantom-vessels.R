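plexus_codes <- c(none = 0L, RPCP = 1L, SVP = 2L, ICP = 3L, DCP = 4L,
                  interconnect = 5L)

# capillary mesh as the ridge set of a Voronoi tessellation of blue-noise
# seed points: pixels nearly equidistant from their two nearest seeds form
# the lobule walls. The ridge coordinate (d2 - d1, px) is thresholded at
# its empirical per-bin quantile so the achieved area fraction matches the
# (possibly spatially varying) target fraction essentially exactly.
mesh_mask <- function(nx, ny, cell_px, frac_map) {
  if (cell_px < 2)
    stop("target area fraction unreachable at the given capillary width: ",
         "implied lobule size below 2 pixels")
  gx <- seq(0.5, nx + cell_px, by = cell_px)
  gy <- seq(0.5, ny + cell_px, by = cell_px)
  sx <- rep(gx, times = length(gy)) + stats::runif(length(gx) * length(gy),
                                                   -0.45, 0.45) * cell_px
  sy <- rep(gy, each = length(gx)) + stats::runif(length(gx) * length(gy),
                                                  -0.45, 0.45) * cell_px
  px <- rep(seq_len(nx), times = ny)
  py <- rep(seq_len(ny), each = nx)
  gap <- nearest_two_gap_grid(px, py, sx, sy, length(gx), length(gy),
                              cell_px)
  frac <- round(as.numeric(frac_map), 2)
  mask <- logical(nx * ny)
  for (f in unique(frac)) {
    sel <- which(frac == f)
    if (f <= 0) next
    mask[sel] <- gap[sel] <= stats::quantile(gap[sel], f, names = FALSE)
  }
  matrix(mask, nx, ny)
}

# radial peripapillary capillaries: gently arcuate streamlines fanning out
# from the optic disc edge. Rays are accreted until the mean area fraction
# over the in-grid peripapillary annulus reaches the target, so density
# decays ~1/r with distance from the disc by pure geometry.
ray_mask <- function(config, target) {
  nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
  dxy <- config$voxel_spacing[1] / 1000
  x <- config_x_mm(config); y <- config_y_mm(config)
  r_disc <- sqrt(outer((x - config$disc_center[1])^2,
                       (y - config$disc_center[2])^2, "+"))
  r0 <- config$disc_radius
  r1 <- config$plexus_params$rpcp$extent_mm
  domain <- r_disc >= r0 & r_disc <= r1
  n_dom <- sum(domain)
  mask <- matrix(FALSE, nx, ny)
  if (n_dom < 50) return(list(mask = mask, domain = domain))
  golden <- pi * (3 - sqrt(5))
  n_max <- 1440L
  theta0 <- (seq_len(n_max) - 1) * golden
  curv <- stats::rnorm(n_max, 0, 0.25)          # rad per mm of radial travel
  tt <- seq(r0, r1, by = dxy / 2)
  got <- 0L
  for (k in seq_len(n_max)) {
    th <- theta0[k] + curv[k] * (tt - r0)
    cxm <- config$disc_center[1] + tt * cos(th)
    cym <- config$disc_center[2] + tt * sin(th)
    ci <- round((cxm - config$origin_mm[1]) / dxy) + 1
    cj <- round((cym - config$origin_mm[2]) / dxy) + 1
    ok <- ci >= 1 & ci <= nx & cj >= 1 & cj <= ny
    if (any(ok)) mask[cbind(ci[ok], cj[ok])] <- TRUE
    got <- got + 1L
    if (k %% 8L == 0L && sum(mask & domain) / n_dom >= target) break
  }
  achieved <- sum(mask & domain) / n_dom
  if (abs(achieved / target - 1) > 0.10)
    stop(sprintf(paste0("target area fraction unreachable for RPCP: ",
                        "achieved %.3f vs target %.3f"), achieved, target))
  list(mask = mask, domain = domain)
}

# branching large-vessel (arcade-like) trees emanating from the disc edge
# toward the fovea; returns an en-face mask of thick vessels.
tree_mask <- function(config) {
  nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
  dxy <- config$voxel_spacing[1] / 1000
  mask <- matrix(FALSE, nx, ny)
  n_trees <- config$plexus_params$svp$n_trees
  if (n_trees < 1L) return(mask)
  x_mm <- config_x_mm(config); y_mm <- config_y_mm(config)
  paint <- function(ci, cj, r_px) {
    o <- ceiling(r_px)
    for (di in -o:o) for (dj in -o:o) {
      if (di * di + dj * dj > r_px * r_px) next
      ii <- ci + di; jj <- cj + dj
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny) mask[ii, jj] <<- TRUE
    }
  }
  trace_vessel <- function(x0, y0, heading, w_mm, depth) {
    step <- dxy
    xx <- x0; yy <- y0; h <- heading; w <- w_mm
    travelled <- 0
    while (TRUE) {
      r_fov <- sqrt((xx - config$fovea_center[1])^2 +
                      (yy - config$fovea_center[2])^2)
      if (r_fov < config$faz_radius + 0.1) break
      if (xx > max(x_mm) + 0.2 || xx < min(x_mm) - 0.2) break
      if (w < 0.02) break
      ci <- round((xx - config$origin_mm[1]) / dxy) + 1
      cj <- round((yy - config$origin_mm[2]) / dxy) + 1
      if (ci >= -3 && ci <= nx + 3 && cj >= -3 && cj <= ny + 3)
        paint(ci, cj, (w / 2) / dxy)
      h <- h + stats::rnorm(1, 0, 0.06) +
        0.02 * sin(travelled * 4)                    # gentle meander
      xx <- xx + step * cos(h); yy <- yy + step * sin(h)
      travelled <- travelled + step
      w <- w * (1 - 0.012 * step / dxy * dxy / 0.03) # slow taper
      if (depth < 2 && travelled > 0.5 && stats::runif(1) < 0.04) {
        trace_vessel(xx, yy, h + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.8),
                     w * 0.6, depth + 1)
      }
    }
  }
  # arcades leave the disc obliquely (superior/inferior), keeping the
  # maculopapillary axis itself clear of the largest trunks
  x_start <- config$disc_center[1] + config$disc_radius
  for (k in seq_len(n_trees)) {
    sgn <- if (k %% 2L == 0L) 1 else -1
    y0 <- sgn * stats::runif(1, 0.04, 0.1)
    h0 <- sgn * stats::runif(1, 1.4, 1.75)
    trace_vessel(x_start, y0, h0, 0.1, 0)
  }
  mask
}

#' Generate the phantom vasculature and ground truth
#'
#' Builds the four plexuses as single-voxel-thick capillary sheets hosted
#' in their anatomic bands, plus large-vessel trees, vertical
#' interconnecting segments, a foveal avascular zone with its perifoveal
#' capillary ring, and (optionally) a homogeneous choriocapillaris slab:
#'
#' * RPCP: radially oriented arcuate capillaries fanning from the disc
#'   edge, at mid-NFL depth; density falls off with distance from the disc.
#' * SVP: an isotropic capillary mesh (Voronoi-ridge lobules) in the GCL
#'   band, with density decaying from the macula to the periphery, plus
#'   branching large-vessel trees around the same depth.
#' * ICP / DCP: lobular meshes whose centerline depths sit at the inner
#'   and outer INL borders at the fovea and approach mid-INL linearly with
#'   eccentricity, coalescing at `merge_eccentricity`. Voxelized sheets
#'   are clamped to stay inside their half-open host bands, so fully
#'   merged sheets occupy adjacent planes while the continuous centerline
#'   separation (in `$sheets`) is exactly zero.
#'
#' Achieved per-plexus capillary area fractions are calibrated to the
#' configured targets by empirical-quantile thresholding of the mesh ridge
#' coordinate; a target that cannot be met (relative error > 10%) raises
#' an error rather than being clipped silently.
#'
#' @param config a [phantom_config()].
#' @param layers the matching [generate_layer_model()] output.
#' @return an object of class `phantom_truth` with elements
#'   `in_situ_flow` (logical grid), `plexus_label` (integer grid coded by
#'   `c(none=0, RPCP=1, SVP=2, ICP=3, DCP=4, interconnect=5)`),
#'   `artifact_flow` (filled in by [render_volume()]), `layer_model`,
#'   `sheets` (per-plexus en-face masks, voxel depths and continuous
#'   centerlines) and `fractions` (target vs achieved).
#' @export
generate_vasculature <- function(config, layers) {
  set.seed(config$seed)
  gs <- config$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  dxy <- config$voxel_spacing[1] / 1000
  x <- config_x_mm(config); y <- config_y_mm(config)
  r_fov <- sqrt(outer((x - config$fovea_center[1])^2,
                      (y - config$fovea_center[2])^2, "+"))
  sf <- layers$surfaces
  pp <- config$plexus_params

  gcc80 <- sf$ILM + 0.8 * (sf$IPL_INL - sf$ILM)
  z_rpcp_c <- (sf$ILM + sf$NFL_GCL) / 2
  z_svp_c <- (sf$NFL_GCL + gcc80) / 2
  mid_inl <- (sf$IPL_INL + sf$INL_OPL) / 2
  s0 <- sf$INL_OPL - sf$IPL_INL
  g <- pmax(0, 1 - r_fov / config$merge_eccentricity)
  z_icp_c <- mid_inl - g * s0 / 2
  z_dcp_c <- mid_inl + g * s0 / 2

  z_rpcp <- round(z_rpcp_c)
  z_svp <- round(z_svp_c)
  z_icp <- pmin(round(z_icp_c), ceiling(mid_inl) - 1)
  z_icp <- pmax(z_icp, ceiling(gcc80))
  z_dcp <- pmax(round(z_dcp_c), ceiling(mid_inl))
  z_dcp <- pmin(z_dcp, ceiling(sf$OPL_ONL) - 1)

  width_px <- function(p) p$width / config$voxel_spacing[1]
  cell_px <- function(p, frac) {
    (2 * p$width / 1000 / frac) / dxy
  }

  # SVP density shape: flat in the macula, linear decline to a peripheral
  # floor (mirrors the observed drop of superficial density with
  # eccentricity); ICP/DCP constant.
  dec <- pp$svp$decay
  shape <- 1 - (1 - dec$floor) *
    clamp((r_fov - dec$r0) / (dec$r1 - dec$r0), 0, 1)
  svp_map <- pp$svp$fraction * shape
  svp_mesh <- mesh_mask(nx, ny, cell_px(pp$svp, pp$svp$fraction), svp_map)
  icp_mesh <- mesh_mask(nx, ny, cell_px(pp$icp, pp$icp$fraction),
                        matrix(pp$icp$fraction, nx, ny))
  dcp_mesh <- mesh_mask(nx, ny, cell_px(pp$dcp, pp$dcp$fraction),
                        matrix(pp$dcp$fraction, nx, ny))

  rp <- ray_mask(config, pp$rpcp$fraction)
  rpcp_mask <- rp$mask

  trees <- tree_mask(config)

  # FAZ: no capillaries inside, a one-pixel perifoveal ring at the rim
  if (config$faz_radius > 0) {
    inside <- r_fov < config$faz_radius
    ring <- r_fov >= config$faz_radius &
      r_fov <= config$faz_radius + 1.2 * dxy
    for (nm in c("svp_mesh", "icp_mesh", "dcp_mesh")) {
      mm <- get(nm); mm[inside] <- FALSE; mm[ring] <- TRUE; assign(nm, mm)
    }
    trees[inside] <- FALSE
  }

  label <- array(0L, gs)
  nxy <- nx * ny
  place <- function(label, mask, zmat, code) {
    idx <- which(mask)
    if (!length(idx)) return(label)
    lin <- idx + (as.integer(zmat[idx]) - 1L) * nxy
    cur <- label[lin]
    label[lin[cur == 0L]] <- code
    label
  }
  label <- place(label, trees, z_svp, plexus_codes[["SVP"]])
  if (any(trees)) {
    label <- place(label, trees, pmax(z_svp - 1, ceiling(sf$NFL_GCL)),
                   plexus_codes[["SVP"]])
    label <- place(label, trees, pmin(z_svp + 1, ceiling(gcc80) - 1),
                   plexus_codes[["SVP"]])
  }
  large_vessel <- label > 0L          # trees only, placed first
  label <- place(label, svp_mesh, z_svp, plexus_codes[["SVP"]])
  label <- place(label, rpcp_mask, z_rpcp, plexus_codes[["RPCP"]])
  label <- place(label, icp_mesh, z_icp, plexus_codes[["ICP"]])
  label <- place(label, dcp_mesh, z_dcp, plexus_codes[["DCP"]])

  # vertical interconnecting segments: SVP -> ICP and SVP -> DCP
  rate <- pp$interconnect_rate
  ic_from <- which(icp_mesh & svp_mesh)
  dc_from <- which(dcp_mesh & svp_mesh)
  pick <- function(v, r) v[stats::runif(length(v)) < r]
  for (i in pick(ic_from, rate)) {
    zr <- seq(z_svp[i] + 1L, z_icp[i] - 1L)
    if (length(zr)) {
      lin <- i + (zr - 1L) * nxy
      label[lin[label[lin] == 0L]] <- plexus_codes[["interconnect"]]
    }
  }
  for (i in pick(dc_from, rate)) {
    zr <- seq(z_svp[i] + 1L, z_dcp[i] - 1L)
    if (length(zr)) {
      lin <- i + (zr - 1L) * nxy
      label[lin[label[lin] == 0L]] <- plexus_codes[["interconnect"]]
    }
  }

  in_situ <- label > 0L
  cc <- config$choriocapillaris
  if (isTRUE(cc$enabled)) {
    z_cc <- round(sf$RPE[1, 1]) + cc$offset_vox
    for (p in seq_len(cc$planes)) {
      zp <- z_cc + p - 1L
      if (zp <= nz) {
        sel <- which(stats::runif(nxy) < cc$fraction) + (zp - 1L) * nxy
        in_situ[sel] <- TRUE
      }
    }
  }

  # achieved fractions over each plexus' vascular domain
  vasc_dom <- r_fov >= config$faz_radius
  frac_tab <- data.frame(
    plexus = c("RPCP", "SVP", "ICP", "DCP"),
    target = c(pp$rpcp$fraction, pp$svp$fraction, pp$icp$fraction,
               pp$dcp$fraction),
    achieved = c(
      if (any(rp$domain)) sum(rpcp_mask & rp$domain) / sum(rp$domain) else NA,
      {
        dom <- vasc_dom & r_fov <= dec$r0
        if (any(dom)) sum(svp_mesh & dom) / sum(dom) else
          sum(svp_mesh & vasc_dom) / sum(vasc_dom) / mean(shape[vasc_dom])
      },
      sum(icp_mesh & vasc_dom) / sum(vasc_dom),
      sum(dcp_mesh & vasc_dom) / sum(vasc_dom)))
  for (k in seq_len(nrow(frac_tab))) {
    a <- frac_tab$achieved[k]
    if (!is.na(a) && abs(a / frac_tab$target[k] - 1) > 0.10)
      stop(sprintf(paste0("target area fraction unreachable for %s at the ",
                          "given capillary width: achieved %.3f vs target %.3f"),
                   frac_tab$plexus[k], a, frac_tab$target[k]))
  }

  structure(list(
    in_situ_flow = in_situ,
    large_vessel = large_vessel,
    plexus_label = label,
    artifact_flow = NULL,
    layer_model = layers,
    sheets = list(
      rpcp = list(mask = rpcp_mask, z = z_rpcp, z_cont = z_rpcp_c),
      svp = list(mask = svp_mesh | trees, z = z_svp, z_cont = z_svp_c),
      icp = list(mask = icp_mesh, z = z_icp, z_cont = z_icp_c),
      dcp = list(mask = dcp_mesh, z = z_dcp, z_cont = z_dcp_c),
      trees = list(mask = trees, z = z_svp)),
    fractions = frac_tab,
    seed = config$seed),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s voxels, %d in-situ flow, %s artifact-only\n",
              paste(dim(x$in_situ_flow), collapse = " x "),
              sum(x$in_situ_flow),
              if (is.null(x$artifact_flow)) "unrendered"
              else format(sum(x$artifact_flow))))
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

#' Check phantom ground-truth invariants
#'
#' Asserts that in-situ and artifact-only grids are disjoint and that every
#' labeled plexus voxel lies inside its host anatomic band (RPCP between
#' ILM and NFL/GCL; SVP between NFL/GCL and the inner-80%-of-GCC limit;
#' ICP between that limit and mid-INL; DCP between mid-INL and OPL/ONL;
#' bands half-open with the voxel-center convention).
#'
#' @param truth a `phantom_truth`.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
check_truth <- function(truth) {
  if (!is.null(truth$artifact_flow) &&
      any(truth$in_situ_flow & truth$artifact_flow))
    stop("in_situ_flow and artifact_flow are not disjoint")
  sf <- truth$layer_model$surfaces
  gcc80 <- sf$ILM + 0.8 * (sf$IPL_INL - sf$ILM)
  mid_inl <- (sf$IPL_INL + sf$INL_OPL) / 2
  bands <- list(RPCP = list(sf$ILM, sf$NFL_GCL),
                SVP = list(sf$NFL_GCL, gcc80),
                ICP = list(gcc80, mid_inl),
                DCP = list(mid_inl, sf$OPL_ONL))
  d <- dim(truth$plexus_label)
  nxy <- d[1] * d[2]
  for (nm in names(bands)) {
    idx <- which(truth$plexus_label == plexus_codes[[nm]])
    if (!length(idx)) next
    z <- (idx - 1L) %/% nxy + 1L
    pix <- (idx - 1L) %% nxy + 1L
    lo <- bands[[nm]][[1]][pix]; hi <- bands[[nm]][[2]][pix]
    if (any(z < lo - 1e-9 | z >= hi - 1e-9))
      stop(nm, " voxels escape their host anatomic band")
  }
  invisible(TRUE)
}
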