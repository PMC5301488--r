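#' Phantom configuration
#'
#' Builds the full parameter set for the synthetic retinal OCTA phantom:
#' acquisition geometry, layered anatomy, plexus vasculature, projection
#' tails and noise. Defaults emulate a 70 kHz SD-OCT geometry (3.1 um axial
#' voxel height; 15 um transverse sampling at full scale) and macular
#' capillary fractions on the scale reported for healthy eyes
#' (SVP 0.30, ICP 0.21, DCP 0.14, RPCP 0.30 near the disc edge).
#'
#' Presets:
#' * `"widefield"`: 456 x 28 x 192 voxels at (30, 30, 3.1) um spanning
#'   x in about \[-5, 8.65\] mm, covering disc, fovea and temporal periphery
#'   in a thin swath along the maculopapillary axis. This is the default
#'   study condition for depth profiles, plexus detection and the ICP/DCP
#'   merge locus.
#' * `"macula"`: 160 x 96 x 192 at (15, 15, 3.1) um centred on the fovea.
#' * `"flat"`: 200 x 200 x 160 at (15, 15, 3.1) um, 3 x 3 mm, pit and
#'   peripapillary modulation off, no foveal avascular zone and no large
#'   vessel trees — the calibration bench for area-fraction recovery.
#'
#' Layer base thicknesses are voxel multiples of 3.1 um so that the flat
#' periphery has reproducible integer boundary planes; total stacked
#' thickness (retina 356.5 um under 80.6 um of vitreous) fits the axial
#' grid everywhere, which `validate_phantom_config()` asserts.
#'
#' @param preset one of `"widefield"`, `"macula"`, `"flat"`.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   phantoms.
#' @param ... named overrides of any top-level field (lists are replaced
#'   element-wise).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(preset = c("widefield", "macula", "flat"),
                           seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    grid_shape = c(456L, 28L, 192L),
    voxel_spacing = c(30, 30, 3.1),
    origin_mm = c(-5.0, -0.405),
    fovea_center = c(0, 0),
    disc_center = c(-4.0, 0),
    disc_radius = 0.75,
    layer_params = list(
      vitreous_offset = 80.6,               # um above the ILM (flat locus)
      nfl = 31.0, gcl_ipl = 93.0, inl = 43.4, opl = 34.1, outer = 155.0,
      pit_depth = 100, pit_sigma = 0.35,    # um / mm
      nfl_gain = 62, nfl_sigma = 1.0),      # um at disc center / mm
    plexus_params = list(
      rpcp = list(fraction = 0.30, width = 15, pattern = "radial",
                  extent_mm = 2.2),
      svp  = list(fraction = 0.30, width = 15, pattern = "mesh",
                  decay = list(r0 = 2.5, r1 = 7.0, floor = 0.55),
                  n_trees = 2L),
      icp  = list(fraction = 0.21, width = 15, pattern = "lobular"),
      dcp  = list(fraction = 0.14, width = 15, pattern = "lobular"),
      interconnect_rate = 0.02),
    faz_radius = 0.3,
    merge_eccentricity = 6.5,
    tail_params = list(alpha = 0.8, gate = 0.15),
    noise_params = list(speckle = 0.25, decorr_sd = 0.02),
    flow_params = list(mode = "uniform", range = c(0.20, 0.35),
                       vessel_range = c(0.45, 0.60)),
    choriocapillaris = list(enabled = TRUE, fraction = 0.65,
                            offset_vox = 3L, planes = 2L),
    reflectance_levels = list(vitreous = 0.04, nfl = 1.0, gcl_ipl = 0.65,
                              inl = 0.45, opl = 0.60, outer = 0.28,
                              rpe = 1.15, choroid = 0.50),
    seed = as.integer(seed))
  if (preset == "macula") {
    cfg$grid_shape <- c(160L, 96L, 192L)
    cfg$voxel_spacing <- c(15, 15, 3.1)
    cfg$origin_mm <- c(-1.1925, -0.7125)
    cfg$plexus_params$svp$n_trees <- 1L
  } else if (preset == "flat") {
    cfg$grid_shape <- c(200L, 200L, 160L)
    cfg$voxel_spacing <- c(15, 15, 3.1)
    cfg$origin_mm <- c(-1.4925, -1.4925)
    cfg$layer_params$pit_depth <- 0
    cfg$layer_params$nfl_gain <- 0
    cfg$faz_radius <- 0
    cfg$plexus_params$svp$n_trees <- 0L
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown phantom_config field: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg <- structure(cfg, class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

#' Validate a phantom configuration
#'
#' Checks the structural invariants: positive spacings, the axial grid
#' deep enough for the stacked layers everywhere (including peripapillary
#' thickening), capillary area fractions in (0, 1), nonnegative FAZ radius
#' and tail attenuation in (0, 1).
#'
#' @param config a `phantom_config`.
#' @return the config, invisibly; errors describe the violated invariant.
#' @export
validate_phantom_config <- function(config) {
  if (any(config$voxel_spacing <= 0)) stop("all voxel spacings must be > 0")
  lp <- config$layer_params
  total <- lp$vitreous_offset + lp$nfl + lp$gcl_ipl + lp$inl + lp$opl +
    lp$outer + lp$nfl_gain
  cc_extra <- if (isTRUE(config$choriocapillaris$enabled))
    (config$choriocapillaris$offset_vox + config$choriocapillaris$planes) *
      config$voxel_spacing[3] else 0
  if (config$grid_shape[3] * config$voxel_spacing[3] <= total + cc_extra)
    stop("axial grid (nz * dz) does not exceed total stacked layer thickness")
  inner_total <- lp$nfl + lp$gcl_ipl + lp$inl + lp$opl
  if (lp$pit_depth > 0.97 * inner_total)
    stop("layer collision: foveal pit depth exceeds inner layer thickness")
  for (nm in c("rpcp", "svp", "icp", "dcp")) {
    f <- config$plexus_params[[nm]]$fraction
    if (f <= 0 || f >= 1)
      stop("capillary area fraction for ", nm, " must lie in (0, 1)")
  }
  if (config$faz_radius < 0) stop("faz_radius must be >= 0")
  a <- config$tail_params$alpha
  if (a < 0 || a >= 1)
    stop("tail attenuation alpha must lie in [0, 1); 0 disables tails")
  if (config$merge_eccentricity <= 0) stop("merge_eccentricity must be > 0")
  if (!is.finite(config$seed)) stop("seed must be a finite integer")
  invisible(config)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> preset '%s', %d x %d x %d @ (%g, %g, %g) um, seed %d\n",
              x$preset, x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3],
              x$seed))
  invisible(x)
}

config_x_mm <- function(config) {
  config$origin_mm[1] +
    (seq_len(config$grid_shape[1]) - 1) * config$voxel_spacing[1] / 1000
}

config_y_mm <- function(config) {
  config$origin_mm[2] +
    (seq_len(config$grid_shape[2]) - 1) * config$voxel_spacing[2] / 1000
}

config_landmarks <- function(config) {
  data.frame(
    name = c("fovea", "disc_center", "disc_edge"),
    x_mm = c(config$fovea_center[1], config$disc_center[1],
             config$disc_center[1] + config$disc_radius),
    y_mm = c(config$fovea_center[2], config$disc_center[2],
             config$disc_center[2]))
}
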