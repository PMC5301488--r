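#' Generate the phantom's retinal layer boundary surfaces
#'
#' Builds seven ordered depth surfaces (six anatomic boundaries plus the
#' implicit flat choroidal floor) bottom-up from a flat RPE: boundary
#' depths are cumulative layer thicknesses measured up from the RPE, so
#' thinning the inner layers at the fovea produces the pit as a depression
#' of the ILM (and all inner boundaries) while the outer retina stays
#' put, and peripapillary nerve-fiber-layer thickening lifts the ILM
#' toward the vitreous near the disc. All modulations are smooth Gaussians
#' of transverse position, hence band-limited surfaces.
#'
#' Modulations:
#' * foveal pit: the four inner layers (NFL, GCL+IPL, INL, OPL) are
#'   multiplied by `1 - p * exp(-r^2 / (2 * pit_sigma^2))` where `r` is
#'   distance from the fovea and `p = pit_depth / sum(inner thicknesses)`.
#' * peripapillary NFL: the NFL thickness gains
#'   `nfl_gain * exp(-d^2 / (2 * nfl_sigma^2))` um, `d` the distance from
#'   the disc center.
#'
#' Landmarks may lie outside the grid; their modulations then simply
#' evaluate to ~0 inside the field of view.
#'
#' @param config a [phantom_config()].
#' @return a [layer_model()] with surfaces in fractional 1-based voxel
#'   units. Errors if the configuration would make surfaces collide or
#'   leave the axial grid.
#' @export
generate_layer_model <- function(config) {
  gs <- config$grid_shape
  dz <- config$voxel_spacing[3]
  lp <- config$layer_params
  x <- config_x_mm(config); y <- config_y_mm(config)
  r_fov <- sqrt(outer((x - config$fovea_center[1])^2,
                      (y - config$fovea_center[2])^2, "+"))
  r_disc <- sqrt(outer((x - config$disc_center[1])^2,
                       (y - config$disc_center[2])^2, "+"))

  inner_total <- lp$nfl + lp$gcl_ipl + lp$inl + lp$opl
  p <- if (lp$pit_depth > 0) lp$pit_depth / inner_total else 0
  if (p > 0.97) stop("layer collision: pit depth exceeds inner thickness")
  pit <- 1 - p * exp(-r_fov^2 / (2 * lp$pit_sigma^2))

  t_nfl <- lp$nfl * pit + lp$nfl_gain * exp(-r_disc^2 / (2 * lp$nfl_sigma^2))
  t_gcl <- lp$gcl_ipl * pit
  t_inl <- lp$inl * pit
  t_opl <- lp$opl * pit
  t_out <- matrix(lp$outer, gs[1], gs[2])

  z_rpe <- (lp$vitreous_offset + lp$nfl + lp$gcl_ipl + lp$inl + lp$opl +
              lp$outer) / dz + 1    # constant depth, 1-based voxel units
  rpe <- matrix(z_rpe, gs[1], gs[2])
  opl_onl <- rpe - t_out / dz
  inl_opl <- opl_onl - t_opl / dz
  ipl_inl <- inl_opl - t_inl / dz
  nfl_gcl <- ipl_inl - t_gcl / dz
  ilm <- nfl_gcl - t_nfl / dz
  if (min(ilm) < 1)
    stop("layer collision: ILM pushed out of the grid (reduce nfl_gain ",
         "or increase vitreous_offset)")
  layer_model(list(ILM = ilm, NFL_GCL = nfl_gcl, IPL_INL = ipl_inl,
                   INL_OPL = inl_opl, OPL_ONL = opl_onl, RPE = rpe),
              nz = gs[3])
}

#' Ganglion cell complex thickness field of a layer model
#'
#' GCC = NFL + GCL + IPL, i.e. the band from the ILM to the IPL/INL
#' boundary, returned in micrometres.
#'
#' @param layers a `layer_model`.
#' @param dz axial voxel height in um.
#' @return matrix of thicknesses.
#' @export
gcc_thickness <- function(layers, dz = 3.1) {
  (layers$surfaces$IPL_INL - layers$surfaces$ILM) * dz
}
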