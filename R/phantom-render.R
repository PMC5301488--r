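#' Render a phantom truth into an OCTA volume
#'
#' Produces co-registered reflectance and decorrelation grids:
#'
#' * Reflectance: per-layer base levels (NFL bright, nuclear layers dark,
#'   RPE brightest) modulated by multiplicative log-normal speckle of the
#'   configured contrast (unit median).
#' * Decorrelation: in-situ flow voxels draw from the configured flow
#'   distribution (default uniform on \[0.3, 0.6\] of the SSADA scale, above
#'   the 0.12 large-vessel threshold); every voxel below an in-situ flow
#'   voxel in the same axial line whose local reflectance exceeds the gate
#'   receives a projection-tail value attenuated exponentially with the
#'   depth gap (`alpha` per mm) — the "flickering shadow" of superficial
#'   flow. Attenuation is applied in reflectance-normalized space and the
#'   stored tail value is scaled back by the local normalization factor,
#'   so a shadow can never exceed its source after reflectance
#'   normalization, and under uniform reflectance the stored tail equals
#'   `source * alpha^gap` exactly. Gaussian background noise is then added
#'   everywhere and the result clamped to \[0, 1\].
#'
#' With `flow_params$mode = "increasing"` the in-situ values of each axial
#' scan are assigned strictly increasing reflectance-normalized targets
#' (shallow to deep), a construction under which the projection-resolution
#' rule retains every in-situ voxel.
#'
#' Tail-only voxels are recorded in `truth$artifact_flow`.
#'
#' @param config a [phantom_config()].
#' @param truth output of [generate_vasculature()].
#' @return list with elements `volume` (an [octa_volume()]) and `truth`
#'   (the input truth with `artifact_flow` filled in).
#' @export
render_volume <- function(config, truth) {
  set.seed(config$seed + 7919L)
  gs <- config$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  nxy <- nx * ny
  sf <- truth$layer_model$surfaces
  lv <- config$reflectance_levels

  # base reflectance by layer membership (voxel-center convention)
  base <- array(0, gs)
  z_rpe_out <- sf$RPE + 3            # bright RPE complex band
  for (z in seq_len(nz)) {
    pl <- matrix(lv$choroid, nx, ny)
    pl[z < z_rpe_out] <- lv$rpe
    pl[z < sf$RPE] <- lv$outer
    pl[z < sf$OPL_ONL] <- lv$opl
    pl[z < sf$INL_OPL] <- lv$inl
    pl[z < sf$IPL_INL] <- lv$gcl_ipl
    pl[z < sf$NFL_GCL] <- lv$nfl
    pl[z < sf$ILM] <- lv$vitreous
    base[, , z] <- pl
  }
  sc <- config$noise_params$speckle
  refl <- if (sc > 0) base * exp(sc * stats::rnorm(length(base))) else base

  # reference reflectance: median over the inner retina (ILM .. OPL/ONL)
  inner <- array(FALSE, gs)
  for (z in seq_len(nz)) inner[, , z] <- z >= sf$ILM & z < sf$OPL_ONL
  r_ref <- stats::median(refl[inner])
  eps <- 0.5
  nf <- pmax(refl / r_ref, eps)      # normalization factor per voxel

  # in-situ decorrelation
  flow <- array(0, gs)               # reflectance-normalized in-situ values
  idx <- which(truth$in_situ_flow)
  fp <- config$flow_params
  if (identical(fp$mode, "increasing")) {
    pix <- (idx - 1L) %% nxy + 1L
    z <- (idx - 1L) %/% nxy + 1L
    ord <- order(pix, z)
    idx <- idx[ord]; pix <- pix[ord]
    rk <- stats::ave(seq_along(idx), pix, FUN = seq_along)
    cnt <- stats::ave(seq_along(idx), pix, FUN = length)
    dbar_target <- 0.35 + 0.4 * (rk - 1) / pmax(cnt - 1, 1)
    flow[idx] <- dbar_target
  } else {
    u <- stats::runif(length(idx))
    lv <- if (!is.null(truth$large_vessel)) truth$large_vessel[idx]
          else rep(FALSE, length(idx))
    vr <- fp$vessel_range %||% fp$range
    dvals <- ifelse(lv, vr[1] + u * (vr[2] - vr[1]),
                    fp$range[1] + u * (fp$range[2] - fp$range[1]))
    flow[idx] <- dvals / nf[idx]
  }

  # projection tails: per axial line, the running attenuated maximum of
  # shallower in-situ normalized values; both source and tail decay at the
  # same per-mm rate so a single recursion suffices.
  alpha <- config$tail_params$alpha
  gate <- config$tail_params$gate
  a_step <- if (alpha > 0) alpha^(config$voxel_spacing[3] / 1000) else 0
  tails <- array(0, gs)
  carry <- matrix(0, nx, ny)
  for (z in seq_len(nz)) {
    if (z > 1L)
      carry <- pmax(carry, flow[, , z - 1L]) * a_step
    tails[, , z] <- carry * (refl[, , z] > gate)
  }

  dbar <- pmax(flow, tails)
  decorr <- dbar * nf
  sdn <- config$noise_params$decorr_sd
  if (sdn > 0) decorr <- decorr + stats::rnorm(length(decorr), 0, sdn)
  decorr <- clamp(decorr, 0, 1)
  # in-situ voxels keep values inside [0,1] by construction of the flow
  # distribution; extreme speckle can push D past 1, clamp handles it.

  truth$artifact_flow <- tails > 0 & !truth$in_situ_flow
  vol <- octa_volume(refl, decorr,
                     spacing = config$voxel_spacing,
                     origin = config$origin_mm,
                     landmarks = config_landmarks(config),
                     meta = list(kind = "phantom", seed = config$seed,
                                 r_ref = r_ref, norm_eps = eps,
                                 tail_alpha = alpha, tail_gate = gate,
                                 config_hash = object_hash(
                                   unclass(config))))
  list(volume = vol, truth = truth)
}

#' Simulate a complete OCTA phantom
#'
#' Convenience wrapper: layer model, vasculature and rendering in one call.
#'
#' @param config a [phantom_config()]; identical config + seed gives
#'   bit-identical output.
#' @return list with `volume`, `truth`, `config`.
#' @export
simulate_phantom <- function(config = phantom_config()) {
  layers <- generate_layer_model(config)
  truth <- generate_vasculature(config, layers)
  out <- render_volume(config, truth)
  list(volume = out$volume, truth = out$truth, config = config)
}
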