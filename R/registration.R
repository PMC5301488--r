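#' Flatten a volume to the RPE
#'
#' Shifts each axial line by an integer number of voxels so the RPE sits
#' at a constant depth (the deepest rounded RPE position across the
#' field, so no column shifts upward out of the grid). Padded voxels are
#' zero; columns whose inner retina would leave the grid are flagged in
#' the returned attributes. Idempotent: a flat RPE yields the identity.
#'
#' @param volume an [octa_volume()].
#' @param layers the matching [layer_model()].
#' @param target optional target RPE depth (integer voxels).
#' @return list with `volume` (flattened), `layers` (shifted surfaces) and
#'   `shift` (en-face matrix of per-column shifts, positive = moved
#'   deeper).
#' @export
flatten_to_rpe <- function(volume, layers, target = NULL) {
  d <- dim(volume)
  rpe <- round(layers$surfaces$RPE)
  if (min(rpe) < 1 || max(rpe) > d[3]) stop("RPE surface outside the grid")
  if (is.null(target)) target <- max(rpe)
  shift <- target - rpe                      # >= 0 when target = max
  shift_grid <- function(arr) {
    m <- matrix(arr, d[1] * d[2], d[3])
    out <- matrix(0, d[1] * d[2], d[3])
    for (z in seq_len(d[3])) {
      src <- z - as.vector(shift)
      ok <- src >= 1 & src <= d[3]
      out[ok, z] <- m[cbind(which(ok), src[ok])]
    }
    array(out, d)
  }
  lost <- as.vector(shift) < 0 |
    (layers$surfaces$ILM + shift) < 1
  newsurf <- lapply(layers$surfaces, function(s) s + shift)
  out <- octa_volume(shift_grid(volume$reflectance),
                     shift_grid(volume$decorrelation),
                     volume$spacing, volume$origin, volume$landmarks,
                     meta = c(volume$meta, list(rpe_flattened = target)))
  res <- list(volume = out, layers = layer_model(newsurf, nz = d[3]),
              shift = matrix(shift, d[1], d[2]))
  attr(res, "clipped_columns") <- which(matrix(lost, d[1], d[2]))
  res
}

# piecewise-linear axial warp between two layer models, per column.
# Segments: [top, ILM], [ILM, NFL_GCL], [NFL_GCL, IPL_INL],
# [IPL_INL, INL_OPL], [INL_OPL, OPL_ONL], [OPL_ONL, RPE], [RPE, bottom] —
# the middle four realize the (ILM+NFL, GCL+IPL, INL, OPL) grouping.
warp_breaks <- function(layers, nz) {
  s <- layers$surfaces
  ncol <- length(s$ILM)
  cbind(rep(1, ncol), as.vector(s$ILM), as.vector(s$NFL_GCL),
        as.vector(s$IPL_INL), as.vector(s$INL_OPL), as.vector(s$OPL_ONL),
        as.vector(s$RPE), rep(nz, ncol))
}

#' Normalize a volume's depth axis to a reference subject
#'
#' Within each major structural layer (ILM+NFL, GCL+IPL, INL, OPL, and
#' the outer retina to the RPE) the depth axis is rescaled linearly so
#' the layer's thickness matches the reference layer model. Flow
#' (decorrelation) is resampled by forward nearest-neighbour splatting —
#' every source flow voxel lands in exactly one reference plane, which
#' keeps the flow-voxel count approximately conserved and never smears
#' values across the suprathreshold cut; reflectance is resampled with
#' linear interpolation. Columns where a source layer has (near) zero
#' thickness against a nonzero reference are flagged and their flow
#' dropped.
#'
#' @param volume an [octa_volume()] (RPE-flattened recommended).
#' @param layers its [layer_model()].
#' @param reference_layers the reference subject's [layer_model()] (same
#'   transverse grid).
#' @return list with `volume` (in reference depth coordinates), `layers`
#'   (= reference), and `flagged` (column indices excluded).
#' @export
normalize_depth <- function(volume, layers, reference_layers) {
  d <- dim(volume)
  ncol <- d[1] * d[2]
  bs <- warp_breaks(layers, d[3])
  br <- warp_breaks(reference_layers, d[3])
  if (nrow(br) != ncol) stop("reference layer grid mismatch")
  ts <- bs[, -1, drop = FALSE] - bs[, -8, drop = FALSE]  # segment thicknesses
  tr <- br[, -1, drop = FALSE] - br[, -8, drop = FALSE]
  flagged <- which(apply(ts < 0.25 & tr >= 0.25, 1, any))

  seg_of <- function(breaks, z) {
    # segment index per column for depth z (columns vary): 1..7
    g <- rep(1L, nrow(breaks))
    for (k in 2:7) g <- g + (z >= breaks[, k])
    pmin(g, 7L)
  }

  # reflectance: gather with linear interpolation (reference -> source)
  rs <- matrix(volume$reflectance, ncol, d[3])
  rout <- matrix(0, ncol, d[3])
  cols <- seq_len(ncol)
  for (z in seq_len(d[3])) {
    g <- seg_of(br, z)
    lo_r <- br[cbind(cols, g)]; lo_s <- bs[cbind(cols, g)]
    ratio <- ts[cbind(cols, g)] / pmax(tr[cbind(cols, g)], 1e-9)
    zsrc <- lo_s + (z - lo_r) * ratio
    z0 <- floor(zsrc); f <- zsrc - z0
    z0 <- clamp(z0, 1, d[3]); z1 <- clamp(z0 + 1, 1, d[3])
    rout[, z] <- (1 - f) * rs[cbind(cols, z0)] + f * rs[cbind(cols, z1)]
  }

  # flow: forward splat (source -> reference), keep max on collisions
  ds <- matrix(volume$decorrelation, ncol, d[3])
  dout <- matrix(0, ncol, d[3])
  fv <- which(ds > 0, arr.ind = TRUE)
  if (nrow(fv)) {
    ci <- fv[, 1]; z <- fv[, 2]
    g <- rep(1L, length(ci))
    for (k in 2:7) g <- g + (z >= bs[cbind(ci, rep(k, length(ci)))])
    g <- pmin(g, 7L)
    lo_s <- bs[cbind(ci, g)]; lo_r <- br[cbind(ci, g)]
    ratio <- tr[cbind(ci, g)] / pmax(ts[cbind(ci, g)], 1e-9)
    zref <- round(lo_r + (z - lo_s) * ratio)
    ok <- zref >= 1 & zref <= d[3] & !(ci %in% flagged) &
      ts[cbind(ci, g)] >= 0.25
    if (any(ok)) {
      lin <- ci[ok] + (zref[ok] - 1) * ncol
      val <- ds[cbind(ci[ok], z[ok])]
      o <- order(val)                       # max wins on collisions
      dout[lin[o]] <- val[o]
    }
  }
  out <- octa_volume(array(rout, d), array(clamp(dout, 0, 1), d),
                     volume$spacing, volume$origin, volume$landmarks,
                     meta = c(volume$meta, list(depth_normalized = TRUE)))
  list(volume = out, layers = reference_layers, flagged = flagged)
}

#' Normalize the transverse axis to reference landmarks
#'
#' One-dimensional affine map of the x axis sending the subject's disc
#' and fovea centers to the reference positions. Flow columns are gathered
#' nearest-neighbour, reflectance linearly.
#'
#' @param volume an [octa_volume()] with landmarks.
#' @param reference_landmarks data.frame like `volume$landmarks`.
#' @return an `octa_volume` on the same grid with reference-space
#'   landmarks.
#' @export
normalize_transverse <- function(volume, reference_landmarks) {
  get_lm <- function(lm, nm) lm$x_mm[lm$name == nm][1]
  f_s <- get_lm(volume$landmarks, "fovea")
  d_s <- get_lm(volume$landmarks, "disc_center")
  f_r <- get_lm(reference_landmarks, "fovea")
  d_r <- get_lm(reference_landmarks, "disc_center")
  if (anyNA(c(f_s, d_s, f_r, d_r))) stop("missing fovea/disc landmarks")
  b <- (d_s - f_s) / (d_r - f_r)        # ref -> source scale
  xr <- x_coords(volume)                 # output grid in reference space
  xsrc <- f_s + (xr - f_r) * b
  dx <- volume$spacing[1] / 1000
  isrc <- (xsrc - volume$origin[1]) / dx + 1
  d <- dim(volume)
  refl <- array(0, d); dec <- array(0, d)
  i0 <- clamp(floor(isrc), 1, d[1]); i1 <- clamp(i0 + 1, 1, d[1])
  f <- clamp(isrc - floor(isrc), 0, 1)
  inn <- round(isrc); okn <- inn >= 1 & inn <= d[1]
  for (i in seq_len(d[1])) {
    if (isrc[i] >= 0.5 && isrc[i] <= d[1] + 0.5) {
      refl[i, , ] <- (1 - f[i]) * volume$reflectance[i0[i], , ] +
        f[i] * volume$reflectance[i1[i], , ]
      if (okn[i]) dec[i, , ] <- volume$decorrelation[inn[i], , ]
    }
  }
  octa_volume(refl, dec, volume$spacing, volume$origin,
              reference_landmarks,
              meta = c(volume$meta, list(transverse_normalized = TRUE)))
}
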