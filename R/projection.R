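#' Reflectance-normalize a decorrelation volume
#'
#' Computes `Dbar = D / max(R / R_ref, eps)`, where `R_ref` is the median
#' reflectance over the inner retina (ILM to OPL/ONL) when a layer model
#' is supplied, or the volume median otherwise. The floor `eps` (a
#' fraction of `R_ref`) stops optically empty regions — vitreous above the
#' ILM in particular — from having their noise amplified without bound;
#' the normalization form is isolated here so alternatives are pluggable.
#'
#' @param volume an [octa_volume()].
#' @param layers optional [layer_model()] for the inner-retina reference.
#' @param r_ref explicit reference reflectance (overrides `layers`).
#' @param eps normalization floor as a fraction of `r_ref` (default 0.5).
#' @return an object of class `normalized_flow`: the `dbar` grid, the
#'   normalization parameters, and a `theta` slot (NA until set by
#'   [estimate_noise_threshold()] / [set_threshold()]).
#' @export
normalize_decorrelation <- function(volume, layers = NULL, r_ref = NULL,
                                    eps = 0.5) {
  if (max(volume$reflectance) <= 0)
    stop("all-zero reflectance: cannot normalize")
  if (eps <= 0) stop("normalization floor eps must be > 0")
  if (is.null(r_ref)) {
    if (!is.null(layers)) {
      sf <- layers$surfaces
      nz <- dim(volume)[3]
      acc <- vector("list", nz)
      for (z in seq_len(nz)) {
        sel <- z >= sf$ILM & z < sf$OPL_ONL
        if (any(sel)) acc[[z]] <- volume$reflectance[, , z][sel]
      }
      r_ref <- stats::median(unlist(acc))
    } else {
      r_ref <- stats::median(volume$reflectance)
    }
  }
  if (!is.finite(r_ref) || r_ref <= 0)
    stop("reference reflectance must be positive")
  dbar <- volume$decorrelation / pmax(volume$reflectance / r_ref, eps)
  structure(list(dbar = dbar, r_ref = r_ref, eps = eps, theta = NA_real_),
            class = "normalized_flow")
}

#' @export
print.normalized_flow <- function(x, ...) {
  cat(sprintf("<normalized_flow> %s, r_ref = %.4g, eps = %.2f, theta = %s\n",
              paste(dim(x$dbar), collapse = " x "), x$r_ref, x$eps,
              if (is.na(x$theta)) "unset" else format(x$theta)))
  invisible(x)
}

#' Estimate the flow/noise threshold from a noise region
#'
#' `theta = mean + multiplier * SD` of the normalized decorrelation inside
#' the supplied region — about the 99th percentile under normality at the
#' default multiplier 2.33. The canonical region is an avascular band such
#' as the outer nuclear layer.
#'
#' @param normflow a `normalized_flow`.
#' @param noise_region logical array (same shape as `dbar`) marking noise
#'   voxels; must contain at least 100 voxels.
#' @param multiplier SD multiplier (default 2.33).
#' @return the threshold `theta` (numeric scalar).
#' @export
estimate_noise_threshold <- function(normflow, noise_region,
                                     multiplier = 2.33) {
  stopifnot(inherits(normflow, "normalized_flow"))
  if (!identical(dim(noise_region), dim(normflow$dbar)))
    stop("noise_region shape mismatch")
  v <- normflow$dbar[noise_region]
  if (length(v) < 100)
    stop("noise region too small (< 100 voxels)")
  mean(v) + multiplier * stats::sd(v)
}

#' Set the suprathreshold cut on a normalized flow object
#' @param normflow a `normalized_flow`.
#' @param theta positive threshold on normalized decorrelation.
#' @return the updated `normalized_flow`.
#' @export
set_threshold <- function(normflow, theta) {
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  normflow$theta <- theta
  normflow
}

#' Resolve projection artifact (PR-OCTA rule)
#'
#' Classifies each suprathreshold voxel per axial scan line: a voxel keeps
#' its decorrelation value only if its reflectance-normalized
#' decorrelation is at least `theta` AND strictly exceeds the maximum over
#' all shallower voxels of the same axial line; everything else is set to
#' zero. Equality with the running maximum counts as artifact (a shadow
#' can at most replicate its source), and the first suprathreshold voxel
#' of a line is always retained (the maximum over the empty shallower set
#' is -Inf). The retained normalized values therefore increase strictly
#' with depth in every axial line, and the operation is idempotent.
#'
#' @param normflow a `normalized_flow` with `theta` set.
#' @param volume the [octa_volume()] the normalization was derived from.
#' @return a new `octa_volume` whose decorrelation contains in-situ flow
#'   only; `meta$pr` records the threshold and normalization parameters.
#' @export
resolve_projection <- function(normflow, volume) {
  stopifnot(inherits(normflow, "normalized_flow"))
  if (!identical(dim(normflow$dbar), dim(volume$decorrelation)))
    stop("shape mismatch between normalized flow and volume")
  theta <- normflow$theta
  if (!is.finite(theta)) stop("theta is unset; call set_threshold() first")
  db <- normflow$dbar
  d <- dim(db)
  out <- array(0, d)
  runmax <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) {
    dz <- db[, , z]
    keep <- dz >= theta & dz > runmax
    if (any(keep)) {
      oz <- volume$decorrelation[, , z]
      oz[!keep] <- 0
      out[, , z] <- oz
    }
    runmax <- pmax(runmax, dz)
  }
  octa_volume(volume$reflectance, out, volume$spacing, volume$origin,
              volume$landmarks,
              meta = c(volume$meta,
                       list(pr = list(theta = theta, r_ref = normflow$r_ref,
                                      eps = normflow$eps))))
}

#' Columns of a volume with no inner-retinal flow signal
#'
#' Utility for building a clean noise region: marks en-face columns whose
#' maximum decorrelation between ILM and OPL/ONL stays below `cutoff`
#' (in-situ capillary values sit well above it), so the avascular outer
#' band beneath them carries no projection tails.
#'
#' @param volume an [octa_volume()].
#' @param layers a [layer_model()].
#' @param cutoff decorrelation cutoff (default 0.15, below the dimmest
#'   in-situ capillary values and far above the noise floor).
#' @return logical en-face matrix.
#' @export
flow_free_columns <- function(volume, layers, cutoff = 0.15) {
  sf <- layers$surfaces
  d <- dim(volume)
  mx <- matrix(0, d[1], d[2])
  for (z in seq_len(d[3])) {
    sel <- z >= sf$ILM & z < sf$OPL_ONL
    dz <- volume$decorrelation[, , z]
    dz[!sel] <- 0
    mx <- pmax(mx, dz)
  }
  mx < cutoff
}

#' Default avascular noise band (outer nuclear layer)
#'
#' Voxels between OPL/ONL and the RPE with a 2-voxel margin on either
#' side, restricted to flow-free columns so projection tails from
#' overlying vessels do not contaminate the noise statistics.
#'
#' @param volume an [octa_volume()].
#' @param layers a [layer_model()].
#' @param restrict_flow_free drop columns with inner-retinal flow.
#' @return logical array marking the noise region.
#' @export
onl_noise_region <- function(volume, layers, restrict_flow_free = TRUE) {
  sf <- layers$surfaces
  d <- dim(volume)
  reg <- array(FALSE, d)
  cols <- if (restrict_flow_free) flow_free_columns(volume, layers)
          else matrix(TRUE, d[1], d[2])
  for (z in seq_len(d[3])) {
    sel <- (z >= sf$OPL_ONL + 2) & (z < sf$RPE - 2) & cols
    reg[, , z] <- sel
  }
  reg
}

#' One-shot projection resolution
#'
#' Normalize, estimate the noise threshold from the outer nuclear layer
#' band (or use an explicit `theta`), and resolve.
#'
#' @param volume an [octa_volume()].
#' @param layers a [layer_model()].
#' @param theta optional explicit threshold; otherwise estimated.
#' @param eps normalization floor.
#' @param multiplier noise-threshold multiplier.
#' @return list with `volume` (resolved), `normflow`, `theta`.
#' @export
pr_resolve <- function(volume, layers, theta = NULL, eps = 0.5,
                       multiplier = 2.33) {
  nfl <- normalize_decorrelation(volume, layers, eps = eps)
  if (is.null(theta)) {
    theta <- estimate_noise_threshold(nfl, onl_noise_region(volume, layers),
                                      multiplier = multiplier)
  }
  nfl <- set_threshold(nfl, theta)
  list(volume = resolve_projection(nfl, volume), normflow = nfl,
       theta = theta)
}
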