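#' OCTA volume container
#'
#' Paired reflectance and decorrelation 3-D grids with voxel spacing and
#' transverse landmarks. Arrays are indexed `[x, y, z]` with z = 1 the
#' innermost (vitreous-side) plane; z increases with depth, so "shallower"
#' always means smaller z. Transverse coordinates are in mm relative to the
#' fovea center with positive x temporal.
#'
#' @param reflectance 3-D numeric array, nonnegative, arbitrary units.
#' @param decorrelation 3-D numeric array in `[0, 1]` (SSADA scale), same
#'   shape as `reflectance`.
#' @param spacing voxel spacing `c(dx, dy, dz)` in micrometres.
#' @param origin mm position `c(x0, y0)` of the first voxel center.
#' @param landmarks data.frame with columns `name`, `x_mm`, `y_mm`; should
#'   contain `fovea`, `disc_center` and `disc_edge`.
#' @param meta free-form provenance list.
#' @return an object of class `octa_volume`.
#' @export
octa_volume <- function(reflectance, decorrelation, spacing,
                        origin = c(0, 0), landmarks = NULL, meta = list()) {
  stopifnot(length(dim(reflectance)) == 3L, length(dim(decorrelation)) == 3L)
  if (!identical(dim(reflectance), dim(decorrelation)))
    stop("reflectance and decorrelation grids must share one shape")
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  rng <- range(decorrelation)
  if (rng[1] < 0 || rng[2] > 1) stop("decorrelation must lie in [0, 1]")
  if (min(reflectance) < 0) stop("reflectance must be nonnegative")
  structure(
    list(reflectance = reflectance, decorrelation = decorrelation,
         spacing = as.numeric(spacing), origin = as.numeric(origin),
         landmarks = landmarks, meta = meta),
    class = "octa_volume")
}

#' @export
dim.octa_volume <- function(x) dim(x$decorrelation)

#' @export
print.octa_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<octa_volume> %d x %d x %d voxels @ (%.1f, %.1f, %.1f) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  x: [%.2f, %.2f] mm, y: [%.2f, %.2f] mm\n",
              min(x_coords(x)), max(x_coords(x)),
              min(y_coords(x)), max(y_coords(x))))
  if (!is.null(x$landmarks))
    cat("  landmarks:", paste(x$landmarks$name, collapse = ", "), "\n")
  invisible(x)
}

#' Transverse voxel-center coordinates in mm
#' @param volume an `octa_volume`.
#' @return numeric vector of x (or y) positions.
#' @export
x_coords <- function(volume) {
  volume$origin[1] + (seq_len(dim(volume)[1]) - 1) * volume$spacing[1] / 1000
}

#' @rdname x_coords
#' @export
y_coords <- function(volume) {
  volume$origin[2] + (seq_len(dim(volume)[2]) - 1) * volume$spacing[2] / 1000
}

#' Look up a landmark position
#' @param volume an `octa_volume`.
#' @param name landmark name, e.g. `"fovea"` or `"disc_edge"`.
#' @return `c(x_mm, y_mm)`.
#' @export
landmark <- function(volume, name) {
  lm <- volume$landmarks
  if (is.null(lm) || !name %in% lm$name) stop("missing landmark: ", name)
  unlist(lm[lm$name == name, c("x_mm", "y_mm")], use.names = FALSE)
}

boundary_names <- c("ILM", "NFL_GCL", "IPL_INL", "INL_OPL", "OPL_ONL", "RPE")

#' Retinal layer boundary model
#'
#' Per-(x, y) depth surfaces for the anatomic boundaries, in fractional
#' voxel units (1-based z index). Boundary order from inner to outer:
#' ILM, NFL/GCL, IPL/INL (outer edge of the ganglion cell complex),
#' INL/OPL, OPL/ONL, RPE.
#'
#' @param surfaces named list of `nx x ny` matrices, one per boundary in
#'   `c("ILM","NFL_GCL","IPL_INL","INL_OPL","OPL_ONL","RPE")`.
#' @param nz axial grid size the surfaces must fit in (optional check).
#' @return an object of class `layer_model`.
#' @export
layer_model <- function(surfaces, nz = NULL) {
  if (!all(boundary_names %in% names(surfaces)))
    stop("surfaces must include: ", paste(boundary_names, collapse = ", "))
  surfaces <- surfaces[boundary_names]
  d <- dim(surfaces[[1]])
  for (s in surfaces) stopifnot(identical(dim(s), d))
  for (k in seq_len(length(surfaces) - 1L)) {
    if (any(surfaces[[k]] > surfaces[[k + 1L]] + 1e-9)) {
      bad <- which(surfaces[[k]] > surfaces[[k + 1L]] + 1e-9, arr.ind = TRUE)[1, ]
      stop(sprintf("layer collision: %s below %s at (x=%d, y=%d)",
                   boundary_names[k], boundary_names[k + 1L], bad[1], bad[2]))
    }
  }
  if (!is.null(nz)) {
    if (min(surfaces$ILM) < 1 || max(surfaces$RPE) > nz)
      stop("layer surfaces fall outside the axial grid")
  }
  structure(list(surfaces = surfaces), class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  rng <- vapply(x$surfaces, function(s) range(s), numeric(2))
  cat("<layer_model> boundary depth ranges (voxels):\n")
  for (nm in colnames(rng))
    cat(sprintf("  %-8s %7.2f .. %7.2f\n", nm, rng[1, nm], rng[2, nm]))
  invisible(x)
}

# mean boundary depths over a set of en-face pixels (linear index)
mean_boundaries <- function(layers, sel = NULL) {
  vapply(layers$surfaces, function(s) {
    if (is.null(sel)) mean(s) else mean(s[sel])
  }, numeric(1))
}
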