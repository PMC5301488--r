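#' Fractional slab specification
#'
#' A named depth band whose inner and outer surfaces are defined as
#' fractional offsets between two named layer boundaries, e.g. the SVP
#' slab's outer limit is 80% of the way from the ILM to the IPL/INL
#' boundary (the "inner 80% of the ganglion cell complex").
#'
#' @param name slab name.
#' @param inner,outer anchors: `list(from, to, frac)` resolving to
#'   `z(from) + frac * (z(to) - z(from))`; `frac = 0` pins the anchor to
#'   `from`.
#' @return an object of class `slab_spec`.
#' @export
slab_spec <- function(name, inner, outer) {
  for (a in list(inner, outer)) {
    stopifnot(all(c("from", "to", "frac") %in% names(a)))
    if (!all(c(a$from, a$to) %in% boundary_names))
      stop("unknown boundary in slab spec: ", a$from, " / ", a$to)
  }
  structure(list(name = name, inner = inner, outer = outer),
            class = "slab_spec")
}

anchor_surface <- function(anchor, layers) {
  s <- layers$surfaces
  s[[anchor$from]] + anchor$frac * (s[[anchor$to]] - s[[anchor$from]])
}

#' Resolve a slab specification to a depth band
#'
#' Linear interpolation between the referenced boundaries at every (x, y).
#' Bands are half-open `[z_in, z_out)` in fractional voxel units; with the
#' voxel-center membership convention this makes the standard plexus set a
#' partition of the inner retina.
#'
#' @param spec a [slab_spec()].
#' @param layers a [layer_model()].
#' @return list with matrices `z_in`, `z_out` and the slab `name`.
#' @export
resolve_slab <- function(spec, layers) {
  z_in <- anchor_surface(spec$inner, layers)
  z_out <- anchor_surface(spec$outer, layers)
  if (any(z_in > z_out + 1e-9)) {
    bad <- which(z_in > z_out + 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("inverted band '%s' at (x=%d, y=%d)", spec$name,
                 bad[1], bad[2]))
  }
  list(name = spec$name, z_in = z_in, z_out = z_out)
}

#' Standard plexus and complex slab definitions
#'
#' The empirical segmentation scheme for the four plexuses and two
#' complexes:
#' * RPCP: ILM to the NFL/GCL interface.
#' * SVP: NFL/GCL to the inner 80% of the GCC (GCC = NFL + GCL + IPL,
#'   i.e. ILM to IPL/INL).
#' * ICP: outer 20% of the GCC to the inner 50% of the INL.
#' * DCP: outer 50% of the INL to the OPL/ONL boundary.
#' * SVC = RPCP + SVP (ILM to inner 80% of GCC); DVC = ICP + DCP (outer
#'   20% of GCC to the OPL); `retina` spans ILM to RPE.
#'
#' @return named list of [slab_spec()] objects.
#' @export
standard_plexus_specs <- function() {
  b <- function(from, frac = 0, to = from) list(from = from, to = to,
                                                frac = frac)
  gcc80 <- b("ILM", 0.8, "IPL_INL")
  inl50 <- b("IPL_INL", 0.5, "INL_OPL")
  list(
    RPCP = slab_spec("RPCP", b("ILM"), b("NFL_GCL")),
    SVP = slab_spec("SVP", b("NFL_GCL"), gcc80),
    ICP = slab_spec("ICP", gcc80, inl50),
    DCP = slab_spec("DCP", inl50, b("OPL_ONL")),
    SVC = slab_spec("SVC", b("ILM"), gcc80),
    DVC = slab_spec("DVC", gcc80, b("OPL_ONL")),
    retina = slab_spec("retina", b("ILM"), b("RPE")))
}

#' Single-voxel inter-plexus slabs
#'
#' One-voxel-thick bands through the capillary-free inter-plexus spaces:
#' one centred mid-way between the SVP slab's outer limit and the IPL/INL
#' boundary (the IPL space between SVP and ICP), one at the INL midpoint
#' (between ICP and DCP).
#'
#' @param layers a [layer_model()].
#' @return named list of two bands, each `list(name, z_in, z_out)` with
#'   `z_out = z_in + 1` everywhere.
#' @export
interplexus_slabs <- function(layers) {
  s <- layers$surfaces
  gcc80 <- s$ILM + 0.8 * (s$IPL_INL - s$ILM)
  ipl_center <- (gcc80 + s$IPL_INL) / 2
  inl_center <- (s$IPL_INL + s$INL_OPL) / 2
  band1 <- list(name = "IPL_space", z_in = ipl_center - 0.5,
                z_out = ipl_center + 0.5)
  band2 <- list(name = "INL_space", z_in = inl_center - 0.5,
                z_out = inl_center + 0.5)
  list(IPL_space = band1, INL_space = band2)
}
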