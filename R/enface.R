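#' En-face maximum flow projection over a slab
#'
#' Per (x, y), the maximum decorrelation over the half-open band
#' `[z_in, z_out)`; a voxel contributes when its center falls in the
#' band. Zero-thickness columns yield 0 and are flagged.
#'
#' @param volume an [octa_volume()].
#' @param band output of [resolve_slab()] (or any list with `z_in`,
#'   `z_out`, `name`).
#' @return object of class `enface_image`: `image` matrix, `modality`
#'   ("flow-max"), `slab`, `spacing`, and `empty` (logical matrix of
#'   empty columns).
#' @export
project_flow_max <- function(volume, band) {
  d <- dim(volume)
  if (max(band$z_out) > d[3] + 1 || min(band$z_in) < 0)
    stop("band outside the grid")
  img <- matrix(0, d[1], d[2])
  any_vox <- matrix(FALSE, d[1], d[2])
  for (z in seq_len(d[3])) {
    w <- z >= band$z_in & z < band$z_out
    if (!any(w)) next
    any_vox <- any_vox | w
    sl <- volume$decorrelation[, , z]
    sl[!w] <- 0
    img <- pmax(img, sl)
  }
  structure(list(image = img, modality = "flow-max",
                 slab = band$name %||% "band",
                 spacing = volume$spacing[1:2], empty = !any_vox),
            class = "enface_image")
}

#' En-face mean reflectance over a slab
#'
#' Per-column average of the reflectance over the band with
#' partial-voxel weighting at the fractional band edges (a voxel
#' occupying `[z - 0.5, z + 0.5)` contributes the overlapped fraction).
#' Zero-thickness columns are NA and flagged.
#'
#' @inheritParams project_flow_max
#' @return an `enface_image` with modality "reflectance-mean".
#' @export
project_reflectance_mean <- function(volume, band) {
  d <- dim(volume)
  acc <- matrix(0, d[1], d[2]); wt <- matrix(0, d[1], d[2])
  for (z in seq_len(d[3])) {
    w <- pmax(0, pmin(z + 0.5, band$z_out) - pmax(z - 0.5, band$z_in))
    if (!any(w > 0)) next
    acc <- acc + w * volume$reflectance[, , z]
    wt <- wt + w
  }
  img <- acc / wt
  img[wt == 0] <- NA_real_
  structure(list(image = img, modality = "reflectance-mean",
                 slab = band$name %||% "band",
                 spacing = volume$spacing[1:2], empty = wt == 0),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %s of slab '%s', %d x %d px\n", x$modality,
              x$slab, nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' Color-composite cross-sectional overlay
#'
#' Grayscale reflectance with suprathreshold flow overlaid, colored by
#' retinal vs choroidal membership (the RPE surface as the divider):
#' retinal flow purple, choroidal flow red.
#'
#' @param volume an [octa_volume()] (PR-resolved for a clean overlay).
#' @param layers a [layer_model()] supplying the RPE surface.
#' @param y_index B-scan index along y.
#' @param flow_threshold decorrelation cut for the overlay.
#' @return an `nx x nz x 3` RGB array in `[0, 1]` (x horizontal, depth
#'   along the second dimension).
#' @export
composite_cross_section <- function(volume, layers, y_index,
                                    flow_threshold = 0) {
  d <- dim(volume)
  if (y_index < 1 || y_index > d[2]) stop("y_index outside the grid")
  refl <- volume$reflectance[, y_index, ]
  dec <- volume$decorrelation[, y_index, ]
  hi <- stats::quantile(refl, 0.99)
  g <- clamp(refl / max(hi, .Machine$double.eps), 0, 1)
  rgb <- array(rep(g, 3), c(d[1], d[3], 3))
  rpe <- layers$surfaces$RPE[, y_index]
  zmat <- matrix(seq_len(d[3]), d[1], d[3], byrow = TRUE)
  flow <- dec > flow_threshold
  retinal <- flow & zmat < rpe
  choroidal <- flow & zmat >= rpe
  # purple overlay for retina, red for choroid
  r1 <- rgb[, , 1]; g1 <- rgb[, , 2]; b1 <- rgb[, , 3]
  r1[retinal] <- 0.63; g1[retinal] <- 0.13; b1[retinal] <- 0.94
  r1[choroidal] <- 0.9; g1[choroidal] <- 0.1; b1[choroidal] <- 0.1
  rgb[, , 1] <- r1; rgb[, , 2] <- g1; rgb[, , 3] <- b1
  rgb
}
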