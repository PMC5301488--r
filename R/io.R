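#' Persist a volume (and optional truth) as a single-file container
#'
#' Serializes the paired grids, spacing, landmarks, optional ground truth
#' and a provenance block (package version, config hash and seed when
#' present in the volume's metadata) into one file. Writing is
#' deterministic byte-for-byte for identical inputs, and a write/read
#' round trip reproduces the grids bit-exactly.
#'
#' @param volume an [octa_volume()].
#' @param path destination file (conventionally `.octa.rds`).
#' @param truth optional `phantom_truth` stored alongside.
#' @param overwrite allow clobbering an existing file.
#' @return `path`, invisibly.
#' @export
write_container <- function(volume, path, truth = NULL, overwrite = FALSE) {
  stopifnot(inherits(volume, "octa_volume"))
  if (file.exists(path) && !overwrite)
    stop("file exists (use overwrite = TRUE): ", path)
  obj <- list(format = "octapr-container", container_version = 1L,
              volume = volume, truth = truth,
              provenance = list(
                package_version = as.character(utils::packageVersion("octapr")),
                seed = volume$meta$seed %||% NA_integer_,
                config_hash = volume$meta$config_hash %||% NA_character_))
  saveRDS(obj, path, version = 3L, compress = "gzip")
  invisible(path)
}

#' Read a volume container
#'
#' Validates the format tag and the container invariants (matching grid
#' shapes, positive spacing, decorrelation range) and fails with an
#' explicit format error on corrupted or foreign files.
#'
#' @param path file written by [write_container()].
#' @return list with `volume`, `truth` (NULL when absent) and
#'   `provenance`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable octapr container (corrupted or foreign file): ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "octapr-container"))
    stop("not an octapr container: missing format tag")
  v <- obj$volume
  # re-validate invariants through the constructor
  v <- octa_volume(v$reflectance, v$decorrelation, v$spacing, v$origin,
                   v$landmarks, v$meta)
  list(volume = v, truth = obj$truth, provenance = obj$provenance)
}

#' Export a density profile or findings table as delimited text
#'
#' One header row; numeric values at full precision so a reread equals
#' the written table within float formatting. Works for
#' `depth_density_profile`, `transverse_profile`,
#' `cross_section_density_map` (written long: x_mm, z_mm, density) and
#' plain data.frames.
#'
#' @param profile the object to export.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
export_tables <- function(profile, path) {
  df <- if (inherits(profile, "cross_section_density_map")) {
    data.frame(x_mm = rep(attr(profile, "x_mm"), times = ncol(profile)),
               z_mm = rep(attr(profile, "z_mm"), each = nrow(profile)),
               density = as.vector(unclass(profile)))
  } else {
    as.data.frame(profile)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write an en-face image (or list of them) as TIFF
#'
#' Flow images are mapped linearly from decorrelation `[0, 0.6]` to
#' `[0, 1]` for display (display only; no quantitative path uses this
#' scaling); reflectance images are scaled by their 99th percentile.
#' Multiple images become a multi-page TIFF.
#'
#' @param images an `enface_image` or list of them.
#' @param path destination TIFF.
#' @return `path`, invisibly.
#' @export
write_enface_tiff <- function(images, path) {
  if (inherits(images, "enface_image")) images <- list(images)
  pages <- lapply(images, function(ef) {
    img <- ef$image
    img[is.na(img)] <- 0
    if (identical(ef$modality, "flow-max")) {
      img <- clamp(img / 0.6, 0, 1)
    } else {
      hi <- stats::quantile(img, 0.99, na.rm = TRUE)
      img <- clamp(img / max(hi, .Machine$double.eps), 0, 1)
    }
    t(img)[, , drop = TRUE]   # TIFF rows = y
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an RGB array as PNG
#' @param rgb array `nx x nz x 3` (or any width x height x 3) in `[0,1]`.
#' @param path destination PNG.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(aperm(rgb, c(2, 1, 3)), path)
  invisible(path)
}
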