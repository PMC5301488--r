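# shared fixtures: phantoms are generated in code, cached per session

phantom_cache <- new.env(parent = emptyenv())

# the default wide-field study phantom taken through the whole pipeline
default_study <- function(seed = 1L) {
  key <- paste0("wf", seed)
  if (is.null(phantom_cache[[key]])) {
    cfg <- phantom_config("widefield", seed = seed)
    sim <- simulate_phantom(cfg)
    pr <- pr_resolve(sim$volume, sim$truth$layer_model, multiplier = 3)
    fl <- flatten_to_rpe(pr$volume, sim$truth$layer_model)
    nd <- normalize_depth(fl$volume, fl$layers, fl$layers)
    svp_band <- resolve_slab(standard_plexus_specs()$SVP, nd$layers)
    lvm <- build_large_vessel_mask(project_flow_max(nd$volume, svp_band)$image)
    phantom_cache[[key]] <- list(config = cfg, sim = sim, pr = pr,
                                 vol = nd$volume, layers = nd$layers,
                                 mask = lvm, shift = fl$shift)
  }
  phantom_cache[[key]]
}

study_window <- c(0.4, 0.8)
study_prominence <- 0.05

region_findings <- function(st, center, region,
                            window = study_window,
                            min_prominence = study_prominence) {
  prof <- depth_density_profile(st$vol, center, region, mask = st$mask,
                                window = window)
  assign_plexus_labels(find_peaks_troughs(prof, min_prominence),
                       st$layers, region = region, center = center,
                       volume = st$vol)
}

# ground-truth sheet depth (after flattening shifts) inside a window
truth_depth <- function(st, plexus, center, window = study_window) {
  w <- octapr:::window_columns(st$vol, center, window)
  sh <- st$sim$truth$sheets[[plexus]]
  z <- (sh$z + st$shift)[w$ix, w$iy]
  sel <- sh$mask[w$ix, w$iy]
  stats::median(z[sel])
}

# a flat phantom config on a custom (small) grid, fovea-centred
flat_cfg <- function(nx = 60, ny = 60, nz = 160, seed = 1L, ...) {
  phantom_config("flat", seed = seed, grid_shape = c(nx, ny, nz),
                 origin_mm = -c(nx - 1, ny - 1) * 0.015 / 2, ...)
}

# hand-built octa_volume from a decorrelation array (uniform reflectance)
make_volume <- function(decorr, refl = NULL, spacing = c(100, 100, 10)) {
  if (is.null(refl)) refl <- array(1, dim(decorr))
  octa_volume(refl, decorr, spacing,
              origin = c(0, 0),
              landmarks = data.frame(name = c("fovea", "disc_center",
                                              "disc_edge"),
                                     x_mm = c(0, -4, -3.25), y_mm = 0))
}

# minimal ground truth for custom render experiments
make_truth <- function(cfg, in_situ_idx) {
  layers <- generate_layer_model(cfg)
  arr <- array(FALSE, cfg$grid_shape)
  arr[in_situ_idx] <- TRUE
  structure(list(in_situ_flow = arr,
                 large_vessel = array(FALSE, cfg$grid_shape),
                 plexus_label = array(0L, cfg$grid_shape),
                 artifact_flow = NULL, layer_model = layers,
                 sheets = list(), fractions = NULL, seed = cfg$seed),
            class = "phantom_truth")
}

# two smoothed blobs whose suprathreshold component has an exactly
# chosen pixel count: scale a fixed two-delta response so that the n-th
# largest smoothed value straddles the 0.12 cut
blob_image <- function(n_px, nr = 81, nc = 81) {
  base <- matrix(0, nr, nc)
  base[38, 41] <- 1
  base[44, 43] <- 0.83          # asymmetric pair: no tied smoothed values
  sm <- EBImage::filter2(base, gaussian_kernel(20, 5), boundary = 0)
  v <- sort(as.vector(sm), decreasing = TRUE)
  base * (0.12 * 2 / (v[n_px] + v[n_px + 1]))
}

# independent brute-force oracle for the projection-resolution rule:
# for every voxel, explicitly scan ALL shallower voxels of its axial line
pr_oracle_keep <- function(dbar, theta) {
  d <- dim(dbar)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- dbar[i, j, ]
    for (z in seq_len(d[3])) {
      m <- if (z == 1L) -Inf else max(v[1:(z - 1L)])
      out[i, j, z] <- v[z] >= theta && v[z] > m
    }
  }
  out
}

# retained normalized values strictly increase with depth in every A-scan
all_scans_strictly_increasing <- function(dbar, resolved) {
  d <- dim(dbar)
  db <- matrix(dbar, d[1] * d[2], d[3])
  kp <- matrix(resolved > 0, d[1] * d[2], d[3])
  ok <- vapply(seq_len(nrow(db)), function(i) {
    v <- db[i, kp[i, ]]
    length(v) < 2 || all(diff(v) > 0)
  }, logical(1))
  all(ok)
}
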