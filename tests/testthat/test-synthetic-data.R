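test_that("flat config yields planar surfaces at cumulative thicknesses", {
  cfg <- flat_cfg(nx = 30, ny = 20)
  lay <- generate_layer_model(cfg)
  dz <- cfg$voxel_spacing[3]
  lp <- cfg$layer_params
  expected <- cumsum(c(lp$vitreous_offset, lp$nfl, lp$gcl_ipl, lp$inl,
                       lp$opl, lp$outer)) / dz + 1
  names(expected) <- c("ILM", "NFL_GCL", "IPL_INL", "INL_OPL", "OPL_ONL",
                       "RPE")
  for (nm in names(expected)) {
    expect_equal(max(lay$surfaces[[nm]]) - min(lay$surfaces[[nm]]), 0)
    expect_equal(lay$surfaces[[nm]][1, 1], expected[[nm]])
  }
})

test_that("boundary surfaces are ordered inner to outer for every preset", {
  for (p in c("widefield", "macula", "flat")) {
    lay <- generate_layer_model(phantom_config(p, seed = 2))
    s <- lay$surfaces
    for (k in seq_len(5)) {
      expect_true(all(s[[k]] <= s[[k + 1]] + 1e-9),
                  info = paste(p, names(s)[k]))
    }
  }
})

test_that("a 100 um pit thins the GCC at the fovea by >= 50 um vs 1.5 mm", {
  cfg <- phantom_config("macula", seed = 1,
                        layer_params = list(pit_depth = 100))
  lay <- generate_layer_model(cfg)
  gcc <- gcc_thickness(lay, cfg$voxel_spacing[3])
  xs <- octapr:::config_x_mm(cfg)
  ys <- octapr:::config_y_mm(cfg)
  i0 <- which.min(abs(xs)); j0 <- which.min(abs(ys))
  # 1.5 mm eccentricity is outside the macular grid along x; evaluate the
  # generator's own thickness formula directly at both radii
  lp <- cfg$layer_params
  pit <- function(r) 1 - (lp$pit_depth / (lp$nfl + lp$gcl_ipl + lp$inl +
                                            lp$opl)) *
    exp(-r^2 / (2 * lp$pit_sigma^2))
  expected_drop <- (lp$nfl + lp$gcl_ipl) * (pit(1.5) - pit(0))
  expect_gte(expected_drop, 50)
  # and the rendered field matches the formula at the fovea
  # i0/j0 are the nearest grid columns to the fovea (within half a voxel)
  expect_equal(gcc[i0, j0], (lp$nfl + lp$gcl_ipl) * pit(0), tolerance = 0.005)
})

test_that("impossible pit depth is rejected as a layer collision", {
  expect_error(phantom_config("macula", layer_params = list(pit_depth = 250)),
               "collision")
})

test_that("no retinal flow inside the foveal avascular zone", {
  st <- default_study()
  tr <- st$sim$truth
  cfg <- st$config
  x <- octapr:::config_x_mm(cfg); y <- octapr:::config_y_mm(cfg)
  r <- sqrt(outer((x - cfg$fovea_center[1])^2,
                  (y - cfg$fovea_center[2])^2, "+"))
  inside <- which(r < cfg$faz_radius)
  sf <- tr$layer_model$surfaces
  d <- dim(tr$in_situ_flow)
  nxy <- d[1] * d[2]
  idx <- which(tr$in_situ_flow)
  z <- (idx - 1L) %/% nxy + 1L
  pix <- (idx - 1L) %% nxy + 1L
  retinal <- z >= sf$ILM[pix] & z < sf$OPL_ONL[pix]
  expect_equal(sum(retinal & pix %in% inside), 0)
})

test_that("ICP/DCP centerline separation hits zero at the merge locus", {
  st <- default_study()
  tr <- st$sim$truth
  cfg <- st$config
  x <- octapr:::config_x_mm(cfg); y <- octapr:::config_y_mm(cfg)
  i7 <- which.min(abs(x - 7)); j0 <- which.min(abs(y))
  sep <- tr$sheets$dcp$z_cont - tr$sheets$icp$z_cont
  expect_equal(sep[i7, j0], 0)        # 7 mm > merge_eccentricity 6.5
  i3 <- which.min(abs(x - 3))
  s0 <- tr$layer_model$surfaces$INL_OPL[i3, j0] -
    tr$layer_model$surfaces$IPL_INL[i3, j0]
  expect_equal(sep[i3, j0], s0 * (1 - 3 / cfg$merge_eccentricity),
               tolerance = 0.02)      # linear ramp
})

test_that("achieved capillary area fractions stay within 10% of target", {
  for (s in 1:5) {
    tr <- generate_vasculature(flat_cfg(seed = s),
                               generate_layer_model(flat_cfg(seed = s)))
    dev <- abs(tr$fractions$achieved / tr$fractions$target - 1)
    expect_true(all(dev[!is.na(dev)] <= 0.10), info = paste("seed", s))
  }
})

test_that("a 0.20 SVP target yields ~0.20 en-face GCL-band flow fraction", {
  cfg <- phantom_config("flat", seed = 11,
                        plexus_params = list(svp = list(fraction = 0.20)))
  sim <- simulate_phantom(cfg)
  tr <- sim$truth
  sf <- tr$layer_model$surfaces
  d <- dim(tr$in_situ_flow)
  ef <- matrix(FALSE, d[1], d[2])
  for (z in seq_len(d[3])) {
    w <- z >= sf$NFL_GCL & z < sf$ILM + 0.8 * (sf$IPL_INL - sf$ILM)
    ef <- ef | (tr$in_situ_flow[, , z] & w)
  }
  expect_gte(mean(ef), 0.18)
  expect_lte(mean(ef), 0.22)
})

test_that("unreachable area fractions error rather than silently clip", {
  # at 30 um sampling a 0.9 fraction of 15 um capillaries needs lobules
  # below the grid resolution
  cfg <- phantom_config("widefield", seed = 1)
  cfg$plexus_params$svp$fraction <- 0.9
  expect_error(generate_vasculature(cfg, generate_layer_model(cfg)),
               "unreachable")
})

test_that("identical config and seed give bit-identical phantom output", {
  cfg <- flat_cfg(nx = 50, ny = 40, seed = 99)
  a <- simulate_phantom(cfg)
  b <- simulate_phantom(cfg)
  expect_identical(a$volume$decorrelation, b$volume$decorrelation)
  expect_identical(a$volume$reflectance, b$volume$reflectance)
  expect_identical(a$truth$plexus_label, b$truth$plexus_label)
  expect_identical(a$truth$artifact_flow, b$truth$artifact_flow)
})

test_that("plexus labels respect their host bands; flows are disjoint", {
  for (p in c("widefield", "flat")) {
    sim <- if (p == "widefield") default_study()$sim else
      simulate_phantom(flat_cfg(seed = 4))
    expect_true(check_truth(sim$truth))
    expect_equal(sum(sim$truth$in_situ_flow & sim$truth$artifact_flow), 0)
  }
})

test_that("a single flow voxel casts an exponential tail under uniform reflectance", {
  lv <- as.list(rep(1.0, 8))
  names(lv) <- c("vitreous", "nfl", "gcl_ipl", "inl", "opl", "outer",
                 "rpe", "choroid")
  cfg <- flat_cfg(nx = 12, ny = 6, seed = 5,
                  noise_params = list(speckle = 0, decorr_sd = 0),
                  reflectance_levels = lv,
                  choriocapillaris = list(enabled = FALSE),
                  tail_params = list(alpha = 0.8, gate = 0.15))
  z0 <- 60L
  tru <- make_truth(cfg, cbind(5L, 3L, z0))
  out <- render_volume(cfg, tru)
  D <- out$volume$decorrelation
  src <- D[5, 3, z0]
  expect_gt(src, 0)
  dz_mm <- cfg$voxel_spacing[3] / 1000
  for (gap in c(1L, 10L, 40L)) {
    expect_equal(D[5, 3, z0 + gap], src * 0.8^(gap * dz_mm),
                 tolerance = 1e-12)
  }
  # tail-only voxels are recorded and disjoint from in-situ flow
  expect_true(out$truth$artifact_flow[5, 3, z0 + 10])
  expect_false(out$truth$artifact_flow[5, 3, z0])
  # with alpha = 0 the tail vanishes: flow only at the in-situ voxel
  cfg0 <- flat_cfg(nx = 12, ny = 6, seed = 5,
                   noise_params = list(speckle = 0, decorr_sd = 0),
                   reflectance_levels = lv,
                   choriocapillaris = list(enabled = FALSE),
                   tail_params = list(alpha = 0, gate = 0.15))
  out0 <- render_volume(cfg0, make_truth(cfg0, cbind(5L, 3L, z0)))
  expect_equal(which(out0$volume$decorrelation > 0),
               which(out0$truth$in_situ_flow))
})

test_that("noise-free tails are strictly subordinate to their source", {
  cfg <- flat_cfg(nx = 40, ny = 30, seed = 6,
                  noise_params = list(speckle = 0, decorr_sd = 0))
  sim <- simulate_phantom(cfg)
  nf <- normalize_decorrelation(sim$volume, sim$truth$layer_model)
  db <- nf$dbar
  d <- dim(db); nxy <- d[1] * d[2]
  idx <- which(sim$truth$artifact_flow & sim$volume$decorrelation > 0)
  idx <- idx[seq(1, length(idx), length.out = min(5000, length(idx)))]
  for (k in idx) {
    z <- (k - 1L) %/% nxy + 1L
    pix <- (k - 1L) %% nxy + 1L
    i <- (pix - 1L) %% d[1] + 1L; j <- (pix - 1L) %/% d[1] + 1L
    shallower <- db[i, j, seq_len(z - 1L)]
    expect_lt(db[i, j, z], max(shallower))
  }
})
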