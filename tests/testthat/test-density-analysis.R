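test_that("component size filtering is exact at the 50-pixel rule", {
  img50 <- blob_image(50)
  m50 <- build_large_vessel_mask(img50)
  expect_equal(sum(m50$mask), 0)              # size 50 removed
  img51 <- blob_image(51)
  m51 <- build_large_vessel_mask(img51)
  expect_equal(sum(m51$mask), 51)             # size 51 retained
  # all-background image yields an empty, valid mask
  expect_equal(sum(build_large_vessel_mask(matrix(0.05, 40, 40))$mask), 0)
})

test_that("no final mask component has 50 pixels or fewer", {
  st <- default_study()
  lab <- label_components8(st$mask$mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    expect_true(all(sizes > 50))
  }
  # the mask covers the generated large-vessel trees
  trees <- st$sim$truth$sheets$trees$mask
  expect_gte(sum(st$mask$mask & trees) / sum(trees), 0.9)
})

test_that("8-connected labeling joins diagonals that 4-connectivity splits", {
  m <- matrix(0L, 5, 5)
  m[cbind(1:4, 1:4)] <- 1L
  lab <- label_components8(m)
  expect_equal(max(lab), 1L)
  m[1, 5] <- 1L                              # isolated pixel
  expect_equal(max(label_components8(m)), 2L)
})

test_that("depth densities are flow-pixel ratios with absent-plane flagging", {
  D <- array(0, c(40, 20, 6))
  D[seq_len(80) * 10 - 9] <- 0.5             # 80 flow pixels in plane 1
  vol <- make_volume(D)                       # 800-column window
  prof <- depth_density_profile(vol, c(1.95, 0.95), window = c(3.9, 1.9))
  expect_equal(prof$density[1], 80 / 800)
  expect_equal(prof$n[1], 800)
  # fully masked window: every plane flagged absent, not zero
  fullmask <- structure(list(mask = matrix(TRUE, 40, 20)),
                        class = "large_vessel_mask")
  prof2 <- depth_density_profile(vol, c(1.95, 0.95), mask = fullmask,
                                 window = c(3.9, 1.9))
  expect_true(all(is.na(prof2$density)))
  # window escaping the grid errors
  expect_error(depth_density_profile(vol, c(3.9, 0.95), window = c(3.9, 1.9)),
               "outside the grid")
})

test_that("adding flow voxels never lowers a window's density", {
  set.seed(5)
  D <- array(rbinom(40 * 20 * 6, 1, 0.1) * 0.4, c(40, 20, 6))
  vol <- make_volume(D)
  d0 <- depth_density_profile(vol, c(1.95, 0.95), window = c(3.9, 1.9))
  D2 <- D
  zero <- which(D2 == 0)
  D2[sample(zero, 200)] <- 0.4
  d1 <- depth_density_profile(make_volume(D2), c(1.95, 0.95),
                              window = c(3.9, 1.9))
  expect_true(all(d1$density >= d0$density))
})

test_that("cross-section super-voxel map recovers uniform and zero flow", {
  expect_true(all(cross_section_density_map(
    make_volume(array(0, c(60, 54, 40)), spacing = c(15, 15, 3.1))) == 0))
  set.seed(9)
  D <- array(rbinom(120 * 54 * 96, 1, 0.1) * 0.5, c(120, 54, 96))
  m <- cross_section_density_map(make_volume(D, spacing = c(15, 15, 3.1)))
  expect_equal(mean(m), 0.1, tolerance = 0.01)
  # interior super-voxels (edge bins hold fewer voxels) within 5 binomial
  # SDs of p = 0.1 at the minimum interior occupancy (6 x 54 x 3 voxels)
  interior <- m[-nrow(m), -ncol(m)]
  expect_true(all(abs(interior - 0.1) < 5 * sqrt(0.1 * 0.9 / (6 * 54 * 3))))
})

test_that("the cross-section map shows three macular bands merging to two", {
  st <- default_study()
  m <- cross_section_density_map(st$vol)
  xmm <- attr(m, "x_mm"); zmm <- attr(m, "z_mm")
  count_bands <- function(x0) {
    i0 <- which.min(abs(xmm - x0))
    col <- colMeans(m[(i0 - 1):(i0 + 1), ])  # 0.3 mm of super-voxel columns
    inner <- zmm > 0.10 & zmm < 0.28         # inner retina depth range
    sum(rle(col[inner] > 0.07)$values)
  }
  expect_equal(count_bands(1.5), 3)
  expect_equal(count_bands(7.5), 2)
})

test_that("transverse profiles hit the degenerate cases exactly", {
  D <- array(0, c(60, 50, 20))
  D[, , 10] <- 0.5                           # a solid flow plane
  vol <- make_volume(D, spacing = c(50, 50, 10))
  lay <- layer_model(lapply(
    list(ILM = 2, NFL_GCL = 4, IPL_INL = 6, INL_OPL = 8, OPL_ONL = 9,
         RPE = 15), function(v) matrix(v, 60, 50)))
  specs <- list(slab_spec("avascular", list(from = "ILM", to = "ILM", frac = 0),
                          list(from = "NFL_GCL", to = "NFL_GCL", frac = 0)),
                slab_spec("vessel", list(from = "OPL_ONL", to = "OPL_ONL",
                                         frac = 0),
                          list(from = "RPE", to = "RPE", frac = 0)))
  tp <- transverse_density_profile(vol, lay, specs)
  expect_true(all(tp$density[tp$plexus == "avascular"] == 0))
  expect_true(all(tp$density[tp$plexus == "vessel"] == 1))
})

test_that("phantom RPCP density decays monotonically from the disc edge", {
  st <- default_study()
  tp <- transverse_density_profile(st$vol, st$layers, step = 0.1)
  rp <- tp[tp$plexus == "RPCP", ]
  ext <- st$config$plexus_params$rpcp$extent_mm - st$config$disc_radius
  rp <- rp[rp$ecc_mm >= 0.1 & rp$ecc_mm <= ext - 0.1, ]
  rho <- suppressWarnings(cor(rp$ecc_mm, rp$density, method = "spearman"))
  expect_lt(rho, -0.9)
})

test_that("coefficient of variation matches its closed form", {
  expect_equal(repeatability_cov(c(0.3, 0.3, 0.3)), 0)
  expect_equal(repeatability_cov(c(0.2, 0.3)), 100 * sd(c(0.2, 0.3)) / 0.25)
  expect_equal(repeatability_cov(c(0.2, 0.3)), 28.2842712, tolerance = 1e-7)
  expect_equal(repeatability_cov(3 * c(0.21, 0.25, 0.19)),
               repeatability_cov(c(0.21, 0.25, 0.19)))
  expect_error(repeatability_cov(0.3), "at least 2")
})
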