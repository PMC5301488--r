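test_that("normalization is the identity when reflectance equals the reference", {
  set.seed(1)
  D <- array(runif(4 * 3 * 10), c(4, 3, 10))
  vol <- make_volume(D)                      # R == 1 everywhere
  nf <- normalize_decorrelation(vol, r_ref = 1)
  expect_equal(nf$dbar, D)
  # D = 0 stays 0 under any reflectance
  R2 <- array(runif(length(D), 0.5, 2), dim(D))
  vol2 <- make_volume(array(0, dim(D)), refl = R2)
  expect_true(all(normalize_decorrelation(vol2, r_ref = 1)$dbar == 0))
})

test_that("halving reflectance above the floor doubles normalized flow", {
  D <- array(0.4, c(2, 2, 4))
  R <- array(2, dim(D))
  R[1, 1, 1] <- 1                            # still above floor (eps*r_ref)
  nf <- normalize_decorrelation(make_volume(D, refl = R), r_ref = 1,
                                eps = 0.25)
  expect_equal(nf$dbar[1, 1, 1], 2 * nf$dbar[2, 2, 1])
})

test_that("all-zero reflectance is rejected", {
  vol <- suppressWarnings(make_volume(array(0.1, c(2, 2, 4)),
                                      refl = array(0, c(2, 2, 4))))
  expect_error(normalize_decorrelation(vol), "zero reflectance")
})

test_that("noise threshold reduces to region mean and value for degenerate inputs", {
  D <- array(0, c(10, 10, 10))
  reg <- array(TRUE, dim(D))
  nf <- normalize_decorrelation(make_volume(D + 0.07), r_ref = 1)
  expect_equal(estimate_noise_threshold(nf, reg), 0.07)       # SD = 0
  set.seed(2)
  nf2 <- normalize_decorrelation(make_volume(array(runif(1000, 0, 0.2),
                                                   c(10, 10, 10))), r_ref = 1)
  expect_equal(estimate_noise_threshold(nf2, reg, multiplier = 0),
               mean(nf2$dbar))
  reg_small <- array(FALSE, dim(D)); reg_small[1:99] <- TRUE
  expect_error(estimate_noise_threshold(nf2, reg_small), "too small")
})

test_that("mean + 2.33 SD cuts ~1% of Gaussian noise voxels", {
  set.seed(7)
  n <- 2e5
  D <- array(abs(rnorm(n, 0.3, 0.04)), c(200, 100, 10)) # positive Gaussian body
  D <- pmin(D, 1)
  vol <- make_volume(D)
  nf <- normalize_decorrelation(vol, r_ref = 1)
  reg <- array(TRUE, dim(D))
  theta <- estimate_noise_threshold(nf, reg)   # 2.33 default
  fp <- mean(nf$dbar > theta)
  expect_gte(fp, 0.007)
  expect_lte(fp, 0.013)
})

test_that("the retention rule matches hand-worked axial scans", {
  # suprathreshold and higher than ALL shallower voxels; ties are artifact
  scan <- c(0.30, 0.20, 0.40, 0.35)
  vol <- make_volume(array(scan, c(1, 1, 4)))
  nf <- set_threshold(normalize_decorrelation(vol, r_ref = 1), 0.10)
  out <- resolve_projection(nf, vol)
  expect_equal(as.vector(out$decorrelation), c(0.30, 0, 0.40, 0))

  dec <- c(0.5, 0.45, 0.4, 0.3, 0.2)          # monotonically decreasing
  vol2 <- make_volume(array(dec, c(1, 1, 5)))
  nf2 <- set_threshold(normalize_decorrelation(vol2, r_ref = 1), 0.10)
  expect_equal(as.vector(resolve_projection(nf2, vol2)$decorrelation),
               c(0.5, 0, 0, 0, 0))

  tie <- c(0.3, 0.3, 0.31)                     # equality = artifact
  vol3 <- make_volume(array(tie, c(1, 1, 3)))
  nf3 <- set_threshold(normalize_decorrelation(vol3, r_ref = 1), 0.10)
  expect_equal(as.vector(resolve_projection(nf3, vol3)$decorrelation),
               c(0.3, 0, 0.31))
})

test_that("resolution agrees exactly with the brute-force oracle", {
  # many short axial scans
  set.seed(11)
  d1 <- c(250, 200, 24)                        # 5e4 A-scans
  D1 <- array(runif(prod(d1)), d1)
  vol1 <- make_volume(D1)
  nf1 <- set_threshold(normalize_decorrelation(vol1, r_ref = 1), 0.3)
  out1 <- resolve_projection(nf1, vol1)
  keep1 <- pr_oracle_keep(nf1$dbar, 0.3)
  expect_identical(out1$decorrelation > 0, keep1)
  expect_equal(out1$decorrelation, D1 * keep1)

  # a deep volume with reflectance-modulated normalization
  set.seed(12)
  d2 <- c(40, 40, 128)
  D2 <- array(runif(prod(d2)), d2)
  R2 <- array(runif(prod(d2), 0.4, 2), d2)
  vol2 <- make_volume(D2, refl = R2)
  nf2 <- set_threshold(normalize_decorrelation(vol2, r_ref = 1), 0.5)
  out2 <- resolve_projection(nf2, vol2)
  keep2 <- pr_oracle_keep(nf2$dbar, 0.5)
  expect_identical(out2$decorrelation > 0, keep2)
  expect_equal(out2$decorrelation, D2 * keep2)
})

test_that("output is subordinate, suprathreshold-supported and idempotent", {
  st <- default_study()
  vol <- st$sim$volume
  nfw <- st$pr$normflow
  res <- st$pr$volume
  expect_true(all(res$decorrelation <= vol$decorrelation))
  expect_true(all(nfw$dbar[res$decorrelation > 0] >= nfw$theta))
  # fixed point: resolving the resolved volume changes nothing
  nf2 <- set_threshold(normalize_decorrelation(res, r_ref = nfw$r_ref,
                                               eps = nfw$eps), nfw$theta)
  res2 <- resolve_projection(nf2, res)
  expect_identical(res2$decorrelation, res$decorrelation)
})

test_that("retained normalized values strictly increase with depth everywhere", {
  st <- default_study()
  expect_true(all_scans_strictly_increasing(st$pr$normflow$dbar,
                                            st$pr$volume$decorrelation))
})

test_that("noise-free phantom: all artifacts removed; ordered sources all kept", {
  cfg <- phantom_config("widefield", seed = 21,
                        noise_params = list(speckle = 0, decorr_sd = 0),
                        tail_params = list(alpha = 0.8, gate = 0.15))
  sim <- simulate_phantom(cfg)
  pr <- pr_resolve(sim$volume, sim$truth$layer_model, theta = 0.05)
  art <- sim$truth$artifact_flow
  expect_equal(sum(pr$volume$decorrelation > 0 & art), 0)

  cfg_inc <- phantom_config("widefield", seed = 21,
                            noise_params = list(speckle = 0, decorr_sd = 0),
                            flow_params = list(mode = "increasing"))
  sim2 <- simulate_phantom(cfg_inc)
  pr2 <- pr_resolve(sim2$volume, sim2$truth$layer_model, theta = 0.05)
  ins <- sim2$truth$in_situ_flow
  expect_equal(sum(pr2$volume$decorrelation > 0 & ins), sum(ins))
})
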