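tilted_volume <- function(nx = 20, ny = 4, nz = 60, tilt = 10) {
  D <- array(0, c(nx, ny, nz)); R <- array(0.5, c(nx, ny, nz))
  shift_per_col <- round(seq(0, tilt, length.out = nx))
  surf <- function(base) {
    matrix(rep(base + shift_per_col, ny), nx, ny)
  }
  lay <- layer_model(list(ILM = surf(10), NFL_GCL = surf(14),
                          IPL_INL = surf(24), INL_OPL = surf(30),
                          OPL_ONL = surf(34), RPE = surf(50)), nz = nz)
  for (i in seq_len(nx)) D[i, , 20 + shift_per_col[i]] <- 0.5
  list(volume = make_volume(D, refl = R, spacing = c(15, 15, 3.1)),
       layers = lay, shift_per_col = shift_per_col)
}

test_that("flattening makes the RPE constant and is the identity when flat", {
  tv <- tilted_volume(tilt = 0)
  fl <- flatten_to_rpe(tv$volume, tv$layers)
  expect_identical(fl$volume$decorrelation, tv$volume$decorrelation)
  expect_equal(max(fl$layers$surfaces$RPE) - min(fl$layers$surfaces$RPE), 0)
})

test_that("a tilted RPE is leveled with per-column integer shifts", {
  tv <- tilted_volume(tilt = 10)
  fl <- flatten_to_rpe(tv$volume, tv$layers)
  expect_equal(max(fl$layers$surfaces$RPE) - min(fl$layers$surfaces$RPE), 0)
  # flow markers moved by exactly the per-column offsets
  expected_shift <- max(50 + tv$shift_per_col) - (50 + tv$shift_per_col)
  for (i in c(1, 7, 20)) {
    z <- which(fl$volume$decorrelation[i, 1, ] > 0)
    expect_equal(z, 20 + tv$shift_per_col[i] + expected_shift[i])
  }
  # idempotence
  fl2 <- flatten_to_rpe(fl$volume, fl$layers)
  expect_identical(fl2$volume$decorrelation, fl$volume$decorrelation)
})

# noise-free, projection-resolved phantoms: flow is the sparse set of
# in-situ capillary sheets, the regime depth normalization is built for
two_layer_phantoms <- function() {
  quiet <- list(speckle = 0, decorr_sd = 0)
  a <- flat_cfg(nx = 60, ny = 60, seed = 31, noise_params = quiet)
  b <- flat_cfg(nx = 60, ny = 60, seed = 31, noise_params = quiet,
                layer_params = list(inl = 60.2, gcl_ipl = 80.6))
  sim_a <- simulate_phantom(a); sim_b <- simulate_phantom(b)
  list(a = sim_a, b = sim_b,
       ra = pr_resolve(sim_a$volume, sim_a$truth$layer_model,
                       theta = 0.05)$volume,
       rb = pr_resolve(sim_b$volume, sim_b$truth$layer_model,
                       theta = 0.05)$volume)
}

test_that("depth normalization is the identity against itself and aligns phantoms", {
  ph <- two_layer_phantoms()
  lay_a <- ph$a$truth$layer_model
  nd <- normalize_depth(ph$ra, lay_a, lay_a)
  expect_identical(nd$volume$decorrelation > 0,
                   ph$ra$decorrelation > 0)        # flow exact
  expect_equal(nd$volume$reflectance, ph$ra$reflectance,
               tolerance = 1e-12)

  # phantoms differing only in layer thicknesses align after normalization
  lay_b <- ph$b$truth$layer_model
  nb <- normalize_depth(ph$rb, lay_b, lay_a)
  prof_a <- depth_density_profile(ph$ra, c(0, 0), "a", window = c(0.6, 0.6))
  prof_b <- depth_density_profile(nb$volume, c(0, 0), "b",
                                  window = c(0.6, 0.6))
  pa <- find_peaks_troughs(prof_a, 0.05)$peaks
  pb <- find_peaks_troughs(prof_b, 0.05)$peaks
  sf <- lay_a$surfaces
  inner <- function(p) p[p$z >= sf$ILM[1, 1] & p$z < sf$OPL_ONL[1, 1], ]
  pa <- inner(pa); pb <- inner(pb)
  expect_equal(nrow(pa), 3)
  expect_equal(nrow(pb), 3)
  expect_true(all(abs(pa$z - pb$z) <= 1))
})

test_that("flow mass is approximately conserved across thickness rescaling", {
  ph <- two_layer_phantoms()
  lay_a <- ph$a$truth$layer_model
  for (ratio in c(0.7, 1.4)) {
    cfg_r <- flat_cfg(nx = 60, ny = 60, seed = 31,
                      layer_params = list(inl = 43.4 * ratio,
                                          gcl_ipl = 93 / ratio))
    lay_r <- generate_layer_model(cfg_r)
    nd <- normalize_depth(ph$ra, lay_a, lay_r)
    n0 <- sum(ph$ra$decorrelation > 0)
    n1 <- sum(nd$volume$decorrelation > 0)
    expect_lt(abs(n1 - n0) / n0, 0.05)
  }
})

test_that("transverse normalization maps landmarks and scales features", {
  # 101 columns at 0.1 mm; fovea at x = 0, reference disc at -4 mm
  D <- array(0, c(101, 1, 5))
  D[73, 1, 3] <- 0.5                       # feature at x = +2.2 mm
  vol <- octa_volume(array(1, dim(D)), D, c(100, 100, 10),
                     origin = c(-5, 0),
                     landmarks = data.frame(
                       name = c("fovea", "disc_center", "disc_edge"),
                       x_mm = c(0, -4.4, -3.65), y_mm = 0))
  ref <- data.frame(name = c("fovea", "disc_center", "disc_edge"),
                    x_mm = c(0, -4, -3.25), y_mm = 0)
  # identity when landmarks already match the reference
  vol_id <- vol; vol_id$landmarks <- ref
  expect_equal(normalize_transverse(vol_id, ref)$decorrelation, D)
  # disc-fovea distance ratio 1.1: the feature lands at x = 2.2/1.1 = 2.0
  out <- normalize_transverse(vol, ref)
  expect_equal(which(out$decorrelation[, 1, 3] > 0), 71)   # x = +2.0 mm
  # composing with the inverse map restores the original feature position
  back <- normalize_transverse(out, vol$landmarks)
  expect_equal(which(back$decorrelation[, 1, 3] > 0), 73)
})
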