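test_that("infinite-medium Green's function matches hand evaluation and limits", {
  props <- list(mua = 0.02, musp = 1.0, n = 1.4)
  # continuous-wave closed form evaluated independently
  Dm <- 1 / (3 * 1.02)
  ref <- exp(-20 * sqrt(3 * 0.02 * 1.02)) / (4 * pi * Dm * 20)
  g <- greens_homogeneous(props, 20, 0)
  expect_equal(Re(g), ref, tolerance = 1e-12)
  expect_equal(Im(g), 0)
  # fixed r, increasing frequency: magnitude non-increasing, phase lag
  # increasing (r small enough that the phase stays below pi, unwrapped)
  fs <- c(0, 100, 300, 600, 1000)
  vals <- vapply(fs, function(f) greens_homogeneous(props, 12, f), complex(1))
  expect_true(all(diff(Mod(vals)) <= 0))
  expect_true(all(diff(Arg(vals)) > 0))
  expect_error(greens_homogeneous(props, 0, 100), "singularity")
})

test_that("Green's function amplitude ratio matches an independent arithmetic oracle", {
  gp <- get_tissue_property("gray", 850)
  ratio <- Mod(greens_homogeneous(gp, 29, 140)) / Mod(greens_homogeneous(gp, 13, 140))
  ref <- Mod(oracle_greens(gp$mua, gp$musp, gp$n, 29, 140)) /
    Mod(oracle_greens(gp$mua, gp$musp, gp$n, 13, 140))
  expect_equal(ratio, ref, tolerance = 1e-12)
})

test_that("semi-infinite kernel vanishes on the extrapolated boundary and has the deep limit", {
  props <- list(mua = 0.015, musp = 0.9, n = 1.4)
  Dm <- 1 / (3 * (0.015 + 0.9))
  zb <- 2 * boundary_A(1.4) * Dm
  src <- c(0, 0, 0)
  # any point on the extrapolated plane z = -zb is equidistant from source and image
  for (x in c(0, 5, 17)) {
    val <- greens_semi_infinite(props, src, c(x, 0, -zb), 200)
    expect_lt(Mod(val), 1e-15)
  }
  # deep point: superposition equals difference of two infinite-medium kernels
  fp <- c(10, -4, 30)
  z0 <- 1 / props$musp
  r1 <- sqrt(10^2 + 4^2 + (30 - z0)^2)
  r2 <- sqrt(10^2 + 4^2 + (30 + z0 + 2 * zb)^2)
  ref <- greens_homogeneous(props, r1, 200) - greens_homogeneous(props, r2, 200)
  expect_equal(greens_semi_infinite(props, src, fp, 200), ref, tolerance = 1e-12)
  # continuous wave is purely real
  expect_equal(Im(greens_semi_infinite(props, src, fp, 0)), 0)
})

test_that("continuous-wave voxel solve has zero phase and decaying magnitude", {
  ph <- tiny_slab()
  st <- make_stamp(ph, 17, 17, optode_source_depth(ph, 850))
  fld <- solve_fd_diffusion(ph, st, frequency = 0, wavelength = 850)
  expect_lt(max(abs(Arg(fld[abs(fld) > 0]))), 1e-10)
  # magnitude decays along depth under the source
  prof <- Mod(fld[9, 9, ])
  expect_true(all(diff(prof[2:ph$nz]) < 0))
})

test_that("sparse and spectral solvers agree to round-off on the same operator", {
  ph <- tiny_slab()
  z0 <- optode_source_depth(ph, 690)
  stamps <- list(make_stamp(ph, 11, 17, z0), make_stamp(ph, 24, 18, z0))
  for (f in c(0, 300)) {
    sp <- solve_fd_diffusion(ph, stamps, frequency = f, wavelength = 690)
    sl <- solve_layered(ph, 690, f, stamps)
    for (k in 1:2) {
      expect_lt(max(abs(sp[[k]] - sl[[k]])) / max(abs(sl[[k]])), 1e-8)
    }
  }
})

test_that("multi-source solves equal per-source solves and obey reciprocity", {
  ph <- tiny_slab()
  z0 <- optode_source_depth(ph, 850)
  s1 <- make_stamp(ph, 11, 17, z0)
  s2 <- make_stamp(ph, 24, 18, z0)
  both <- solve_fd_diffusion(ph, list(s1, s2), frequency = 200, wavelength = 850)
  single <- solve_fd_diffusion(ph, s1, frequency = 200, wavelength = 850)
  expect_equal(both[[1]], single, tolerance = 1e-12, ignore_attr = TRUE)
  m12 <- measure_stamp(ph, both[[1]], s2)
  m21 <- measure_stamp(ph, both[[2]], s1)
  expect_lt(Mod(m12 - m21) / Mod(m12), 1e-8)
})

test_that("phase lag is non-negative and grows with distance in a homogeneous medium", {
  props <- tissue_optical_properties()
  props$mua <- 0.018; props$musp <- 0.9
  ph <- build_layered_slab(lateral_extent = 70, depth_extent = 50,
                           voxel_size = 2, properties = props)
  st <- make_stamp(ph, 35, 35, 25)   # internal source
  fld <- solve_layered(ph, 850, 500, list(st))[[1]]
  ix0 <- 18; line <- Arg(fld[19:32, 18, 13])   # radial line in x
  expect_true(all(line >= -1e-12))
  expect_true(all(diff(line) > -1e-10))
})

test_that("layered solver reproduces the closed-form kernel in a homogeneous block", {
  props <- tissue_optical_properties()
  props$mua <- 0.02; props$musp <- 1.0
  ph <- build_layered_slab(lateral_extent = 72, depth_extent = 72,
                           voxel_size = 1.5, properties = props)
  st <- make_stamp(ph, 36.4, 36.4, 36.4)
  fld <- solve_layered(ph, 850, 200, list(st))[[1]]
  cc <- voxel_centers(ph)
  iy <- which.min(abs(cc$y - 36.4)); iz <- which.min(abs(cc$z - 36.4))
  r <- cc$x - 36.4
  sel <- which(r >= 8 & r <= 20)
  g <- greens_homogeneous(list(mua = 0.02, musp = 1.0, n = 1.4), r[sel], 200)
  num <- fld[sel, iy, iz]
  expect_lt(max(abs(Mod(num) / Mod(g) - 1)), 0.05)
  expect_lt(max(abs(Arg(num) - Arg(g))) * 180 / pi, 2)
})
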