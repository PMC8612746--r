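test_that("Rytov data extraction has the closed-form values and wrapping", {
  base <- complex(modulus = c(1, 2, 0.5), argument = c(0.3, -1.2, 2.0))
  expect_equal(rytov_data(base, base)$log_amp, c(0, 0, 0))
  expect_equal(rytov_data(base, base)$phase, c(0, 0, 0))
  pert <- 2 * base * exp(1i * pi / 6)
  rd <- rytov_data(pert, base)
  expect_equal(rd$log_amp, rep(log(2), 3), tolerance = 1e-12)
  expect_equal(rd$phase, rep(pi / 6, 3), tolerance = 1e-12)
  # a 359-degree phase advance wraps to -1 degree
  rd <- rytov_data(exp(1i * 359 * pi / 180), 1 + 0i)
  expect_equal(rd$phase, -pi / 180, tolerance = 1e-12)
  expect_error(rytov_data(base, c(0 + 0i, 1, 1)), "degenerate baseline")
})

make_small_setup <- function(frequency, wavelength = 850) {
  ph <- tiny_slab()
  arr <- place_checkerboard_array(13, 2, 2, ph)
  ch <- enumerate_channels(arr, 3)
  mask <- define_roi(ph, arr, lateral_margin = -4, sensitivity_floor = 0)
  roi <- roi_index(ph, mask)
  ff <- forward_fields(ph, arr, roi, wavelength, frequency)
  list(ph = ph, arr = arr, ch = ch, roi = roi, ff = ff,
       jac = assemble_rytov_jacobian(ff, ph, ch))
}

test_that("continuous-wave Jacobians have intensity rows only and match the f->0 limit", {
  s0 <- make_small_setup(0)
  s1 <- make_small_setup(1)
  expect_true(all(s0$jac$datum == "intensity"))
  expect_equal(nrow(s1$jac$J), 2 * nrow(s0$jac$J))
  nc <- s0$jac$n_channels
  re1 <- s1$jac$J[seq_len(nc), ]
  rel <- max(abs(re1 - s0$jac$J)) / max(abs(s0$jac$J))
  expect_lt(rel, 1e-3)
  # phase rows at 1 MHz are tiny but finite; at exactly 0 they are absent
  expect_true(all(is.finite(s1$jac$J)))
})

test_that("adjoint Jacobian entries match brute-force forward perturbation", {
  # central-difference oracle: perturb one voxel's absorption, re-run the
  # full forward solver, form the Rytov datum
  s <- make_small_setup(300)
  ph <- s$ph
  z0 <- optode_source_depth(ph, 850)
  set.seed(3)
  picks <- sample(which(s$roi$depth >= 5 & s$roi$depth <= 13), 3)
  delta <- 1e-4
  for (v in picks) {
    for (chi in sample(nrow(s$ch), 2)) {
      src <- s$arr$sources[s$ch$src[chi], ]
      det <- s$arr$detectors[s$ch$det[chi], ]
      sst <- make_stamp(ph, src$x, src$y, z0)
      dst <- make_stamp(ph, det$x, det$y, z0)
      dmua <- array(0, dim = c(ph$nx, ph$ny, ph$nz))
      vox <- s$roi$idx[v]
      meas <- function(d) {
        dmua[vox] <- d
        fld <- solve_fd_diffusion(ph, sst, 300, 850, dmua = dmua, tol = 1e-10)
        measure_stamp(ph, fld, dst)
      }
      datum <- (log(meas(delta)) - log(meas(-delta))) / (2 * delta)
      nc <- nrow(s$ch)
      jentry <- complex(real = s$jac$J[chi, v], imaginary = s$jac$J[nc + chi, v])
      expect_lt(Mod(jentry - datum) / Mod(datum), 0.01)
    }
  }
})

test_that("summed intensity sensitivity is normalized and decays with depth", {
  s <- make_small_setup(0)
  ss <- summed_intensity_sensitivity(s$jac)
  expect_equal(max(ss), 1)
  expect_true(all(is.finite(ss)))
  # single channel: proportional to that channel's own profile
  one <- s$jac
  one$J <- one$J[1, , drop = FALSE]
  one$datum <- "intensity"
  s1 <- summed_intensity_sensitivity(one)
  expect_equal(s1, abs(one$J[1, ]) / max(abs(one$J[1, ])))
  # monotone decay below the array center beyond the optode depth
  mid <- which(s$roi$coords[, 1] == 17 & s$roi$coords[, 2] == 17)
  ord <- mid[order(s$roi$depth[mid])]
  prof <- ss[ord]
  expect_true(all(diff(prof[2:length(prof)]) < 0))
})

test_that("phase sensitivity steepens with depth faster than intensity as frequency grows", {
  ph <- build_layered_slab(lateral_extent = 100, depth_extent = 50)
  arr <- structure(list(sources = data.frame(id = 1, x = 30.5, y = 50.5, z = 0),
                        detectors = data.frame(id = 1, x = 69.5, y = 50.5, z = 0)),
                   class = "dot_optodes")
  ch <- structure(data.frame(src = 1, det = 1, sep_mm = 39, nn = 3),
                  class = c("dot_channels", "data.frame"))
  mask <- array(FALSE, c(ph$nx, ph$ny, ph$nz)); mask[25, 25, ] <- TRUE
  roi <- roi_index(ph, mask)
  ratio <- function(f) {
    jac <- assemble_rytov_jacobian(forward_fields(ph, arr, roi, 850, f), ph, ch)
    sh <- which(roi$depth == 9); dp <- which(roi$depth == 25)
    c(I = abs(jac$J[1, dp] / jac$J[1, sh]),
      P = abs(jac$J[2, dp] / jac$J[2, sh]))
  }
  r200 <- ratio(200); r800 <- ratio(800)
  # steepening = how much the deep/shallow ratio shrinks from 200 to 800 MHz
  expect_gt(r200[["P"]] / r800[["P"]], r200[["I"]] / r800[["I"]])
  expect_gt(r200[["P"]] / r800[["P"]], 1)
})
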