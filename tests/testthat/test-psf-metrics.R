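test_that("half-maximum thresholding keeps exactly the voxels at or above half max", {
  v <- c(0.2, 1.0, 0.49, 0.5, 0.51)
  expect_equal(threshold_half_max(v), c(2L, 4L, 5L))
  expect_equal(threshold_half_max(c(0, 0, 0.7)), 3L)
  empty <- threshold_half_max(c(-1, -0.5, 0))
  expect_length(empty, 0)
  expect_true(attr(empty, "empty"))
})

test_that("localization error matches symmetry and a brute-force centroid", {
  # single voxel at the truth
  expect_equal(localization_error(matrix(c(5, 5, 5), 1), 1, c(5, 5, 5)), 0)
  # symmetric blob centered 3 mm from the truth
  offs <- as.matrix(expand.grid(x = -2:2, y = -2:2, z = -2:2))
  blob <- sweep(offs, 2, c(10, 13, 20), "+")
  w <- exp(-rowSums(offs^2) / 4)
  expect_equal(localization_error(blob, w, c(10, 10, 20)), 3, tolerance = 1e-12)
  # random sparse blobs against direct accumulation
  set.seed(31)
  for (i in 1:100) {
    n <- sample(1:40, 1)
    coords <- matrix(stats::runif(3 * n, 0, 50), n, 3)
    w <- stats::runif(n, 0.5, 1)
    truth <- stats::runif(3, 0, 50)
    ref <- sqrt(sum((oracle_centroid(coords, w) - truth)^2))
    expect_equal(localization_error(coords, w, truth), ref, tolerance = 1e-12)
  }
})

test_that("FWHM and FVHM match exhaustive scans including large sets", {
  expect_equal(fwhm(matrix(c(1, 2, 3), 1)), 0)
  two <- rbind(c(0, 0, 0), c(6, 8, 0))
  expect_equal(fwhm(two), 10)
  expect_equal(fvhm(2, 8), 16)
  expect_equal(fvhm(1, 8), 8)
  expect_true(is.na(fvhm(0, 8)))
  set.seed(13)
  for (n in c(5, 50, 200)) {
    coords <- matrix(stats::rnorm(3 * n, sd = 10), n, 3)
    expect_equal(fwhm(coords), oracle_max_pair_dist(coords), tolerance = 1e-12)
  }
  # chunk boundary: set larger than the internal block size
  coords <- matrix(stats::rnorm(3 * 700, sd = 5), 700, 3)
  expect_equal(fwhm(coords), max(stats::dist(coords)), tolerance = 1e-12)
})

test_that("a thresholded isotropic Gaussian has the closed-form FWHM", {
  cc <- expand.grid(x = seq(0, 40, 1), y = seq(0, 40, 1), z = seq(0, 40, 1))
  sigma <- 5
  v <- exp(-((cc$x - 20)^2 + (cc$y - 20)^2 + (cc$z - 20)^2) / (2 * sigma^2))
  keep <- threshold_half_max(v)
  width <- fwhm(as.matrix(cc)[keep, ])
  expect_lt(abs(width - 2 * sigma * sqrt(2 * log(2))), 1)   # within one voxel
})

test_that("success gating attaches resolution metrics only when LE is within cutoff", {
  roi <- list(coords = as.matrix(expand.grid(x = seq(1, 19, 2), y = seq(1, 19, 2),
                                             z = seq(1, 19, 2))),
              voxel_volume = 8)
  center <- c(9, 9, 9)
  v <- exp(-rowSums(sweep(roi$coords, 2, center)^2) / 18)
  hit <- score_psf(v, roi, center + c(1, 0, 0))
  expect_true(hit$success)
  expect_false(hit$empty)
  expect_true(is.finite(hit$FWHM) && is.finite(hit$FVHM))
  miss <- score_psf(v, roi, center + c(12, 0, 0))
  expect_false(miss$success)
  expect_true(is.na(miss$FWHM) && is.na(miss$FVHM))
  flat <- score_psf(rep(-1, nrow(roi$coords)), roi, center)
  expect_true(flat$empty)
  expect_true(is.na(flat$LE))
})

test_that("success-rate curves interpolate the 50% crossing and conserve records", {
  # constructed crossing: 80% success at one bin, 20% at the next
  rec <- data.frame(depth = c(rep(20.2, 10), rep(21.2, 10)),
                    LE = c(rep(1, 8), rep(9, 2), rep(1, 2), rep(9, 8)))
  crv <- success_rate_curve(rec, cutoff = 8, bin_width = 1)
  expect_equal(crv$sr, c(0.8, 0.2))
  expect_equal(crv$sr50_depth, mean(crv$depth), tolerance = 1e-12)
  expect_equal(sum(crv$n), nrow(rec))
  # LE = depth - 10 with cutoff 8 crosses at depth 18
  rec2 <- data.frame(depth = rep(seq(10.5, 29.5, 1), each = 4))
  rec2$LE <- rec2$depth - 10
  crv2 <- success_rate_curve(rec2, cutoff = 8, bin_width = 1)
  expect_equal(crv2$sr50_depth, 18, tolerance = 0.51)
  expect_false(crv2$censored)
  # all successes: censored at the deepest sampled bin
  rec3 <- data.frame(depth = stats::runif(50, 5, 25), LE = stats::runif(50, 0, 4))
  crv3 <- success_rate_curve(rec3)
  expect_true(crv3$censored)
  expect_true(all(crv3$sr == 1))
  expect_equal(crv3$sr50_depth, max(crv3$depth))
})

test_that("brain volume summaries form ratios against continuous wave", {
  rec <- expand.grid(frequency = c(0, 300), seed = 1:20)
  rec$brain <- TRUE
  rec$rep_volume <- 10
  rec$LE <- ifelse(rec$frequency == 0, ifelse(rec$seed <= 10, 2, 9),
                   ifelse(rec$seed <= 15, 2, 9))
  b <- brain_volume_summary(rec, le_cutoffs = c(4, 8))
  expect_equal(b$FBT_ratio[b$frequency == 0], c(1, 1))
  expect_equal(b$FBT_ratio[b$frequency == 300], c(1.5, 1.5))
  # identical metrics at all frequencies: every defined ratio is 1
  # (cutoffs below the common LE have zero CW volume and are NA-flagged)
  rec$LE <- 3
  b1 <- brain_volume_summary(rec, le_cutoffs = 1:8)
  expect_true(all(b1$FBT_ratio[!is.na(b1$FBT_ratio)] == 1))
  expect_true(all(is.na(b1$FBT_ratio[b1$le_cutoff <= 3])))
  # nondecreasing in the cutoff
  set.seed(2)
  rec$LE <- stats::runif(nrow(rec), 0, 12)
  b2 <- brain_volume_summary(rec, le_cutoffs = 1:8)
  for (f in unique(b2$frequency)) {
    expect_true(all(diff(b2$FBTV[b2$frequency == f]) >= 0))
  }
  expect_error(brain_volume_summary(rec[rec$frequency > 0, ]), "0 MHz")
})

test_that("single-seed PSF simulation is deterministic and honors the seed contract", {
  ph <- tiny_slab()
  arr <- place_checkerboard_array(13, 2, 2, ph)
  ch <- enumerate_channels(arr, 3)
  roi <- roi_index(ph, define_roi(ph, arr, -4, 0))
  jacs <- list(); ops <- list()
  for (wl in c(690, 850)) {
    jacs[[as.character(wl)]] <-
      assemble_rytov_jacobian(forward_fields(ph, arr, roi, wl, 300), ph, ch)
    ops[[as.character(wl)]] <- build_inverse_operator(jacs[[as.character(wl)]])
  }
  seed <- which(roi$depth == 7 & roi$coords[, 1] == 17 & roi$coords[, 2] == 17)
  a <- simulate_psf(seed, jacs, ops, roi)
  b <- simulate_psf(seed, jacs, ops, roi)
  expect_identical(a, b)
  expect_true(a$success)
  n1 <- simulate_psf(seed, jacs, ops, roi, noise = list(master_seed = 5, scale = 1))
  n2 <- simulate_psf(seed, jacs, ops, roi, noise = list(master_seed = 5, scale = 1))
  n3 <- simulate_psf(seed, jacs, ops, roi, noise = list(master_seed = 6, scale = 1))
  expect_identical(n1, n2)
  expect_false(isTRUE(all.equal(n1$LE, n3$LE)))
})
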