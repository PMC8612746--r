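test_that("layered slab conserves volume and places layers at stated depths", {
  ph <- build_layered_slab()
  expect_equal(ph$nx * ph$ny * ph$nz, 60 * 60 * 30)
  counts <- table(ph$labels)
  expect_equal(sum(counts), 60 * 60 * 30)
  # exactly divisible layers get thickness/voxel_size z-layers
  zcounts <- table(factor(ph$layer_labels, levels = 1:5))
  expect_equal(unname(zcounts[["1"]]), 4 / 2)   # scalp
  expect_equal(unname(zcounts[["3"]]), 2 / 2)   # CSF
  expect_equal(unname(zcounts[["4"]]), 4 / 2)   # gray
  # first gray-matter voxel center sits at scalp+skull+CSF = 13 mm
  first_gray <- min(which(ph$layer_labels == 4L))
  expect_equal(ph$depth_z[first_gray], 13)
  # rebuilding with the same config is bit-identical
  expect_identical(ph$labels, build_layered_slab()$labels)
})

test_that("property lookups reproduce the baseline optical table", {
  p <- get_tissue_property("scalp", 690)
  expect_equal(p$mua, 0.0159)
  expect_equal(p$musp, 0.8000)
  expect_equal(get_tissue_property("CSF", 690)$musp, 0.3000)
  expect_equal(get_tissue_property("CSF", 850)$musp, 0.3000)
  expect_equal(get_tissue_property("gray", 850)$mua, 0.0192)
  tab <- tissue_optical_properties()
  expect_true(all(tab$mua > 0) && all(tab$musp > 0))
  expect_error(get_tissue_property("bone", 690), "no optical properties")
})

test_that("invalid slab geometry is rejected", {
  expect_error(build_layered_slab(c(scalp = -4, skull = 7, CSF = 2, gray = 4)),
               "invalid geometry")
  expect_error(build_layered_slab(layer_thicknesses = c(20, 20, 20, 20),
                                  depth_extent = 60), "invalid geometry")
  expect_error(build_layered_slab(voxel_size = 0), "invalid geometry")
})

test_that("checkerboard array has interleaved counts and the four NN separations", {
  ph <- build_layered_slab()
  arr <- place_checkerboard_array(13, 7, 7, ph)
  expect_equal(nrow(arr$sources), 25)
  expect_equal(nrow(arr$detectors), 24)
  sep <- oracle_pair_distances(arr)
  expect_equal(min(sep), 13)
  distinct <- sort(unique(round(sep[sep <= 47], 2)))
  expect_equal(distinct, c(13.00, 29.07, 39.00, 46.87))
  # closed-form lattice separations p, p*sqrt(5), 3p, p*sqrt(13)
  expect_equal(distinct, round(13 * c(1, sqrt(5), 3, sqrt(13)), 2),
               tolerance = 0.01)
  expect_error(place_checkerboard_array(13, 12, 12, ph), "out of bounds")
})

test_that("channel enumeration matches a brute-force window scan and nests", {
  ph <- build_layered_slab()
  arr <- place_checkerboard_array(13, 7, 7, ph)
  ch3 <- enumerate_channels(arr, 3)
  ch4 <- enumerate_channels(arr, 4)
  expect_equal(nrow(ch3), oracle_channel_count(arr, c(13, 29, 39), 1))
  expect_equal(nrow(ch4), oracle_channel_count(arr, c(13, 29, 39, 47), 1))
  key <- function(ch) paste(ch$src, ch$det)
  expect_true(all(key(ch3) %in% key(ch4)))
  expect_true(all(ch3$nn %in% 1:3))
  # one isolated pair at 13 mm gives a single class-1 channel
  arr1 <- list(sources = data.frame(id = 1, x = 20, y = 20, z = 0),
               detectors = data.frame(id = 1, x = 33, y = 20, z = 0))
  ch1 <- enumerate_channels(arr1, 3)
  expect_equal(nrow(ch1), 1)
  expect_equal(ch1$nn, 1L)
  expect_equal(ch1$sep_mm, 13)
})

test_that("ROI masks respect margins, sensitivity floor and shrink monotonically", {
  ph <- build_layered_slab(lateral_extent = 60, depth_extent = 30)
  arr <- place_checkerboard_array(13, 3, 3, ph)
  # synthetic sensitivity peaking under the array center, decaying with
  # depth and lateral distance
  cc0 <- voxel_centers(ph)
  lat <- exp(-outer((cc0$x - 30)^2, (cc0$y - 30)^2, "+") / 400)
  sens <- array(outer(lat, exp(-cc0$z / 5)), dim = c(ph$nx, ph$ny, ph$nz))
  full <- define_roi(ph, arr, lateral_margin = 0, sensitivity_floor = 0)
  cc <- voxel_centers(ph)
  opt <- rbind(arr$sources, arr$detectors)
  inx <- cc$x >= min(opt$x) & cc$x <= max(opt$x)
  expect_equal(sum(full), sum(inx)^2 * ph$nz)
  only_max <- define_roi(ph, arr, 0, 1, sens)
  expect_equal(sum(only_max), sum(sens == max(sens) & full))
  m0 <- sum(define_roi(ph, arr, 0, 1e-3, sens))
  m1 <- sum(define_roi(ph, arr, 5, 1e-3, sens))
  m2 <- sum(define_roi(ph, arr, 5, 1e-2, sens))
  expect_true(m1 <= m0 && m2 <= m1)
  expect_error(define_roi(ph, arr, 1e6, 0), "degenerate ROI")
})

test_that("roi_index and TSV exports round-trip geometry", {
  ph <- build_layered_slab(lateral_extent = 60, depth_extent = 30)
  arr <- place_checkerboard_array(13, 3, 3, ph)
  mask <- define_roi(ph, arr, 0, 0)
  roi <- roi_index(ph, mask)
  expect_equal(roi$n, sum(mask))
  expect_equal(roi$voxel_volume, 8)
  expect_true(all(roi$depth == roi$coords[, 3]))
  expect_equal(sort(unique(roi$label[roi$brain])), c(4L, 5L))
  tf <- tempfile(fileext = ".tsv")
  write_optodes_tsv(arr, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), nrow(arr$sources) + nrow(arr$detectors))
  write_channels_tsv(enumerate_channels(arr, 3), tf)
  tab <- read.delim(tf)
  expect_named(tab, c("src", "det", "sep_mm", "nn"))
})
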