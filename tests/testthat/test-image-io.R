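# Stack containers, TIFF round trips, ROIs and cropping.

test_that("image_stack validates its invariants", {
  v <- array(1, c(2, 4, 6, 6))
  s <- image_stack(v, c(0.2, 0.1, 0.1))
  expect_s3_class(s, "image_stack")
  expect_equal(s$channel_names, c("gfp", "mcherry"))
  expect_error(image_stack(array(-1, c(2, 2, 2)), c(1, 1, 1)), "non-negative")
  expect_error(image_stack(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  expect_error(image_stack(v, c(0.2, 0.1, 0.2)), "isotropic")
  expect_error(image_stack(v, c(0, 0.1, 0.1)), "positive")
  expect_error(image_stack(array(1, c(4, 2, 2, 2)), c(1, 1, 1)),
               "channel count")
})

test_that("16-bit TIFF stacks survive a write/read round trip", {
  s <- ball_stack()
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(s, path)
  r <- read_stack(path, s$spacing, s$channel_names)
  expect_equal(dim(r$voxels), dim(s$voxels))
  expect_equal(r$voxels, round(s$voxels), tolerance = 1e-12)
  expect_error(read_stack(withr::local_tempfile(fileext = ".tif"),
                          c(1, 1, 1)), "not found")
})

test_that("32-bit stacks are rescaled so the maximum maps to 65535", {
  m1 <- matrix(stats::runif(64, 0, 0.8), 8, 8)
  m2 <- matrix(stats::runif(64, 0, 0.8), 8, 8)
  m2[3, 4] <- 0.8  # global max
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(m1, m2), path, bits.per.sample = 32L)
  r <- read_stack(path, c(1, 1, 1), "gfp")
  # independent linear rescale oracle
  expected <- array(0, c(1, 2, 8, 8))
  expected[1, 1, , ] <- m1 * (65535 / 0.8)
  expected[1, 2, , ] <- m2 * (65535 / 0.8)
  expect_equal(r$voxels, expected, tolerance = 1e-6)
  expect_equal(max(r$voxels), 65535, tolerance = 1e-6)
})

test_that("page count inconsistent with channel count is an error", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.2, 4, 4),
                       matrix(0.1, 4, 4)), path, bits.per.sample = 16L)
  expect_error(read_stack(path, c(1, 1, 1), c("gfp", "mcherry")),
               "not a multiple")
})

test_that("cropping follows 0-based half-open semantics and composes", {
  v <- array(seq_len(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  s <- image_stack(v, c(1, 1, 1))
  full <- crop_cell(s, cell_roi("a", c(0, 0, 0), c(8, 8, 8)))
  expect_identical(full$voxels, s$voxels)
  sub <- crop_cell(s, cell_roi("b", c(0, 0, 0), c(4, 4, 4)))
  expect_equal(dim(sub$voxels), c(2, 4, 4, 4))
  # half-open: index hi is excluded (brute-force index enumeration)
  edge <- crop_cell(s, cell_roi("c", c(5, 5, 5), c(8, 8, 8)))
  kept <- expand.grid(z = 5:7, y = 5:7, x = 5:7)  # 0-based indices
  for (i in sample(nrow(kept), 5)) {
    k <- kept[i, ]
    expect_equal(edge$voxels[1, k$z - 4, k$y - 4, k$x - 4],
                 s$voxels[1, k$z + 1, k$y + 1, k$x + 1])
  }
  # nested crops equal the composed crop
  c1 <- crop_cell(s, cell_roi("d", c(1, 2, 0), c(7, 8, 6)))
  c2 <- crop_cell(c1, cell_roi("e", c(2, 1, 1), c(5, 4, 6)))
  direct <- crop_cell(s, cell_roi("f", c(3, 3, 1), c(6, 6, 6)))
  expect_identical(c2$voxels, direct$voxels)
  expect_error(crop_cell(s, cell_roi("g", c(0, 0, 0), c(9, 8, 8))),
               "exceeds")
  expect_error(cell_roi("h", c(2, 2, 2), c(2, 3, 3)), "non-empty")
})

test_that("ROI sidecar files round trip", {
  rois <- list(cell_roi("cell_1", c(0, 0, 0), c(8, 16, 16)),
               cell_roi("cell_2", c(2, 3, 4), c(6, 10, 12)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(back, rois)
})

test_that("masks are written as readable 8-bit TIFFs", {
  m <- array(FALSE, c(3, 6, 6)); m[2, 2:4, 2:4] <- TRUE
  bv <- binary_volume(m, c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask(bv, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 3)
  expect_equal(sum(vapply(pages, sum, numeric(1))), 9)
})
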