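# Per-cell morphology: filtering, Vs, fragmentation, weighted features,
# population summaries.

test_that("small-object exclusion is strict and boundary-inclusive", {
  sp <- c(0.2, 0.1, 0.1)          # voxel volume 0.002 um^3
  objs <- list(voxel_cube(3),     # 27 vox = 0.054 um^3, below threshold
               voxel_cube(4),     # 64 vox = 0.128 um^3, kept
               voxel_rod(50))     # 50 vox = 0.100 um^3, exactly at threshold
  kept <- filter_small(objs, sp, min_volume = 0.1)
  expect_length(kept, 2)
  expect_identical(kept[[2]], objs[[3]])  # order preserved, boundary kept
  expect_identical(filter_small(objs, sp, min_volume = 0), objs)
})

test_that("relative volumes sum to 100 and match simple ratios", {
  expect_equal(relative_volumes(c(3, 1)), c(75, 25))
  expect_equal(relative_volumes(5), 100)
  expect_equal(relative_volumes(rep(2, 10)), rep(10, 10))
  set.seed(71)
  for (i in 1:20) {
    vs <- relative_volumes(runif(sample(1:12, 1), 0.01, 5))
    expect_equal(sum(vs), 100, tolerance = 1e-6 * 100)
  }
  expect_error(relative_volumes(numeric()), "no objects")
})

test_that("fragmentation index sums exactly the sub-threshold fragments", {
  expect_equal(fragmentation_index(c(60, 25, 15, 5)), 20)
  expect_equal(fragmentation_index(100), 0)
  expect_equal(fragmentation_index(rep(10, 10)), 100)
  expect_equal(fragmentation_index(c(80, 20)), 20)  # threshold is inclusive
  expect_equal(fragmentation_index(c(70, 25, 5), threshold = 25), 30)
})

test_that("surface-area weighting averages features as specified", {
  df <- data.frame(surface_um2 = c(1, 3), x = c(0, 4))
  expect_equal(unname(weighted_cell_features(df, "x")), 3)
  df2 <- data.frame(surface_um2 = rep(2, 5), x = rnorm(5))
  expect_equal(unname(weighted_cell_features(df2, "x")), mean(df2$x))
  df3 <- data.frame(surface_um2 = runif(4, 1, 9), x = rep(7.5, 4))
  expect_equal(unname(weighted_cell_features(df3, "x")), 7.5)
})

test_that("volume is conserved across labelling and features", {
  set.seed(81)
  sp <- c(0.2, 0.1, 0.1)
  m <- random_mask(c(8, 20, 20), 0.4)
  objs <- label_objects(m)
  expect_equal(sum(vapply(objs, nrow, integer(1))), sum(m))
  expect_equal(sum(vapply(objs, nrow, integer(1))) * prod(sp),
               sum(m) * prod(sp))
})

test_that("cell morphology integrates objects, Vs and f on a built mask", {
  sp <- c(0.2, 0.1, 0.1)
  m <- array(FALSE, c(16, 40, 40))
  m[2:9, 2:11, 2:31] <- TRUE       # 2400 vox = 4.8 um^3
  m[2:5, 20:29, 20:29] <- TRUE     # 400 vox  = 0.8 um^3
  m[12:13, 35:38, 35:38] <- TRUE   # 32 vox   = 0.064 um^3 -> excluded
  cm <- cell_morphology(binary_volume(m, sp), cell_label = "c1")
  expect_equal(nrow(cm$objects), 2)
  expect_equal(cm$n_excluded, 1)
  expect_equal(cm$total_volume_um3, 5.6)
  expect_equal(sort(cm$objects$vs), c(100 * 0.8 / 5.6, 100 * 4.8 / 5.6))
  expect_equal(cm$f, 100 * 0.8 / 5.6)  # 14.3% fragment counts toward f
  expect_equal(sum(cm$objects$vs), 100, tolerance = 1e-9)
  # weighted feature of a constant column equals the constant
  cm$objects$const <- 3.25
  expect_equal(unname(weighted_cell_features(cm$objects, "const")), 3.25)
  expect_error(cell_morphology(binary_volume(array(FALSE, c(2, 2, 2)), sp)),
               "no mitochondrial objects")
})

test_that("population summary aggregates f and bins Vs by decile", {
  mk <- function(f, vs) structure(list(f = f,
                                       objects = data.frame(vs = vs)),
                                  class = "cell_morphology")
  cells <- list(mk(10, c(90, 10)), mk(30, c(70, 15, 15)))
  pop <- population_summary(cells)
  expect_equal(pop$mean_f, 20)
  expect_equal(pop$sem_f, 10)
  expect_equal(pop$n_cells, 2)
  # hand-binned oracle: 90 -> [90,100]; 70 -> [70,80); 10, 15, 15 -> [10,20)
  expect_equal(unname(pop$vs_histogram[["[90,100]"]]), 90)
  expect_equal(unname(pop$vs_histogram[["[70,80)"]]), 70)
  expect_equal(unname(pop$vs_histogram[["[10,20)"]]), 40)
  expect_equal(sum(pop$vs_histogram), 200)  # 100% per cell
  # a Vs of exactly 100 falls in the closed top bin
  pop1 <- population_summary(list(mk(0, 100), mk(0, 100)))
  expect_equal(unname(pop1$vs_histogram[["[90,100]"]]), 200)
  expect_true(is.na(population_summary(list(mk(5, 100)))$sem_f))
})
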