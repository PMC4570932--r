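# Co-localisation statistics and power analysis.

test_that("Pearson correlation honours affine relations and symmetry", {
  set.seed(91)
  g <- array(runif(1000, 10, 200), c(10, 10, 10))
  expect_equal(pearson_cc(g, g), 1)
  expect_equal(pearson_cc(g, 3 * g + 7), 1)
  expect_equal(pearson_cc(g, -0.5 * g + 400), -1)
  r <- array(runif(1000, 10, 200), c(10, 10, 10))
  expect_equal(pearson_cc(g, r), pearson_cc(r, g))
  # invariance under positive affine transforms of either channel
  expect_equal(pearson_cc(2.3 * g + 11, r), pearson_cc(g, r),
               tolerance = 1e-12)
  expect_error(pearson_cc(array(5, c(3, 3, 3)), r[1:3, 1:3, 1:3]),
               "zero intensity variance")
})

test_that("independent channels decorrelate as 3/sqrt(n)", {
  set.seed(101)
  n <- 40000
  g <- array(rnorm(n), c(10, 40, 100))
  r <- array(rnorm(n), c(10, 40, 100))
  expect_lt(abs(pearson_cc(g, r)), 3 / sqrt(n))
})

test_that("r2 equals pcc^2 and the explicit regression fit", {
  set.seed(111)
  g <- array(runif(512, 0, 100), c(8, 8, 8))
  r <- 0.6 * g + array(rnorm(512, sd = 15), c(8, 8, 8)) + 20
  r <- pmax(r, 0)
  mask <- array(runif(512) < 0.7, c(8, 8, 8))
  expect_equal(r_squared(g, r, mask), pearson_cc(g, r, mask)^2)
  fit <- lm(r[mask] ~ g[mask])
  r2_lm <- 1 - sum(residuals(fit)^2) / sum((r[mask] - mean(r[mask]))^2)
  expect_equal(r_squared(g, r, mask), r2_lm, tolerance = 1e-12)
})

test_that("batch colocalisation reports per-cell results and flags errors", {
  s <- ball_stack(dim = c(8L, 48L, 24L))
  # duplicate the cell side by side so two ROIs see identical data
  v <- s$voxels
  v2 <- array(0, c(2, 8, 48, 48))
  v2[, , , 1:24] <- v; v2[, , , 25:48] <- v
  big <- image_stack(v2, s$spacing, s$channel_names)
  rois <- list(cell_roi("left", c(0, 0, 0), c(8, 48, 24)),
               cell_roi("right", c(0, 0, 24), c(8, 48, 48)))
  out <- batch_coloc(big, rois, sigma = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$pcc[1], out$pcc[2])
  expect_true(all(is.na(out$error)))
  expect_equal(nrow(batch_coloc(big, list(), sigma = 2)), 0)
  # a constant cell is flagged, not dropped
  v2[, , 40:48, 1:24] <- 50
  v2[, , , 25:48] <- 33
  flat <- image_stack(v2, s$spacing, s$channel_names)
  out2 <- batch_coloc(flat, rois, sigma = 2)
  expect_false(is.na(out2$error[2]))
  expect_true(is.na(out2$pcc[2]))
  expect_error(batch_coloc(ball_stack(), rois, green = "missing"),
               "lacks")
})

test_that("whole-cell mask mode uses every cropped voxel", {
  s <- ball_stack(dim = c(6L, 20L, 20L))
  roi <- list(cell_roi("c", c(0, 0, 0), c(6, 20, 20)))
  out <- batch_coloc(s, roi, mask_mode = "all")
  expect_equal(out$n_voxels, 6L * 20L * 20L)
})

test_that("power analysis matches an independent power-curve scan", {
  a <- c(0.8, 0.82, 0.78, 0.81)
  b <- c(0.5, 0.55, 0.52, 0.49)
  # oracle: scan n upward on the normal-approximation power curve
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  d <- abs(mean(a) - mean(b)) / sp
  power_at <- function(n) pnorm(d * sqrt(n / 2) - qnorm(0.975))
  n_oracle <- 2
  while (power_at(n_oracle) < 0.8) n_oracle <- n_oracle + 1
  expect_equal(min_cells_power(a, b), n_oracle)
  # canonical effect size d = 2
  a2 <- c(-1, 0, 1); b2 <- a2 + 2  # pooled sd 1, d = 2
  n2 <- min_cells_power(a2, b2)
  powers <- vapply(2:20, function(n) pnorm(2 * sqrt(n / 2) - qnorm(0.975)),
                   numeric(1))
  expect_equal(n2, (2:20)[which(powers >= 0.8)[1]])
  # monotonicity: larger effects never need more cells
  expect_lte(min_cells_power(a2, a2 + 4), n2)
  # zero effect, non-zero spread
  expect_identical(min_cells_power(a2, a2), Inf)
  expect_error(min_cells_power(c(1, 1), c(1, 1)), "pooled")
  # exact method agrees within 1 cell at this effect size
  expect_lte(abs(min_cells_power(a2, b2, method = "exact") - n2), 2)
})

test_that("group summaries report mean, SEM and failure counts", {
  df <- data.frame(pcc = c(0.8, 0.9, NA), r2 = c(0.64, 0.81, NA))
  s <- coloc_group_summary(df)
  expect_equal(s$mean_pcc, 0.85)
  expect_equal(s$sem_pcc, sd(c(0.8, 0.9)) / sqrt(2))
  expect_equal(s$n, 2)
  expect_equal(s$n_failed, 1)
  s1 <- coloc_group_summary(data.frame(pcc = 0.7))
  expect_true(is.na(s1$sem_pcc))
})
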