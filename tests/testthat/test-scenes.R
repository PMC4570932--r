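# Synthetic scene generation.

test_that("scene specs validate geometry, phi and the mandatory seed", {
  ok <- scene_spec(objects = list(sphere_obj(c(1.9, 3.2, 3.2), 0.8)),
                   seed = 1)
  expect_s3_class(ok, "scene_spec")
  expect_error(scene_spec(objects = list(sphere_obj(c(1.9, 3.2, 3.2), 0.8))),
               "seed")
  expect_error(scene_spec(objects = list(sphere_obj(c(1.9, 3.2, 3.2), 0.8)),
                          phi = 1.2, seed = 1), "phi")
  expect_error(scene_spec(objects = list(sphere_obj(c(0.1, 3.2, 3.2), 0.8)),
                          seed = 1), "outside")
  expect_error(sphere_obj(c(1, 1, 1), 0), "radius > 0")
})

test_that("identical specs rasterise to identical stacks", {
  spec <- scene_spec(objects = list(sphere_obj(c(1.9, 3.2, 3.2), 0.7),
                                    tube_obj(rbind(c(1.5, 1, 1),
                                                   c(1.5, 5, 5)), 0.2)),
                     phi = 0.4, seed = 99)
  s1 <- rasterise_scene(spec)
  s2 <- rasterise_scene(spec)
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  # a different seed changes the noise realisation
  spec2 <- scene_spec(objects = spec$objects, phi = 0.4, seed = 100)
  expect_false(identical(rasterise_scene(spec2)$stack$voxels,
                         s1$stack$voxels))
})

test_that("rasterised sphere volume matches the analytic ball", {
  sp <- c(0.1, 0.1, 0.1)
  spec <- scene_spec(dim = c(26L, 26L, 26L), spacing = sp,
                     objects = list(sphere_obj(c(1.3, 1.3, 1.3), 1.0)),
                     noise = list(poisson = FALSE, read_sd = 0),
                     psf_sigma = 0, seed = 1)
  sc <- rasterise_scene(spec)
  expect_length(sc$ground_truth, 1)
  v_an <- 4 / 3 * pi * 1.0^3
  expect_lt(abs(nrow(sc$ground_truth[[1]]) * prod(sp) - v_an) / v_an, 0.05)
})

test_that("without delocalisation, noise or blur the red channel tracks green", {
  spec <- scene_spec(objects = list(sphere_obj(c(1.9, 3.2, 3.2), 0.8)),
                     phi = 0, noise = list(poisson = FALSE, read_sd = 0),
                     psf_sigma = 0, seed = 5)
  sc <- rasterise_scene(spec)
  g <- get_channel(sc$stack, "gfp"); r <- get_channel(sc$stack, "mcherry")
  expect_equal(g, r)
  expect_equal(pearson_cc(g, r, sc$object_mask |
                            (g > 0)), 1)  # proportional everywhere
  # full delocalisation: red is flat over the cytosol
  spec1 <- scene_spec(objects = spec$objects, phi = 1,
                      noise = list(poisson = FALSE, read_sd = 0),
                      psf_sigma = 0, seed = 5)
  sc1 <- rasterise_scene(spec1)
  r1 <- get_channel(sc1$stack, "mcherry")
  expect_equal(length(unique(round(r1[sc1$cytosol], 9))), 1)
})

test_that("overlapping objects merge in the ground truth", {
  spec <- scene_spec(objects = list(sphere_obj(c(1.9, 2.8, 2.8), 0.5),
                                    sphere_obj(c(1.9, 3.4, 3.4), 0.5)),
                     seed = 3)
  sc <- rasterise_scene(spec)
  expect_length(sc$ground_truth, 1)
})

test_that("fragmentation designs hit the target exactly and flag infeasible ones", {
  for (tf in c(0, 20, 45, 100)) {
    vs <- mitomorph:::design_vs(tf)
    expect_equal(sum(vs), 100)
    expect_equal(fragmentation_index(vs), tf)
  }
  expect_error(mitomorph:::design_vs(90), "infeasible")
  expect_error(mitomorph:::design_vs(101), "target_f")
})

test_that("a small fragmentation series recovers its designed f", {
  series <- make_fragmentation_series("spherical", 45, n_cells = 2,
                                      seed = 500)
  for (cell in series) {
    expect_equal(fragmentation_index(cell$designed_vs), 45)
    cm <- cell_morphology(segment_mitochondria(cell$scene$stack))
    expect_lt(abs(cm$f - cell$expected_f), 5)
  }
  # reproducibility of the whole series
  again <- make_fragmentation_series("spherical", 45, n_cells = 2,
                                     seed = 500)
  expect_identical(series[[1]]$scene$stack$voxels,
                   again[[1]]$scene$stack$voxels)
})
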