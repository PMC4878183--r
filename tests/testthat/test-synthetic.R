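test_that("scene specs validate their invariants", {
  expect_error(scene_spec(permeable_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scene_spec(image_shape = c(32, 256)), ">= 64")
  expect_error(scene_spec(noise_sd = -1), ">= 0")
  expect_error(scene_spec(n_macrophages = -2), ">= 0")
})

test_that("regeneration with identical spec and seed is bit-identical", {
  sp <- scene_spec(n_macrophages = 6, n_adipocytes = 1, noise_sd = 10, seed = 5)
  a <- generate_cls_scene(sp)
  b <- generate_cls_scene(sp)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cells, b$truth$cells)

  # different seed: different pixels
  c <- generate_cls_scene(modifyList(sp, list(seed = 6)))
  expect_false(identical(a$stack$channels$Cy3, c$stack$channels$Cy3))
})

test_that("permeable flags are reproducible binomial draws", {
  sp <- scene_spec(n_macrophages = 10, n_adipocytes = 2, permeable_fraction = 0.3,
                   seed = 9)
  a <- generate_cls_scene(sp)
  b <- generate_cls_scene(sp)
  expect_identical(a$truth$cells$permeable, b$truth$cells$permeable)
  expect_true(all(a$truth$cells$permeable %in% c(TRUE, FALSE)))
  # Cy5 painted exactly on the permeable subset
  lab <- a$truth$labels
  cy5 <- a$stack$channels$Cy5
  for (i in seq_len(10)) {
    filled <- mean(cy5[lab == i]) > 100
    expect_identical(filled, a$truth$cells$permeable[i])
  }
})

test_that("noise-free painting is conservative (totals equal ground truth)", {
  sp <- scene_spec(n_macrophages = 5, n_adipocytes = 1, noise_sd = 0,
                   permeable_fraction = 0, membrane_signal_mean = 0,
                   background_level = 0, seed = 4)
  sc <- generate_cls_scene(sp)
  # with membrane off, Cy3 total is exactly the painted puncta
  expect_equal(sum(sc$stack$channels$Cy3),
               sum(sc$truth$cells$true_lysosomal_signal), tolerance = 1e-9)

  sp2 <- modifyList(sp, list(membrane_signal_mean = 80, lysosomal_signal_mean = 0,
                             n_puncta_mean = 0))
  sc2 <- generate_cls_scene(sp2)
  expect_equal(sum(sc2$stack$channels$Cy3),
               sum(sc2$truth$cells$true_surface_signal), tolerance = 1e-9)
})

test_that("crown macrophages lie on an adipocyte perimeter annulus, dispersed do not", {
  spc <- scene_spec(n_macrophages = 8, n_adipocytes = 2, geometry = "crown", seed = 2)
  scc <- generate_cls_scene(spc)
  spd <- modifyList(spc, list(geometry = "dispersed"))
  scd <- generate_cls_scene(spd)
  ring_r <- spc$adipocyte_radius_px + spc$macrophage_radius_px + 1
  dist_to_adip <- function(truth) {
    apply(truth$cells[, c("row", "col")], 1, function(p) {
      min(sqrt((truth$adipocyte_centers[, 1] - p[1])^2 +
               (truth$adipocyte_centers[, 2] - p[2])^2))
    })
  }
  expect_true(all(abs(dist_to_adip(scc$truth) - ring_r) < 1e-6))
  expect_true(all(dist_to_adip(scd$truth) > ring_r + spc$macrophage_radius_px))
  expect_true(all(scc$truth$cells$contact))
  expect_false(any(scd$truth$cells$contact))
})

test_that("identical spec under two seeds keeps summary statistics close", {
  sp <- scene_spec(n_macrophages = 30, n_adipocytes = 4, noise_sd = 5,
                   image_shape = c(420, 420), seed = 1)
  a <- generate_cls_scene(sp)
  b <- generate_cls_scene(modifyList(sp, list(seed = 99)))
  ma <- mean(a$truth$cells$true_surface_signal)
  mb <- mean(b$truth$cells$true_surface_signal)
  # lognormal heterogeneity: means agree within sampling error at n = 30
  expect_lt(abs(ma - mb) / ma, 0.35)
})

test_that("pH scene: noise-free ratio equals the generating response", {
  field <- matrix(5.0, 80, 80)
  sp <- ph_scene_spec(field, noise_sd = 0, seed = 1)
  sc <- generate_ph_scene(sp)
  inside <- sc$truth$label_mask
  ratio <- sc$stack$channels$CypHer5E[inside] / sc$stack$channels$Alexa488[inside]
  expect_equal(unique(round(ratio, 10)),
               round(response_4pl(5.0, sp$calibration_truth), 10))

  # piecewise-constant field gives a two-level ratio image
  field2 <- matrix(4.5, 80, 80); field2[, 41:80] <- 7.0
  sc2 <- generate_ph_scene(ph_scene_spec(field2, noise_sd = 0))
  r2 <- sc2$stack$channels$CypHer5E / pmax(sc2$stack$channels$Alexa488, 1e-12)
  expect_equal(sort(unique(round(r2[sc2$truth$label_mask], 8))),
               sort(round(response_4pl(c(7.0, 4.5), sp$calibration_truth), 8)))
})

test_that("pH scene rejects a non-monotone calibration and out-of-range fields", {
  field <- matrix(6, 64, 64)
  expect_error(ph_scene_spec(field, calibration_truth = list(a = 1, d = 2, c = 6, b = 6)),
               "decreasing")
  expect_error(ph_scene_spec(matrix(10, 64, 64)), "\\[3, 9\\]")
})

test_that("noisy pH scene recovers the expected mean ratio", {
  field <- matrix(6.0, 100, 100)
  truth <- list(a = 3, d = 0.2, c = 6, b = 6)
  sp <- ph_scene_spec(field, calibration_truth = truth, alexa_level = 800,
                      noise_sd = 20, seed = 33)
  sc <- generate_ph_scene(sp)
  inside <- sc$truth$label_mask
  ratio <- sc$stack$channels$CypHer5E[inside] / sc$stack$channels$Alexa488[inside]
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - response_4pl(6.0, truth)), 3 * se + 1e-3)
})

test_that("EM volume ground truth does the voxel arithmetic", {
  # half-integer centre so the 4.5 half-width box spans exactly 10 voxels
  cube_spec <- function(sealed) volume_spec(
    volume_shape = c(32, 32, 48), voxel_size_nm = c(20, 20, 20),
    cavities = list(list(shape = "box", center = c(16.5, 16.5, 22.5),
                         size = c(4.5, 4.5, 4.5), sealed = sealed)))
  gen <- generate_em_volume(cube_spec(TRUE))
  expect_equal(gen$truth$cavities$voxel_count, 1000)
  expect_equal(gen$truth$cavities$volume_nm3, 8.0e6)
  expect_true(gen$truth$cavities$sealed)

  # same cavity opened to a face
  gen2 <- generate_em_volume(cube_spec(FALSE))
  expect_false(gen2$truth$cavities$sealed)
  # the channel reaches the +X face as lumen
  expect_true(any(gen2$truth$phases[, , dim(gen2$truth$phases)[3]] == "lumen"))

  # two disjoint sealed cavities: 5^3 and 7^3
  gen3 <- generate_em_volume(volume_spec(
    volume_shape = c(32, 32, 48), voxel_size_nm = c(20, 20, 20),
    cavities = list(
      list(shape = "box", center = c(10, 10, 20), size = c(2, 2, 2), sealed = TRUE),
      list(shape = "box", center = c(22, 22, 26), size = c(3, 3, 3), sealed = TRUE))))
  expect_equal(gen3$truth$cavities$voxel_count, c(125, 343))
  expect_equal(nrow(gen3$truth$cavities), 2)

  expect_error(generate_em_volume(volume_spec(
    volume_shape = c(32, 32, 48), voxel_size_nm = c(20, 20, 20),
    cavities = list(list(shape = "box", center = c(2, 16, 24),
                         size = c(5, 5, 5), sealed = TRUE)))),
    "bounds|enclosed")
})

test_that("EM phases tile the volume and flags pass the flood-fill self-check", {
  gen <- generate_em_volume(volume_spec(
    cavities = list(list(shape = "ellipsoid", center = c(24, 32, 32),
                         size = c(5, 7, 6), sealed = TRUE))))
  expect_true(all(gen$truth$phases %in%
                    c("background", "lumen", "macrophage", "adipocyte")))
})

test_that("uptake scene paints exact per-cell truths and contact geometry", {
  up <- generate_uptake_scene(c(100, 0, 250), c(TRUE, FALSE, TRUE), seed = 2)
  expect_equal(up$truth$cells$true_signal, c(100, 0, 250))
  # noise-free painted totals per ground-truth label
  sig <- up$stack$channels$Alexa546
  for (i in 1:3) {
    expect_equal(sum(sig[up$truth$labels == i]), c(100, 0, 250)[i], tolerance = 1e-9)
  }
  expect_error(generate_uptake_scene(c(-1, 5), c(TRUE, TRUE)), ">= 0")
  expect_error(generate_uptake_scene(c(1, 5), c(TRUE)), "lengths")

  # all-zero truths: signal channel is background only
  up0 <- generate_uptake_scene(rep(0, 3), rep(TRUE, 3), seed = 3,
                               background_level = 7)
  expect_true(all(up0$stack$channels$Alexa546 == 7))
})
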