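make_disc <- function(shape, center, radius, level, base = 0) {
  m <- matrix(base, shape[1], shape[2])
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  m[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- level
  m
}

test_that("count_nuclei counts disjoint discs and honours 8-connected bridges", {
  expect_equal(count_nuclei(matrix(0, 64, 64)), 0L)

  img <- make_disc(c(64, 64), c(15, 15), 4, 200) +
    make_disc(c(64, 64), c(40, 40), 4, 200) +
    make_disc(c(64, 64), c(15, 48), 4, 200)
  expect_equal(count_nuclei(img), 3L)

  # two discs merged by a 1-px bridge count as one under 8-connectivity
  # (kernel_px = 1: smoothing off, so the bridge is not attenuated)
  img2 <- make_disc(c(64, 64), c(30, 20), 5, 200) +
    make_disc(c(64, 64), c(30, 40), 5, 200)
  img2[30, 25:35] <- 200
  expect_equal(count_nuclei(img2, kernel_px = 1), 1L)
  # the 5x5 pre-filter attenuates the 1-px bridge below threshold: two nuclei
  expect_equal(count_nuclei(img2, kernel_px = 5), 2L)

  expect_error(count_nuclei(img, min_area_px = 0), ">= 1")
})

test_that("surface pipeline recovers painted membrane signal on clean scenes", {
  sp <- scene_spec(n_macrophages = 2, n_adipocytes = 1, noise_sd = 0,
                   permeable_fraction = 0, lysosomal_signal_mean = 0,
                   n_puncta_mean = 0, heterogeneity_sdlog = 1e-9,
                   membrane_signal_mean = 50, seed = 8)
  sc <- generate_cls_scene(sp)
  res <- surface_lamp1_per_cell(sc$stack)
  truth_per_cell <- mean(sc$truth$cells$true_surface_signal)
  expect_equal(res$cell_count, 2L)
  expect_equal(res$signal_per_cell, truth_per_cell, tolerance = 0.1)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(tidy(res)$signal_per_cell, res$signal_per_cell)
})

test_that("blank Cy3 gives zero signal; all-permeable scenes give empty masks", {
  sp <- scene_spec(n_macrophages = 3, n_adipocytes = 1, noise_sd = 0,
                   membrane_signal_mean = 0, lysosomal_signal_mean = 0,
                   n_puncta_mean = 0, permeable_fraction = 0,
                   background_level = 0, seed = 12)
  sc <- generate_cls_scene(sp)
  res <- surface_lamp1_per_cell(sc$stack)
  expect_equal(res$signal_per_cell, 0)

  # every macrophage calnexin-positive: full exclusion, zero total
  spp <- modifyList(sp, list(permeable_fraction = 1, membrane_signal_mean = 90))
  scp <- generate_cls_scene(spp)
  params <- quant_params(nuclei_mode = "all")
  resp <- surface_lamp1_per_cell(scp$stack, params)
  expect_equal(resp$total_signal, 0)
  expect_true(sum(resp$gating$combined) == 0)
})

test_that("lysosomal variant is never below the surface variant on one stack", {
  for (s in c(3, 14)) {
    sp <- scene_spec(n_macrophages = 4, n_adipocytes = 1, noise_sd = 2,
                     permeable_fraction = 0.5, seed = s)
    sc <- generate_cls_scene(sp)
    surf <- surface_lamp1_per_cell(sc$stack, quant_params(nuclei_mode = "all"))
    lyso <- lysosomal_lamp1_per_cell(sc$stack, quant_params(nuclei_mode = "all"))
    expect_gte(lyso$total_signal, surf$total_signal - 1e-9)
  }
})

test_that("lysosomal pipeline recovers punctum totals per nucleus", {
  sp <- scene_spec(n_macrophages = 3, n_adipocytes = 1, noise_sd = 0,
                   membrane_signal_mean = 0, permeable_fraction = 0,
                   lysosomal_signal_mean = 2000, n_puncta_mean = 5,
                   heterogeneity_sdlog = 1e-9, seed = 21)
  sc <- generate_cls_scene(sp)
  res <- lysosomal_lamp1_per_cell(sc$stack)
  truth <- sum(sc$truth$cells$true_lysosomal_signal) / 3
  expect_equal(res$signal_per_cell, truth, tolerance = 0.1)
})

test_that("pipeline results match the pixel-arithmetic oracle", {
  sp <- scene_spec(image_shape = c(128, 128), n_macrophages = 3,
                   n_adipocytes = 1, noise_sd = 4,
                   permeable_fraction = 0.4, seed = 17)
  sc <- generate_cls_scene(sp)
  params <- quant_params(nuclei_mode = "all")
  got <- surface_lamp1_per_cell(sc$stack, params)
  ref <- oracle_lamp1(sc$stack, exclude_permeable = TRUE, nuclei_mode = "all")
  expect_equal(got$total_signal, ref$total, tolerance = 1e-8)
  expect_equal(got$cell_count, ref$cells)
})

test_that("pipeline output is invariant to channel ordering", {
  sp <- scene_spec(n_macrophages = 3, n_adipocytes = 1, noise_sd = 3, seed = 19)
  sc <- generate_cls_scene(sp)
  shuffled <- channel_stack(sc$stack$channels[c("Cy5", "DAPI", "FITC", "Cy3")],
                            pixel_size = sc$stack$pixel_size)
  a <- surface_lamp1_per_cell(sc$stack)
  b <- surface_lamp1_per_cell(shuffled)
  expect_identical(a$signal_per_cell, b$signal_per_cell)
})

test_that("smoothing before thresholding does not fragment a two-level mask", {
  img <- make_disc(c(64, 64), c(32, 32), 10, 100)
  raw_n <- max(label_components(img > 50, 8))
  smooth_n <- max(label_components(
    as.matrix(threshold_mask(gaussian_smooth(img, 5), "otsu")), 8))
  expect_lte(smooth_n, raw_n)
})

test_that("classify_permeable recovers ground-truth flags at zero noise", {
  sp <- scene_spec(image_shape = c(480, 480), n_macrophages = 40,
                   n_adipocytes = 5, permeable_fraction = 0.3, noise_sd = 0,
                   seed = 23)
  sc <- generate_cls_scene(sp)
  call <- classify_permeable(sc$stack)
  expect_equal(nrow(call$cells), 40)
  lab <- label_components(
    as.matrix(threshold_mask(gaussian_smooth(sc$stack$channels$FITC, 5), "otsu")),
    8, min_size = 20)
  ids <- match_labels_to_centers(lab, sc$truth$cells[, c("row", "col")])
  expect_identical(call$cells$permeable[ids], sc$truth$cells$permeable)
  expect_equal(call$fraction, mean(sc$truth$cells$permeable))

  # degenerate edges
  sp0 <- modifyList(sp, list(permeable_fraction = 0, image_shape = c(256, 256),
                             n_macrophages = 8, n_adipocytes = 1))
  expect_equal(classify_permeable(generate_cls_scene(sp0)$stack)$fraction, 0)
  sp1 <- modifyList(sp0, list(permeable_fraction = 1))
  expect_equal(classify_permeable(generate_cls_scene(sp1)$stack)$fraction, 1)
})

test_that("missing channels and empty fields raise contract errors", {
  sp <- scene_spec(n_macrophages = 2, n_adipocytes = 1, seed = 3)
  sc <- generate_cls_scene(sp)
  no_cy5 <- channel_stack(sc$stack$channels[c("FITC", "Cy3", "DAPI")])
  expect_error(surface_lamp1_per_cell(no_cy5), "missing channel")
  expect_no_error(lysosomal_lamp1_per_cell(no_cy5))
})
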