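sealed_open_spec <- function(noise_sd = 0, seed = 1) {
  volume_spec(
    volume_shape = c(48, 64, 96), voxel_size_nm = c(20, 10, 10),
    cavities = list(
      list(shape = "box", center = c(16, 20, 48), size = c(4, 4, 4), sealed = TRUE),
      list(shape = "box", center = c(32, 44, 48), size = c(3, 3, 3), sealed = TRUE),
      list(shape = "box", center = c(24, 32, 70), size = c(3, 3, 3), sealed = FALSE)),
    noise_sd = noise_sd, seed = seed)
}

test_that("phase classification reproduces generating phases exactly without noise", {
  gen <- generate_em_volume(sealed_open_spec())
  vol <- classify_phases(gen$volume, thresholds = c(45, 105, 175))
  expect_identical(vol$phases, gen$truth$phases)
  expect_error(classify_phases(gen$volume, thresholds = c(105, 45)), "increasing")
})

test_that("phase recovery stays above 99 percent at 10x contrast-to-noise", {
  # minimum inter-phase gap is 50 AFU; SNR 10 puts the noise SD at 5
  gen <- generate_em_volume(sealed_open_spec(noise_sd = 5, seed = 3))
  vol <- classify_phases(gen$volume, thresholds = c(45, 105, 175))
  expect_gte(mean(vol$phases == gen$truth$phases), 0.99)
})

test_that("thresholds straddling no voxels give an empty lumen phase", {
  gen <- generate_em_volume(volume_spec(cavities = list()))
  vol <- classify_phases(gen$volume, thresholds = c(45, 105, 175))
  expect_false(any(vol$phases == "lumen"))
  cs <- extract_compartments(vol)
  expect_equal(nrow(cs), 0)
})

test_that("sealedness and adjacency single out the lysosomal-synapse candidates", {
  gen <- generate_em_volume(sealed_open_spec())
  cs <- extract_compartments(classify_phases(gen$volume, thresholds = c(45, 105, 175)))
  expect_equal(sum(cs$candidate), 2)
  expect_equal(sum(!cs$sealed), 1)
  truth <- gen$truth$cavities
  expect_setequal(cs$voxel_count[cs$candidate], truth$voxel_count[truth$sealed])
  # physical volumes: count x dz*dy*dx (20 x 10 x 10 nm here)
  expect_equal(cs$volume_nm3, cs$voxel_count * 2000)
  expect_equal(cs$volume_um3, cs$volume_nm3 / 1e9)
  expect_true(all(cs$touches_macrophage[cs$candidate]))
  expect_true(all(cs$touches_adipocyte[cs$candidate]))
})

test_that("a one-voxel channel to a face makes a cavity open", {
  cube <- function(sealed) volume_spec(cavities = list(
    list(shape = "box", center = c(24.5, 32.5, 30.5), size = c(4.5, 4.5, 4.5),
         sealed = sealed)))
  cs_closed <- extract_compartments(
    classify_phases(generate_em_volume(cube(TRUE))$volume, c(45, 105, 175)))
  cs_open <- extract_compartments(
    classify_phases(generate_em_volume(cube(FALSE))$volume, c(45, 105, 175)))
  expect_true(cs_closed$sealed)
  expect_equal(cs_closed$voxel_count, 1000)
  expect_equal(cs_closed$volume_nm3, 1000 * 2000)
  expect_false(any(cs_open$sealed))
})

test_that("compartment_volumes does the unit arithmetic", {
  tbl <- tibble::tibble(id = 1:2, voxel_count = c(1000, 1))
  out <- compartment_volumes(tbl, c(20, 20, 20))
  expect_equal(out$volume_nm3, c(8.0e6, 8000))
  out2 <- compartment_volumes(tbl, c(20, 10, 10))
  expect_equal(out2$volume_nm3[2], 2000)
  expect_equal(out2$volume_um3[1], 2e6 / 1e9)
})

test_that("padding with background never seals a cavity; lumen count is conserved", {
  gen <- generate_em_volume(sealed_open_spec())
  phases <- gen$truth$phases
  cs <- extract_compartments(phases, voxel_size_nm = c(20, 10, 10))
  d <- dim(phases)
  padded <- array("background", d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- phases
  cs_pad <- extract_compartments(padded, voxel_size_nm = c(20, 10, 10))
  expect_equal(sum(cs_pad$sealed), sum(cs$sealed))
  expect_equal(sort(cs_pad$voxel_count), sort(cs$voxel_count))
  # partition: sealed + unsealed voxel counts cover all lumen voxels
  expect_equal(sum(cs$voxel_count), sum(phases == "lumen"))
})

test_that("ellipsoid volumes approach the analytic value on a fine grid", {
  half <- c(10, 14, 12) # >= 20 voxels across each axis
  gen <- generate_em_volume(volume_spec(
    volume_shape = c(64, 64, 64), voxel_size_nm = c(20, 10, 10),
    cavities = list(list(shape = "ellipsoid", center = c(32, 32, 28),
                         size = half, sealed = TRUE))))
  cs <- extract_compartments(gen$truth$phases, c(20, 10, 10))
  analytic <- 4 / 3 * pi * prod(half) * prod(c(20, 10, 10))
  expect_lt(abs(cs$volume_nm3[cs$sealed] - analytic) / analytic, 0.05)
})

test_that("downsampling by two changes recovered volumes by less than 10 percent", {
  half <- c(10, 14, 12)
  gen <- generate_em_volume(volume_spec(
    volume_shape = c(64, 64, 64), voxel_size_nm = c(20, 10, 10),
    cavities = list(list(shape = "ellipsoid", center = c(32, 32, 28),
                         size = half, sealed = TRUE))))
  phases <- gen$truth$phases
  full <- extract_compartments(phases, c(20, 10, 10))
  # shrink by a factor of 2 in X and Y, as in stack preprocessing
  ds <- phases[, seq(1, 64, 2), seq(1, 64, 2)]
  half_res <- extract_compartments(ds, c(20, 20, 20))
  v1 <- full$volume_nm3[full$sealed]
  v2 <- half_res$volume_nm3[half_res$sealed]
  expect_lt(abs(v2 - v1) / v1, 0.10)
})
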