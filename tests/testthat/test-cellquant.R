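paint_ring <- function(m, center, r_out, r_in, level) {
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  m[d2 <= r_out^2 & d2 > r_in^2] <- level
  m
}

test_that("CtB rings are labelled and filled; blank channels yield no cells", {
  expect_warning(lab0 <- label_cells_from_ctb(matrix(5, 64, 64)), "constant")
  expect_equal(max(lab0), 0)

  ctb <- matrix(0, 96, 96)
  centers <- list(c(25, 25), c(25, 70), c(70, 45))
  for (ctr in centers) ctb <- paint_ring(ctb, ctr, 9, 7, 150)
  lab <- label_cells_from_ctb(ctb)
  expect_equal(max(lab), 3)
  # filled areas approximate the disc areas (ring + interior), same for all
  sizes <- tabulate(lab[lab > 0])
  expect_true(all(abs(sizes - pi * 9^2) / (pi * 9^2) < 0.25))
  expect_equal(length(unique(sizes)), 1)

  # two rings sharing a boundary arc merge into one label
  ctb2 <- paint_ring(paint_ring(matrix(0, 96, 96), c(40, 40), 9, 7, 150),
                     c(40, 56), 9, 7, 150)
  expect_equal(max(label_cells_from_ctb(ctb2)), 1)
})

test_that("border-touching cells are excluded by default", {
  ctb <- paint_ring(matrix(0, 64, 64), c(5, 32), 9, 7, 150)
  ctb <- paint_ring(ctb, c(40, 32), 9, 7, 150)
  expect_equal(max(label_cells_from_ctb(ctb)), 1)
  expect_equal(max(label_cells_from_ctb(ctb, exclude_border = FALSE)), 2)
})

test_that("contact_filter follows Euclidean distance and is monotone in radius", {
  cells <- matrix(0L, 40, 40)
  cells[18:22, 6:10] <- 1L     # nearest mask column is 13: 3 px away
  cells[18:22, 30:34] <- 2L    # overlapping the mask
  adip <- matrix(FALSE, 40, 40)
  adip[, 13:31] <- TRUE
  expect_equal(contact_filter(cells, adip, radius_px = 0)$in_contact, c(FALSE, TRUE))
  expect_equal(contact_filter(cells, adip, radius_px = 1)$in_contact, c(FALSE, TRUE))
  expect_equal(contact_filter(cells, adip, radius_px = 3)$in_contact, c(TRUE, TRUE))

  # empty mask: all false
  expect_false(any(contact_filter(cells, matrix(FALSE, 40, 40))$in_contact))

  # monotone: the contact set never shrinks as radius grows
  withr::with_seed(7, {
    rc <- matrix(runif(1600) > 0.8, 40, 40)
  })
  prev <- rep(FALSE, 2)
  for (r in 0:6) {
    cur <- contact_filter(cells, rc, radius_px = r)$in_contact
    expect_true(all(cur | !prev))
    prev <- cur
  }
})

test_that("cell_power is exact, additive over partitions, label-permutation invariant", {
  cells <- matrix(0L, 20, 20)
  cells[2:11, 2:6] <- 1L # 50 px
  sig <- matrix(20, 20, 20)
  expect_equal(cell_power(cells, sig)$power, 1000)
  expect_equal(cell_power(cells, matrix(0, 20, 20))$power, 0)

  withr::with_seed(5, {
    sig2 <- matrix(runif(400, 0, 50), 20, 20)
    split <- cells
    split[cells == 1L & matrix(runif(400) > 0.5, 20, 20)] <- 2L
  })
  whole <- cell_power(cells, sig2)$power
  parts <- cell_power(split, sig2)$power
  expect_equal(sum(parts), whole)

  perm <- cells
  perm[split == 1L] <- 2L; perm[split == 2L] <- 1L
  expect_equal(sort(cell_power(perm, sig2)$power), sort(parts))
})

test_that("region_power is additive and warns on an empty ROI", {
  withr::with_seed(9, sig <- matrix(runif(400, 0, 10), 20, 20))
  full <- matrix(TRUE, 20, 20)
  expect_equal(region_power(full, sig), sum(sig))
  a <- matrix(FALSE, 20, 20); a[1:10, ] <- TRUE
  b <- !a
  expect_equal(region_power(a, sig) + region_power(b, sig), sum(sig))
  expect_warning(z <- region_power(matrix(FALSE, 20, 20), sig), "empty ROI")
  expect_equal(z, 0)
})

test_that("uptake pipeline recovers painted truths and ground-truth contact flags", {
  truths <- c(100, 0, 250)
  flags <- c(TRUE, FALSE, TRUE)
  up <- generate_uptake_scene(truths, flags, seed = 2)
  cells <- label_cells_from_ctb(up$stack$channels$CtB)
  ids <- match_labels_to_centers(cells, up$truth$cells[, c("row", "col")])
  pw <- cell_power(cells, up$stack$channels$Alexa546)
  expect_equal(pw$power[ids], truths, tolerance = 1e-9)

  adip <- adipocyte_mask_from_channel(up$stack$channels$Adipocyte,
                                      largest_only = TRUE)
  contact <- contact_filter(cells, adip, radius_px = 1)
  expect_equal(contact$in_contact[ids], flags)

  # gated quantification keeps exactly the contacting cells
  q <- quantify_uptake(up$stack)
  expect_equal(sort(q$power), sort(truths[flags]), tolerance = 1e-9)
})

test_that("positivity rules flag cells and fractions as specified", {
  expect_equal(positivity(c(0, 0, 10, 10), "fixed", threshold = 5)$fraction, 0.5)
  expect_equal(positivity(c(1, 2, 3), "fixed", threshold = 5)$fraction, 0)
  expect_error(positivity(c(1, 2), "mad"), "control")
  call <- positivity(tibble::tibble(power = c(1, 2, 50)), "mad",
                     control = c(1, 1.5, 2, 2.5, 1.2))
  expect_equal(call$cells$positive, c(FALSE, FALSE, TRUE))
  expect_s3_class(tidy(call), "tbl_df")
})

test_that("adaptive foam-cell calling recovers a known mixture fraction", {
  res <- simulate_foam_experiment(n_cells = 200, positive_fraction = 0.6, seed = 31)
  ci <- qbinom(c(0.025, 0.975), 200, 0.6) / 200
  expect_gte(res$fraction, ci[1] - 0.02)
  expect_lte(res$fraction, ci[2] + 0.02)
})

test_that("surface LAMP-1 in culture recovers painted ring totals", {
  sh <- c(96, 96)
  ctb <- matrix(0, sh[1], sh[2]); lamp <- matrix(0, sh[1], sh[2])
  centers <- list(c(30, 30), c(30, 66), c(66, 48))
  totals <- c(500, 0, 1200)
  for (i in seq_along(centers)) {
    ctb <- paint_ring(ctb, centers[[i]], 9, 7, 150)
    if (totals[i] > 0) {
      n_px <- sum(paint_ring(matrix(0, sh[1], sh[2]), centers[[i]], 6, 4, 1))
      lamp <- lamp + paint_ring(matrix(0, sh[1], sh[2]), centers[[i]], 6, 4,
                                totals[i] / n_px)
    }
  }
  stack <- channel_stack(list(CtB = ctb, LAMP1 = lamp))
  pw <- surface_lamp1_culture(stack)
  ids <- match_labels_to_centers(
    label_cells_from_ctb(ctb), do.call(rbind, centers))
  expect_equal(pw$power[ids], totals, tolerance = 1e-9)
})

test_that("a generated treated-vs-control LAMP-1 contrast is recovered per cell", {
  res <- simulate_lamp1_experiment(n_cells = 16, fold_change = 5, snr = 10, seed = 41)
  expect_lt(abs(res$fold_per_cell - 5) / 5, 0.35) # single seed, n = 16
  expect_lt(res$p_value, 0.01)
})
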