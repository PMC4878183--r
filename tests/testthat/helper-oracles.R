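# Independent brute-force oracles. These deliberately avoid the package's
# vectorized/compiled code paths: dense loops, direct definitions.

# dense 2D convolution with reflective padding (no separability)
oracle_convolve <- function(image, taps) {
  r <- (length(taps) - 1) / 2
  kern <- outer(taps, taps)
  n <- nrow(image); m <- ncol(image)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + kern[di + r + 1, dj + r + 1] *
        image[reflect(i + di, n), reflect(j + dj, m)]
    }
    out[i, j] <- acc
  }
  out
}

# exact Otsu from the definition: explicit loop over the midpoints between
# consecutive distinct values, recomputing class means directly
oracle_otsu <- function(image) {
  x <- as.vector(image)
  u <- sort(unique(x))
  best <- -Inf
  thr <- NA_real_
  for (j in seq_len(length(u) - 1)) {
    t <- (u[j] + u[j + 1]) / 2
    lo <- x[x <= t]
    hi <- x[x > t]
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best) {
      best <- bc
      thr <- t
    }
  }
  thr
}

# pure-R flood-fill connected components (recursion-free BFS), 2D/3D
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  if (length(d) == 2) { mask <- array(mask, c(d, 1)); d3 <- c(d, 1) } else d3 <- d
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    m <- abs(dz) + abs(dy) + abs(dx)
    if (m == 0) next
    if (connectivity %in% c(4, 6) && m > 1) next
    if (connectivity == 18 && m > 2) next
    offs[[length(offs) + 1]] <- c(dz, dy, dx)
  }
  lab <- array(0L, d3)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      z <- (i - 1) %% d3[1] + 1
      y <- ((i - 1) %/% d3[1]) %% d3[2] + 1
      x <- (i - 1) %/% (d3[1] * d3[2]) + 1
      for (o in offs) {
        zz <- z + o[1]; yy <- y + o[2]; xx <- x + o[3]
        if (zz < 1 || zz > d3[1] || yy < 1 || yy > d3[2] || xx < 1 || xx > d3[3]) next
        j <- (xx - 1) * d3[1] * d3[2] + (yy - 1) * d3[1] + zz
        if (mask[j] && lab[j] == 0) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  array(lab, d)
}

# rank-sum exact two-sided p by recursive subset enumeration over midranks
oracle_rank_sum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); n <- length(r)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  sums <- c()
  pick <- function(start, k, acc) {
    if (k == 0) { sums <<- c(sums, acc); return(invisible()) }
    for (i in start:(n - k + 1)) pick(i + 1, k - 1, acc + r[i])
  }
  pick(1, na, 0)
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}

# pixel-arithmetic re-implementation of the tissue LAMP-1 quantification,
# written from the pipeline definition (masks as plain comparisons)
oracle_lamp1 <- function(stack, exclude_permeable, nuclei_mode = "fitc_gated",
                         subtract_background = TRUE) {
  sm <- function(ch) oracle_convolve(get_channel(stack, ch), c(1, 4, 6, 4, 1) / 16)
  fitc <- sm("FITC")
  mask <- fitc > oracle_otsu(fitc)
  if (exclude_permeable) {
    cy5 <- sm("Cy5")
    cy5_mask <- if (diff(range(cy5)) > 0) cy5 > oracle_otsu(cy5) else cy5 > Inf
    combined <- mask & !cy5_mask
  } else combined <- mask
  cy3 <- sm("Cy3")
  bg <- if (subtract_background && any(!mask)) median(cy3[!mask]) else 0
  total <- sum(cy3[combined] - bg)

  dapi <- sm("DAPI")
  dmask <- if (diff(range(dapi)) > 0) dapi > oracle_otsu(dapi) else dapi > Inf
  lab <- oracle_label(dmask, 8)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  ids <- ids[vapply(ids, function(i) sum(lab == i) >= 5, logical(1))]
  count <- 0L
  within <- if (nuclei_mode == "fitc_gated") combined else NULL
  for (i in ids) {
    if (is.null(within)) { count <- count + 1L; next }
    px <- which(lab == i)
    rr <- round(mean((px - 1) %% nrow(lab) + 1))
    cc <- round(mean((px - 1) %/% nrow(lab) + 1))
    if (within[rr, cc]) count <- count + 1L
  }
  list(total = total, cells = count,
       per_cell = if (count > 0) total / count else NA_real_)
}

# small random test stack: a few discs per channel on a background
random_test_stack <- function(seed, shape = c(64, 64)) {
  withr::with_seed(seed, {
    mk <- function(n_blobs, lvl, bg) {
      m <- matrix(bg, shape[1], shape[2])
      for (i in seq_len(n_blobs)) {
        ctr <- runif(2, 10, shape - 10)
        rad <- runif(1, 3, 6)
        rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
        cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
        m[(rows - ctr[1])^2 + (cols - ctr[2])^2 <= rad^2] <- lvl * runif(1, 0.8, 1.2)
      }
      pmax(m + matrix(rnorm(prod(shape), 0, 2), shape[1], shape[2]), 0)
    }
    channel_stack(list(FITC = mk(4, 150, 10), Cy3 = mk(5, 120, 10),
                       DAPI = mk(4, 200, 5), Cy5 = mk(2, 180, 10)))
  })
}

sidecar_path_t <- function(path) paste0(path, ".yaml")
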