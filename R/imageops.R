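#' Gaussian smoothing with a normalized separable kernel
#'
#' Smooths an intensity image with an N x N discrete Gaussian, the
#' pre-filtering step applied before every thresholding operation in the
#' quantification pipelines (5 x 5 for immunofluorescence channels, 7 x 7 for
#' ratiometric pH channels). The default taps are the normalized binomial
#' coefficients (5-tap `[1,4,6,4,1]/16`, 7-tap `[1,6,15,20,15,6,1]/64`), the
#' standard discrete approximation of an N x N Gaussian; an explicit `sigma`
#' switches to sampled Gaussian taps. Boundaries are handled by reflective
#' padding, so a constant image is exactly preserved and total intensity of
#' interior-supported signals is conserved.
#'
#' @param image numeric matrix (AFU).
#' @param kernel_px odd kernel width in pixels (3, 5, 7, ...).
#' @param sigma optional Gaussian standard deviation in pixels; when `NULL`
#'   (default) binomial taps are used.
#' @return Smoothed matrix of the same dimension.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 1
#' sum(gaussian_smooth(m, 5)) # == 1, kernel is normalized
#' @export
gaussian_smooth <- function(image, kernel_px = 5, sigma = NULL) {
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    abort("`image` must be a finite numeric matrix.")
  if (length(kernel_px) != 1 || kernel_px < 1 || kernel_px %% 2 != 1)
    abort("`kernel_px` must be a single odd integer (3, 5, 7, ...).")
  taps <- kernel_taps(kernel_px, sigma)
  sep_convolve(sep_convolve(image, taps, by_row = FALSE), taps, by_row = TRUE)
}

kernel_taps <- function(kernel_px, sigma = NULL) {
  if (is.null(sigma)) {
    t <- choose(kernel_px - 1, 0:(kernel_px - 1))
  } else {
    if (sigma <= 0) abort("`sigma` must be positive.")
    r <- (kernel_px - 1) / 2
    t <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  }
  t / sum(t)
}

# 1D convolution along columns (by_row = FALSE) or rows with reflective
# padding; vectorized as a weighted sum of shifted copies.
sep_convolve <- function(image, taps, by_row) {
  r <- (length(taps) - 1L) / 2L
  n <- if (by_row) ncol(image) else nrow(image)
  if (n == 1L) return(image)
  # reflect indices (edge pixel not repeated: ..3,2 | 1,2,3.. style)
  idx <- c(rev(seq_len(min(r, n - 1)) + 1L), seq_len(n),
           n - seq_len(min(r, n - 1)))
  # if n - 1 < r, extend by cycling reflection
  while (length(idx) < n + 2L * r) idx <- c(idx[1], idx, idx[length(idx)])
  padded <- if (by_row) image[, idx, drop = FALSE] else image[idx, , drop = FALSE]
  out <- matrix(0, nrow(image), ncol(image))
  for (k in seq_along(taps)) {
    sl <- (k - 1L) + seq_len(n)
    out <- out + taps[k] *
      (if (by_row) padded[, sl, drop = FALSE] else padded[sl, , drop = FALSE])
  }
  out
}

#' Binary mask from intensity thresholding
#'
#' Creates the binary masks used throughout the mask-algebra quantification
#' (e.g. the F4/80 mask selecting macrophages, the calnexin mask flagging
#' permeable cells). A pixel is in the mask when its intensity is strictly
#' greater than the threshold. Methods: `"otsu"` (exact between-class
#' variance maximization over the empirical intensities, no histogram
#' binning — the default since the original analysis does not state its
#' thresholds), `"fixed"` (user value), and
#' `"quantile"` (threshold at the q-quantile of pixel intensities). The
#' threshold actually used is recorded on the mask for provenance.
#'
#' @param image numeric matrix (AFU), typically pre-smoothed.
#' @param method `"otsu"`, `"fixed"` or `"quantile"`.
#' @param value threshold (AFU) for `"fixed"`, or probability in (0,1) for
#'   `"quantile"`.
#' @param source_channel optional channel name recorded for provenance.
#' @return A `binary_mask`: logical matrix with attributes `threshold` and
#'   `source_channel`.
#' @export
threshold_mask <- function(image, method = c("otsu", "fixed", "quantile"),
                           value = NULL, source_channel = NA_character_) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image))
    abort("`image` must be a numeric matrix.")
  thr <- switch(method,
    otsu = {
      if (diff(range(image)) == 0)
        abort(paste("Otsu thresholding is undefined on a constant image;",
                    "use method = 'fixed' with an explicit threshold."))
      otsu_threshold(image)
    },
    fixed = {
      if (is.null(value)) abort("method = 'fixed' requires `value` (AFU).")
      value
    },
    quantile = {
      if (is.null(value) || value <= 0 || value >= 1)
        abort("method = 'quantile' requires `value` in (0, 1).")
      as.numeric(quantile(image, probs = value, names = FALSE))
    })
  new_binary_mask(image > thr, threshold = thr, source_channel = source_channel)
}

# exact Otsu on the empirical intensity distribution: between-class variance
# is maximized over every split between consecutive distinct values (no
# histogram binning, so the optimum is well-defined and reproducible); the
# threshold is the midpoint of the straddling values
otsu_threshold <- function(image) {
  v <- sort(as.vector(image))
  n <- length(v)
  cs <- cumsum(v)
  i <- seq_len(n - 1)
  w1 <- as.numeric(i)
  w2 <- as.numeric(n - i)
  mu1 <- cs[i] / w1
  mu2 <- (cs[n] - cs[i]) / w2
  bcv <- w1 * w2 * (mu1 - mu2)^2
  valid <- which(v[i] < v[i + 1])
  k <- valid[which.max(bcv[valid])]
  (v[k] + v[k + 1]) / 2
}

new_binary_mask <- function(pixels, threshold = NA_real_,
                            source_channel = NA_character_) {
  structure(pixels, threshold = threshold, source_channel = source_channel,
            class = c("binary_mask", class(pixels)))
}

#' Mask algebra
#'
#' Boolean complement and conjunction of binary masks, the primitives from
#' which the gating pipelines are composed (e.g. FITC mask AND NOT Cy5 mask
#' to select intact macrophages). Threshold provenance of operands is dropped
#' on combination.
#'
#' @param mask,a,b logical matrices ([threshold_mask()] output or any logical
#'   matrix of matching shape).
#' @return A `binary_mask`.
#' @export
mask_invert <- function(mask) {
  check_mask(mask)
  new_binary_mask(!unclass_mask(mask))
}

#' @rdname mask_invert
#' @export
mask_and <- function(a, b) {
  check_mask(a); check_mask(b)
  if (!identical(dim(a), dim(b)))
    abort("mask shapes do not match.")
  new_binary_mask(unclass_mask(a) & unclass_mask(b))
}

check_mask <- function(m) {
  if (!is.matrix(m) || !is.logical(m))
    abort("masks must be logical matrices.")
  invisible(m)
}

unclass_mask <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

#' Connected-component labelling
#'
#' Labels connected foreground regions of a 2D mask or 3D volume. Default
#' connectivity is 8 in 2D (diagonal neighbours connect) and 26 in 3D, the
#' strictest setting for sealedness testing where a single diagonal gap counts
#' as a leak. Components smaller than `min_size` (pixels/voxels) are removed
#' and labels compacted to 1..n.
#'
#' @param mask logical matrix or 3D logical array.
#' @param connectivity 4 or 8 (2D); 6, 18 or 26 (3D).
#' @param min_size minimum component size kept.
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3) 26 else 8,
                             min_size = 0) {
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% 2:3)
    abort("`mask` must be a 2D matrix or 3D array.")
  if (length(d) == 2) {
    if (!connectivity %in% c(4, 8)) abort("2D connectivity must be 4 or 8.")
    conn3 <- if (connectivity == 4) 6L else 26L
    dims <- c(d, 1L)
  } else {
    if (!connectivity %in% c(6, 18, 26)) abort("3D connectivity must be 6, 18 or 26.")
    conn3 <- as.integer(connectivity)
    dims <- d
  }
  lab <- cc_label_cpp(as.logical(mask), as.integer(dims), conn3)
  dim(lab) <- d
  if (min_size > 0 && max(lab) > 0) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_size)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[] <- ifelse(lab > 0, remap[pmax(lab, 1)], 0L)
  }
  lab
}
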