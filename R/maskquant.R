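#' Count nuclei in a DAPI channel
#'
#' Smooths the DAPI channel, thresholds it, and counts 8-connected components
#' exceeding a minimum area. Two nuclei merged by a bridge of foreground
#' pixels count as one (documented behaviour; a watershed split is optional
#' and off by default because the per-field denominator tolerates occasional
#' merges better than over-segmentation).
#'
#' @param dapi numeric matrix, DAPI intensities (AFU).
#' @param min_area_px minimum nucleus area in pixels (>= 1).
#' @param kernel_px smoothing kernel width before thresholding.
#' @param method,value thresholding rule passed to [threshold_mask()].
#' @param within optional logical matrix; only nuclei whose centroid falls
#'   inside this mask are counted (used to restrict the denominator to
#'   F4/80-positive cells).
#' @param watershed if `TRUE`, split merged nuclei by a distance-transform
#'   watershed before counting.
#' @return Integer nucleus count (0 when nothing is above threshold).
#' @export
count_nuclei <- function(dapi, min_area_px = 5, kernel_px = 5,
                         method = "otsu", value = NULL, within = NULL,
                         watershed = FALSE) {
  if (min_area_px < 1) abort("`min_area_px` must be >= 1.")
  sm <- gaussian_smooth(dapi, kernel_px)
  if (diff(range(sm)) == 0) return(0L)
  mask <- threshold_mask(sm, method, value, source_channel = "DAPI")
  if (!any(mask)) return(0L)
  if (watershed) {
    dist <- EBImage::distmap(unclass_mask(mask) * 1)
    lab <- EBImage::imageData(EBImage::watershed(dist))
    sizes <- tabulate(lab)
    lab[lab > 0 & sizes[pmax(lab, 1)] < min_area_px] <- 0L
  } else {
    lab <- label_components(unclass_mask(mask), connectivity = 8,
                            min_size = min_area_px)
  }
  ids <- unique(lab[lab > 0])
  if (length(ids) == 0) return(0L)
  if (!is.null(within)) {
    cent <- component_centroids(lab)
    inside <- within[cbind(pmin(pmax(round(cent$row), 1), nrow(within)),
                           pmin(pmax(round(cent$col), 1), ncol(within)))]
    return(as.integer(sum(inside)))
  }
  length(ids)
}

component_centroids <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(tibble::tibble(label = integer(), row = numeric(), col = numeric()))
  lb <- lab[idx]
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  tibble::tibble(
    label = sort(unique(lb)),
    row = as.numeric(tapply(rows, lb, mean)),
    col = as.numeric(tapply(cols, lb, mean))
  )
}

#' Quantification parameters for tissue mask-algebra pipelines
#'
#' @param kernel_px Gaussian pre-filter width (pixels); the tissue analysis
#'   uses 5.
#' @param threshold_method,threshold_value thresholding rule for the gating
#'   channels (see [threshold_mask()]).
#' @param min_nucleus_px minimum nucleus area for the DAPI count.
#' @param nuclei_mode `"fitc_gated"` counts only nuclei inside the F4/80 mask
#'   (macrophage nuclei); `"all"` counts every DAPI nucleus in the field.
#' @param subtract_background estimate the Cy3 background as the median
#'   smoothed Cy3 intensity outside the F4/80 mask and subtract it per pixel
#'   before summing (local background correction, standard in quantitative
#'   immunofluorescence; makes per-cell totals unbiased under a constant
#'   offset). Set `FALSE` for raw masked sums.
#' @return A named list of parameters.
#' @export
quant_params <- function(kernel_px = 5, threshold_method = "otsu",
                         threshold_value = NULL, min_nucleus_px = 5,
                         nuclei_mode = c("fitc_gated", "all"),
                         subtract_background = TRUE) {
  list(kernel_px = kernel_px, threshold_method = threshold_method,
       threshold_value = threshold_value, min_nucleus_px = min_nucleus_px,
       nuclei_mode = match.arg(nuclei_mode),
       subtract_background = subtract_background)
}

#' Per-cell surface and lysosomal LAMP-1 from tissue immunofluorescence
#'
#' Implements the crown-like-structure tissue quantification: all channels are
#' smoothed with a 5 x 5 Gaussian; a binary mask from the FITC (F4/80) channel
#' selects macrophage-occupied pixels; for the surface variant it is
#' multiplied by the inverted Cy5 (calnexin) mask so that permeable cells,
#' whose endoplasmic reticulum is antibody-accessible, are excluded; the
#' combined mask is applied to the Cy3 (LAMP-1) channel and the masked Cy3
#' total is divided by the number of nuclei in the field to give average
#' LAMP-1 per cell. `lysosomal_lamp1_per_cell()` is the permeabilized-tissue
#' variant without the calnexin exclusion.
#'
#' @param stack a [channel_stack()] with channels `FITC`, `Cy3`, `DAPI` and
#'   (for the surface variant) `Cy5`.
#' @param params a [quant_params()] list.
#' @return A `per_cell_result`: list with `total_signal` (AFU), `cell_count`,
#'   `signal_per_cell` (AFU/cell) and a `gating` record of masks/thresholds.
#'   Use [tidy()] for a one-row tibble.
#' @export
surface_lamp1_per_cell <- function(stack, params = quant_params()) {
  lamp1_pipeline(stack, params, exclude_permeable = TRUE,
                 metric = "surface_lamp1_per_cell")
}

#' @rdname surface_lamp1_per_cell
#' @export
lysosomal_lamp1_per_cell <- function(stack, params = quant_params()) {
  lamp1_pipeline(stack, params, exclude_permeable = FALSE,
                 metric = "lysosomal_lamp1_per_cell")
}

lamp1_pipeline <- function(stack, params, exclude_permeable, metric) {
  stopifnot(inherits(stack, "channel_stack"))
  need <- c("FITC", "Cy3", "DAPI", if (exclude_permeable) "Cy5")
  missing <- setdiff(need, channel_names(stack))
  if (length(missing))
    abort(paste("stack is missing channel(s):", paste(missing, collapse = ", ")))

  k <- params$kernel_px
  fitc_sm <- gaussian_smooth(get_channel(stack, "FITC"), k)
  mask_fitc <- threshold_mask(fitc_sm, params$threshold_method,
                              params$threshold_value, source_channel = "FITC")
  combined <- mask_fitc
  thr_cy5 <- NA_real_
  if (exclude_permeable) {
    cy5_sm <- gaussian_smooth(get_channel(stack, "Cy5"), k)
    # a blank calnexin channel excludes nothing
    if (diff(range(cy5_sm)) == 0) {
      mask_cy5 <- new_binary_mask(matrix(FALSE, nrow(cy5_sm), ncol(cy5_sm)),
                                  threshold = Inf, source_channel = "Cy5")
    } else {
      mask_cy5 <- threshold_mask(cy5_sm, params$threshold_method,
                                 params$threshold_value, source_channel = "Cy5")
    }
    thr_cy5 <- attr(mask_cy5, "threshold")
    combined <- mask_and(mask_fitc, mask_invert(mask_cy5))
  }

  cy3_sm <- gaussian_smooth(get_channel(stack, "Cy3"), k)
  bg <- 0
  if (isTRUE(params$subtract_background)) {
    outside <- !unclass_mask(mask_fitc)
    if (any(outside)) bg <- median(cy3_sm[outside])
  }
  inside <- unclass_mask(combined)
  total <- sum(cy3_sm[inside] - bg)

  # nuclei are counted inside the same mask the signal is summed over, so the
  # per-cell average covers exactly the analysed (gated) cells
  within <- if (params$nuclei_mode == "fitc_gated") unclass_mask(combined)
  cells <- count_nuclei(get_channel(stack, "DAPI"),
                        min_area_px = params$min_nucleus_px,
                        kernel_px = k, method = params$threshold_method,
                        value = params$threshold_value, within = within)
  if (cells == 0)
    abort("no cells detected in the field (DAPI nucleus count is zero).")

  structure(list(
    total_signal = total,
    cell_count = cells,
    signal_per_cell = total / cells,
    metric = metric,
    gating = list(mask_fitc = mask_fitc,
                  combined = combined,
                  threshold_fitc = attr(mask_fitc, "threshold"),
                  threshold_cy5 = thr_cy5,
                  background = bg,
                  kernel_px = k,
                  nuclei_mode = params$nuclei_mode)),
    class = "per_cell_result")
}

#' @export
print.per_cell_result <- function(x, ...) {
  cat("<per_cell_result> ", x$metric, "\n", sep = "")
  cat(sprintf("  total %.4g AFU over %d cells = %.4g AFU/cell\n",
              x$total_signal, x$cell_count, x$signal_per_cell))
  invisible(x)
}

#' @export
tidy.per_cell_result <- function(x, ...) {
  tibble::tibble(metric = x$metric,
                 total_signal = x$total_signal,
                 cell_count = x$cell_count,
                 signal_per_cell = x$signal_per_cell,
                 threshold_fitc = x$gating$threshold_fitc,
                 threshold_cy5 = x$gating$threshold_cy5)
}

#' Classify permeable macrophages by calnexin signal
#'
#' Flags each macrophage region whose mean Cy5 (calnexin) intensity exceeds a
#' threshold as permeable; such cells are excluded from surface-LAMP-1
#' analysis because antibody access to the endoplasmic reticulum shows the
#' plasma membrane is compromised. Per-cell regions are the 8-connected
#' components of the smoothed, thresholded FITC (F4/80) channel.
#'
#' @param stack a [channel_stack()] with `FITC` and `Cy5` channels.
#' @param params a [quant_params()] list.
#' @param min_cell_px minimum region area treated as a cell.
#' @return A `permeability_call`: list with `cells` (tibble: `cell_id`,
#'   `cy5_mean`, `permeable`), `fraction` (share of permeable cells) and the
#'   Cy5 threshold used.
#' @export
classify_permeable <- function(stack, params = quant_params(), min_cell_px = 20) {
  stopifnot(inherits(stack, "channel_stack"))
  missing <- setdiff(c("FITC", "Cy5"), channel_names(stack))
  if (length(missing))
    abort(paste("stack is missing channel(s):", paste(missing, collapse = ", ")))
  k <- params$kernel_px
  fitc_sm <- gaussian_smooth(get_channel(stack, "FITC"), k)
  mask_fitc <- threshold_mask(fitc_sm, params$threshold_method,
                              params$threshold_value, source_channel = "FITC")
  lab <- label_components(unclass_mask(mask_fitc), 8, min_size = min_cell_px)
  n <- max(lab)
  if (n == 0) abort("no cells detected from the FITC channel.")

  cy5_sm <- gaussian_smooth(get_channel(stack, "Cy5"), k)
  if (diff(range(cy5_sm)) == 0) {
    thr <- Inf
  } else {
    thr <- attr(threshold_mask(cy5_sm, params$threshold_method,
                               params$threshold_value), "threshold")
  }
  idx <- which(lab > 0)
  means <- as.numeric(tapply(cy5_sm[idx], lab[idx], mean))
  cells <- tibble::tibble(cell_id = seq_len(n),
                          cy5_mean = means,
                          permeable = means > thr)
  structure(list(cells = cells,
                 fraction = mean(cells$permeable),
                 threshold_cy5 = thr),
            class = "permeability_call")
}

#' @export
print.permeability_call <- function(x, ...) {
  cat(sprintf("<permeability_call> %d cells, %.1f%% permeable (Cy5 > %.4g)\n",
              nrow(x$cells), 100 * x$fraction, x$threshold_cy5))
  invisible(x)
}

#' @export
tidy.permeability_call <- function(x, ...) x$cells

#' Per-macrophage surface LAMP-1 from tissue immunofluorescence
#'
#' Per-cell resolution variant of [surface_lamp1_per_cell()] for
#' distributional comparisons: macrophage regions are the 8-connected
#' components of the smoothed, thresholded FITC channel; permeable cells
#' (region Cy5 mean above threshold) are excluded; the background-corrected
#' smoothed Cy3 signal is summed within each remaining region.
#'
#' @param stack a [channel_stack()] with `FITC`, `Cy3` and optionally `Cy5`.
#' @param params a [quant_params()] list.
#' @param min_cell_px minimum region area treated as a cell.
#' @return Tibble with `cell_id`, `surface_lamp1` (AFU) and `permeable`;
#'   permeable cells carry `NA` signal and are retained for bookkeeping.
#' @export
surface_lamp1_per_macrophage <- function(stack, params = quant_params(),
                                         min_cell_px = 20) {
  stopifnot(inherits(stack, "channel_stack"))
  k <- params$kernel_px
  fitc_sm <- gaussian_smooth(get_channel(stack, "FITC"), k)
  mask_fitc <- threshold_mask(fitc_sm, params$threshold_method,
                              params$threshold_value, source_channel = "FITC")
  lab <- label_components(unclass_mask(mask_fitc), 8, min_size = min_cell_px)
  n <- max(lab)
  if (n == 0) abort("no cells detected from the FITC channel.")

  permeable <- rep(FALSE, n)
  if ("Cy5" %in% channel_names(stack)) {
    cy5_sm <- gaussian_smooth(get_channel(stack, "Cy5"), k)
    if (diff(range(cy5_sm)) > 0) {
      thr <- attr(threshold_mask(cy5_sm, params$threshold_method,
                                 params$threshold_value), "threshold")
      idx <- which(lab > 0)
      means <- as.numeric(tapply(cy5_sm[idx], lab[idx], mean))
      permeable <- means > thr
    }
  }

  cy3_sm <- gaussian_smooth(get_channel(stack, "Cy3"), k)
  bg <- 0
  if (isTRUE(params$subtract_background)) {
    outside <- lab == 0
    if (any(outside)) bg <- median(cy3_sm[outside])
  }
  pw <- cell_power(lab, cy3_sm - bg)
  tibble::tibble(cell_id = pw$cell_id,
                 surface_lamp1 = ifelse(permeable, NA_real_, pw$power),
                 permeable = permeable)
}
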