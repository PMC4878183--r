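#' Label macrophages from CtB surface staining
#'
#' Identifies individual cells in the culture model from the Alexa488-CtB
#' plasma-membrane stain: the channel is smoothed and thresholded, enclosed
#' interiors of the resulting membrane rings are filled, 8-connected
#' components are labelled, and small components are discarded. Two cells
#' whose rings share a boundary arc merge into one label (documented
#' behaviour). Cells touching the image border are excluded by default since
#' partial cells bias integrated power.
#'
#' @param ctb numeric matrix, CtB channel (AFU).
#' @param kernel_px smoothing width before thresholding.
#' @param method,value thresholding rule (see [threshold_mask()]).
#' @param min_area_px minimum filled cell area kept.
#' @param exclude_border drop labels touching the image border.
#' @return A `cell_label_map`: integer matrix (0 = background) with provenance
#'   attributes `threshold` and `params`. Zero labels yields an empty map with
#'   a warning.
#' @export
label_cells_from_ctb <- function(ctb, kernel_px = 5, method = "otsu",
                                 value = NULL, min_area_px = 20,
                                 exclude_border = TRUE) {
  sm <- gaussian_smooth(ctb, kernel_px)
  if (diff(range(sm)) == 0) {
    warn("CtB channel is constant; no cells labelled.")
    return(new_cell_label_map(matrix(0L, nrow(ctb), ncol(ctb)), NA_real_))
  }
  mask <- threshold_mask(sm, method, value, source_channel = "CtB")
  filled <- EBImage::imageData(EBImage::fillHull(unclass_mask(mask) * 1)) > 0
  lab <- label_components(filled, connectivity = 8, min_size = min_area_px)
  if (exclude_border && max(lab) > 0) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_labels <- setdiff(border_labels, 0L)
    if (length(border_labels)) {
      lab[lab %in% border_labels] <- 0L
      lab <- compact_labels(lab)
    }
  }
  if (max(lab) == 0) warn("no cells found in the CtB channel.")
  new_cell_label_map(lab, attr(mask, "threshold"),
                     params = list(kernel_px = kernel_px, method = method,
                                   min_area_px = min_area_px,
                                   exclude_border = exclude_border))
}

new_cell_label_map <- function(lab, threshold, params = list()) {
  structure(lab, threshold = threshold, params = params,
            class = c("cell_label_map", class(lab)))
}

compact_labels <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0 || identical(ids, seq_along(ids))) return(lab)
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d x %d px, %d cells (threshold %.4g)\n",
              nrow(x), ncol(x), max(x), attr(x, "threshold")))
  invisible(x)
}

#' Gate cells on adipocyte contact
#'
#' Flags each labelled cell as in contact with an adipocyte when its pixels
#' come within `radius_px` (Euclidean) of the adipocyte mask; radius 0
#' requires overlap, the default radius 1 direct adjacency. The contact set
#' never shrinks as the radius grows. Uptake and foam-cell readouts quantify
#' only contacting macrophages, which suppresses signal from free-floating
#' adipocyte debris internalized by ordinary endocytosis.
#'
#' @param cells a [label_cells_from_ctb()] map (or integer label matrix).
#' @param adipocyte_mask logical matrix marking adipocyte pixels.
#' @param radius_px contact radius in pixels (>= 0).
#' @return Tibble with `cell_id` and `in_contact`.
#' @export
contact_filter <- function(cells, adipocyte_mask, radius_px = 1) {
  if (!identical(dim(cells), dim(adipocyte_mask)))
    abort("label map and adipocyte mask shapes do not match.")
  if (radius_px < 0) abort("`radius_px` must be >= 0.")
  n <- max(cells)
  if (n == 0) return(tibble::tibble(cell_id = integer(), in_contact = logical()))
  if (!any(adipocyte_mask)) {
    return(tibble::tibble(cell_id = seq_len(n), in_contact = FALSE))
  }
  # distance from every pixel to the nearest adipocyte pixel (0 on the mask)
  dist <- EBImage::imageData(EBImage::distmap((!adipocyte_mask) * 1))
  idx <- which(cells > 0)
  mind <- tapply(dist[idx], cells[idx], min)
  tibble::tibble(cell_id = as.integer(names(mind)),
                 in_contact = as.numeric(mind) <= radius_px) |>
    dplyr::arrange(.data$cell_id)
}

#' Integrated fluorescence power per cell
#'
#' The per-cell uptake metric: the sum of all raw pixel intensities within
#' each cell's boundary. Intensities are deliberately unsmoothed — smoothing
#' redistributes signal across the boundary. Power is additive over any
#' partition of a cell's pixels and invariant to label permutation.
#'
#' @param cells a cell label map (integer matrix, 0 = background).
#' @param signal_channel numeric matrix of the same shape (AFU).
#' @return Tibble with `cell_id` and `power` (AFU), one row per label.
#' @export
cell_power <- function(cells, signal_channel) {
  if (!identical(dim(cells), dim(signal_channel)))
    abort("label map and signal channel shapes do not match.")
  n <- max(cells)
  if (n == 0) return(tibble::tibble(cell_id = integer(), power = numeric()))
  idx <- which(cells > 0)
  sums <- rep(0, n)
  agg <- rowsum(signal_channel[idx], group = cells[idx])
  sums[as.integer(rownames(agg))] <- agg[, 1]
  tibble::tibble(cell_id = seq_len(n), power = sums)
}

#' Integrated fluorescence power in a fixed region of interest
#'
#' Deposition-style readout: total signal within an ROI such as the adipocyte
#' surface band where lysosomal dextran is deposited. Additive over disjoint
#' ROIs.
#'
#' @param roi_mask logical matrix.
#' @param signal_channel numeric matrix of the same shape (AFU).
#' @return Total power (AFU); 0 with a warning for an empty ROI.
#' @export
region_power <- function(roi_mask, signal_channel) {
  if (!identical(dim(roi_mask), dim(signal_channel)))
    abort("ROI mask and signal channel shapes do not match.")
  if (!any(roi_mask)) {
    warn("empty ROI; returning 0.")
    return(0)
  }
  sum(signal_channel[roi_mask])
}

#' Positivity calls from per-cell powers
#'
#' Classifies cells as positive (e.g. foam cells by LipidTOX power) either
#' against a fixed threshold or adaptively at `k` median absolute deviations
#' above the control median — the default rule for calling foam cells when no
#' absolute threshold is known.
#'
#' @param measurements data frame with a `power` column (e.g. [cell_power()]
#'   output), or a numeric vector of powers.
#' @param rule `"fixed"` or `"mad"`.
#' @param threshold power threshold for `rule = "fixed"`.
#' @param control numeric vector of control powers (required for `"mad"`).
#' @param k MAD multiplier for the adaptive rule.
#' @return A `positivity_call`: list with `cells` (input tibble plus
#'   `positive`), `fraction` and the resolved `threshold`.
#' @export
positivity <- function(measurements, rule = c("fixed", "mad"),
                       threshold = NULL, control = NULL, k = 3) {
  rule <- match.arg(rule)
  if (is.numeric(measurements))
    measurements <- tibble::tibble(power = measurements)
  if (!is.data.frame(measurements) || !"power" %in% names(measurements))
    abort("`measurements` must have a `power` column.")
  if (nrow(measurements) == 0) abort("no measurements supplied.")
  thr <- switch(rule,
    fixed = {
      if (is.null(threshold)) abort("rule = 'fixed' requires `threshold`.")
      threshold
    },
    mad = {
      if (is.null(control) || length(control) == 0)
        abort("rule = 'mad' requires a non-empty `control` sample.")
      median(control) + k * stats::mad(control)
    })
  cells <- dplyr::mutate(tibble::as_tibble(measurements),
                         positive = .data$power > thr)
  structure(list(cells = cells, fraction = mean(cells$positive),
                 threshold = thr, rule = rule),
            class = "positivity_call")
}

#' @export
print.positivity_call <- function(x, ...) {
  cat(sprintf("<positivity_call> %d cells, %.1f%% positive (power > %.4g, %s rule)\n",
              nrow(x$cells), 100 * x$fraction, x$threshold, x$rule))
  invisible(x)
}

#' @export
tidy.positivity_call <- function(x, ...) x$cells

#' Per-cell surface LAMP-1 in the culture model
#'
#' Composition of cell labelling and integrated power for the
#' non-permeabilized culture immunostain: cells are delineated from a
#' boundary channel (CtB, or the F4/80 stain) and the raw LAMP-1 channel is
#' summed within each boundary, giving one surface-LAMP-1 power per
#' macrophage.
#'
#' @param stack a [channel_stack()].
#' @param lamp1_channel,boundary_channel channel names.
#' @param ... passed to [label_cells_from_ctb()].
#' @return Tibble with `cell_id` and `power` (AFU).
#' @export
surface_lamp1_culture <- function(stack, lamp1_channel = "LAMP1",
                                  boundary_channel = "CtB", ...) {
  stopifnot(inherits(stack, "channel_stack"))
  cells <- label_cells_from_ctb(get_channel(stack, boundary_channel), ...)
  cell_power(cells, get_channel(stack, lamp1_channel))
}

#' Adipocyte mask from a labelled-adipocyte channel
#'
#' Threshold plus largest-component selection on the channel that labels the
#' adipocyte body, used to build the contact-gating mask in culture scenes.
#'
#' @param adipo_channel numeric matrix (AFU).
#' @param kernel_px,method,value smoothing/threshold parameters.
#' @param largest_only keep only the largest component.
#' @return Logical matrix.
#' @export
adipocyte_mask_from_channel <- function(adipo_channel, kernel_px = 5,
                                        method = "otsu", value = NULL,
                                        largest_only = FALSE) {
  sm <- gaussian_smooth(adipo_channel, kernel_px)
  if (diff(range(sm)) == 0) return(matrix(FALSE, nrow(sm), ncol(sm)))
  mask <- unclass_mask(threshold_mask(sm, method, value))
  if (largest_only) {
    lab <- label_components(mask, 8)
    if (max(lab) > 0) mask <- lab == which.max(tabulate(lab))
  }
  mask
}

#' Match detected cell labels to ground-truth centres
#'
#' Maps each ground-truth cell centre to the label covering it (or, failing
#' that, the label of the nearest labelled pixel), so per-cell measurements
#' can be compared against generator ground truth whose cell order differs
#' from the component-scan label order.
#'
#' @param cells integer label matrix.
#' @param centers two-column matrix or data frame of (row, col) centres.
#' @return Integer vector of label ids (NA when a centre lies in background
#'   and no labelled pixel exists).
#' @export
match_labels_to_centers <- function(cells, centers) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  out <- integer(n)
  labelled <- which(cells > 0)
  if (length(labelled) == 0) return(rep(NA_integer_, n))
  lr <- (labelled - 1) %% nrow(cells) + 1
  lc <- (labelled - 1) %/% nrow(cells) + 1
  for (i in seq_len(n)) {
    r <- round(centers[i, 1]); c <- round(centers[i, 2])
    if (r >= 1 && r <= nrow(cells) && c >= 1 && c <= ncol(cells) &&
        cells[r, c] > 0) {
      out[i] <- cells[r, c]
    } else {
      j <- which.min((lr - centers[i, 1])^2 + (lc - centers[i, 2])^2)
      out[i] <- cells[labelled[j]]
    }
  }
  out
}
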