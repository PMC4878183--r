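#' Multi-channel image stack
#'
#' A `channel_stack` holds co-registered 2D fluorescence channels on a common
#' pixel grid, the unit of analysis for all 2D quantification. Channels are
#' stored as numeric matrices in arbitrary fluorescence units (AFU), indexed
#' by unique channel names (e.g. `"FITC"`, `"Cy3"`, `"DAPI"`, `"Cy5"`).
#' Pixel coordinates are (row, col) with a pixel-centre convention.
#'
#' @param channels named list of numeric matrices, all the same dimension,
#'   all intensities >= 0.
#' @param pixel_size pixel edge length in micrometres.
#' @return An object of class `channel_stack`.
#' @examples
#' s <- channel_stack(list(FITC = matrix(0, 64, 64), Cy3 = matrix(0, 64, 64)))
#' channel_names(s)
#' @export
channel_stack <- function(channels, pixel_size = 1) {
  if (!is.list(channels) || length(channels) == 0)
    abort("`channels` must be a non-empty named list of matrices.")
  nms <- names(channels)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    abort("channel names must be present and unique.")
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), logical(1))))
    abort("every channel must be a numeric matrix.")
  if (length(unique(dims)) != 1)
    abort("all channels must share the same dimensions.")
  if (any(vapply(channels, function(m) any(m < 0, na.rm = TRUE), logical(1))))
    abort("channel intensities must be non-negative.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    abort("`pixel_size` must be a single positive number (micrometres/pixel).")
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "channel_stack")
}

#' @rdname channel_stack
#' @param x a `channel_stack`.
#' @export
channel_names <- function(x) names(x$channels)

#' Extract one channel as a matrix
#'
#' @param x a [channel_stack()].
#' @param name channel name.
#' @return Numeric matrix of pixel intensities.
#' @export
get_channel <- function(x, name) {
  stopifnot(inherits(x, "channel_stack"))
  if (!name %in% channel_names(x))
    abort(paste0("channel '", name, "' not found; available: ",
                 paste(channel_names(x), collapse = ", ")))
  x$channels[[name]]
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_stack> ", d[1], "x", d[2], " px, ",
      x$pixel_size, " um/px\n", sep = "")
  cat("  channels:", paste(channel_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$channels[[1]])

#' 3D electron-microscopy volume
#'
#' Container for an aligned FIB-SEM intensity volume with anisotropic voxels
#' (e.g. 10 nm in-plane, 20 nm slice spacing) and, optionally, a per-voxel
#' phase labelling among background, macrophage, adipocyte and lumen.
#'
#' @param intensity 3D numeric array, indexed `[z, y, x]`.
#' @param voxel_size_nm numeric length-3, `(dz, dy, dx)` in nanometres.
#' @param phases optional character or factor 3D array of the same shape with
#'   values in `c("background", "macrophage", "adipocyte", "lumen")`.
#' @return An object of class `em_volume`.
#' @export
em_volume <- function(intensity, voxel_size_nm = c(20, 10, 10), phases = NULL) {
  if (!is.array(intensity) || length(dim(intensity)) != 3)
    abort("`intensity` must be a 3D array [z, y, x].")
  if (length(voxel_size_nm) != 3 || any(voxel_size_nm <= 0))
    abort("`voxel_size_nm` must be three positive values (dz, dy, dx).")
  if (!is.null(phases) && !identical(dim(phases), dim(intensity)))
    abort("`phases` must match the intensity dimensions.")
  structure(list(intensity = intensity,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 phases = phases),
            class = "em_volume")
}

#' @export
print.em_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<em_volume> ", d[1], "x", d[2], "x", d[3], " voxels (z,y,x), voxel ",
      paste(x$voxel_size_nm, collapse = "x"), " nm",
      if (!is.null(x$phases)) ", phase-labelled", "\n", sep = "")
  invisible(x)
}
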