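#' Read and write multi-channel stacks as multi-page TIFF
#'
#' A stack is stored as one 32-bit TIFF page per channel plus a YAML sidecar
#' (`<path>.yaml`) carrying channel names, pixel size and the intensity scale.
#' TIFF samples are quantized to the unit range at 32-bit depth; with the
#' recorded scale the round trip is exact for 16-bit-range integer data and
#' accurate to ~1e-9 relative for continuous data. When the sidecar is absent,
#' channel names can be supplied in page order via `channel_names`.
#'
#' @param stack a [channel_stack()].
#' @param path TIFF file path.
#' @param channel_names fallback channel names in page order, used when no
#'   sidecar is found.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns a
#'   [channel_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  scale <- 2^ceiling(log2(max(1, max(unlist(stack$channels)))))
  pages <- lapply(stack$channels, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(channels = as.list(channel_names(stack)),
                        pixel_size_um = stack$pixel_size,
                        intensity_scale = scale),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(unique(lapply(pages, dim))) != 1)
    abort("TIFF pages have inconsistent shapes.")
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path))
  scale <- meta$intensity_scale %||% 1
  nms <- unlist(meta$channels) %||% channel_names
  if (is.null(nms)) nms <- paste0("ch", seq_along(pages))
  if (length(nms) != length(pages))
    abort(sprintf("%d channel name(s) supplied for %d TIFF page(s).",
                  length(nms), length(pages)))
  channels <- setNames(lapply(pages, function(p) p * scale), nms)
  channel_stack(channels, pixel_size = meta$pixel_size_um %||% 1)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read and write 3D EM volumes as TIFF stacks
#'
#' Each z-slice becomes one TIFF page; the YAML sidecar records
#' `voxel_size_nm` `(dz, dy, dx)` and the intensity scale.
#'
#' @param volume an [em_volume()].
#' @param path TIFF file path.
#' @param voxel_size_nm fallback voxel size when no sidecar is found.
#' @return `write_em_volume()` returns `path` invisibly; `read_em_volume()`
#'   an [em_volume()].
#' @export
write_em_volume <- function(volume, path) {
  stopifnot(inherits(volume, "em_volume"))
  scale <- 2^ceiling(log2(max(1, max(volume$intensity))))
  pages <- lapply(seq_len(dim(volume$intensity)[1]),
                  function(z) volume$intensity[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(voxel_size_nm = as.list(volume$voxel_size_nm),
                        intensity_scale = scale),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_em_volume
#' @export
read_em_volume <- function(path, voxel_size_nm = c(20, 10, 10)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path))
  scale <- meta$intensity_scale %||% 1
  vs <- unlist(meta$voxel_size_nm) %||% voxel_size_nm
  d <- dim(pages[[1]])
  intensity <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) intensity[z, , ] <- pages[[z]] * scale
  em_volume(intensity, voxel_size_nm = vs)
}

#' Write a measurement table to CSV
#'
#' Measurement tables are tidy per-cell (or per-region) records: `value`,
#' `condition`, `day`, `metric`, plus identifiers (`cell_id`, `image_id`) and
#' any provenance columns.
#'
#' @param table data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
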