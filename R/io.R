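#' Write a field series to an HDF5 container
#'
#' One file per acquisition protocol. The complex field is stored as an
#' h5py-compatible compound `{r, i}` float32 (complex64) dataset `/field`
#' whose C-order dims are `(t, y, x, z)` (i.e. the package's `(z, x, y, t)`
#' column-major layout), with root attributes `mode`, `n_repeats`, `dt_ms`
#' and `pitch_um`.
#'
#' @param series A [field_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_series <- function(series, path) {
  stopifnot(inherits(series, "field_series"))
  .Call(C_h5_write_field, as.character(path), series$data,
        dim(series$data), series$protocol$mode,
        as.integer(series$protocol$n_repeats),
        as.numeric(series$protocol$dt_ms), as.numeric(series$pitch_um))
  invisible(path)
}

#' Read a field series from an HDF5 container
#'
#' Validates the container (a missing dataset or attribute raises a format
#' error naming the missing key; a t-axis length that disagrees with
#' `n_repeats` raises a validation error) and returns a [field_series()].
#'
#' @param path Path to a container written by [write_field_series()] (or any
#'   HDF5 file following the same layout).
#' @export
read_field_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  raw <- .Call(C_h5_read_field, as.character(path))
  protocol <- acquisition_protocol(raw$mode, raw$n_repeats, raw$dt_ms)
  field_series(raw$data, raw$pitch_um, protocol)
}

# internal: drop a root attribute from a container (exercises error paths)
h5_drop_attr <- function(path, name) {
  .Call(C_h5_del_attr, as.character(path), as.character(name))
  invisible(path)
}

# Multi-page 32-bit TIFF with a JSON sidecar. Page values are stored scaled
# to [0, 1] (this build of the tiff package has no float sample format); the
# sidecar records the scale, so read_angiogram restores physical values with
# precision finer than a float32 mantissa.
write_float_tiff <- function(arr3d, path, meta = list()) {
  stopifnot(length(dim(arr3d)) == 3L)
  if (any(!is.finite(arr3d)))
    stop("volume contains non-finite values; refusing to write", call. = FALSE)
  scale <- max(arr3d)
  pages <- lapply(seq_len(dim(arr3d)[1]), function(z) {
    m <- arr3d[z, , ]
    if (scale > 0) m / scale else m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta$scale <- scale
  meta$dim <- dim(arr3d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_float_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar '%s'", sidecar), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  arr <- array(0, dim = d)
  for (z in seq_len(d[1])) arr[z, , ] <- pages[[z]] * meta$scale
  list(data = arr, meta = meta)
}

#' Save an angiogram as a multi-page TIFF stack
#'
#' One page per z slice, slice 1 = shallowest depth, with a JSON sidecar
#' (`<path>.json`) recording pitch, provenance and the intensity scale.
#'
#' @param vol An [angiogram()].
#' @param path Output TIFF path.
#' @export
save_angiogram <- function(vol, path) {
  stopifnot(inherits(vol, "angiogram"))
  write_float_tiff(vol$data, path,
                   meta = list(kind = "angiogram", pitch_um = vol$pitch_um,
                               provenance = vol$provenance))
}

#' Read an angiogram written by [save_angiogram()]
#' @param path TIFF path (its `.json` sidecar must sit next to it).
#' @export
read_angiogram <- function(path) {
  r <- read_float_tiff(path)
  angiogram(r$data, as.numeric(r$meta$pitch_um), r$meta$provenance)
}

#' Save a 3-D binary mask as a 0/1 TIFF stack
#' @param mask A [binary_mask_3d()].
#' @param path Output TIFF path.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask_3d"))
  write_float_tiff(array(as.numeric(mask$data), dim = dim(mask$data)), path,
                   meta = list(kind = "mask"))
}

#' Read a mask written by [save_mask()]
#' @param path TIFF path.
#' @export
read_mask <- function(path) {
  r <- read_float_tiff(path)
  binary_mask_3d(r$data > 0.5)
}
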