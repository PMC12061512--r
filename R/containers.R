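#' Complex OCT field series volume
#'
#' The raw input of both contrast engines: the reconstructed complex field
#' R(t) on a `(z, x, y, t)` grid. Axis convention is global across the
#' package: `z` is axial depth (increasing downward), `x` the fast scan axis,
#' `y` the slow scan axis; indices are 1-based in R.
#'
#' @param data Complex 4-D array with dims `(nz, nx, ny, nt)`.
#' @param pitch_um Numeric length-3 voxel pitch `(dz, dx, dy)` in micrometers.
#' @param protocol An [acquisition_protocol()]; its `n_repeats` must equal the
#'   length of the t axis.
#' @return Object of class `"field_series"`.
#' @export
field_series <- function(data, pitch_um, protocol) {
  if (!is.complex(data) || length(dim(data)) != 4L)
    stop("data must be a complex 4-D array (z, x, y, t)", call. = FALSE)
  if (anyNA(data) || any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("field series contains NA or non-finite values", call. = FALSE)
  pitch_um <- as.numeric(pitch_um)
  if (length(pitch_um) != 3L || any(!is.finite(pitch_um)) || any(pitch_um <= 0))
    stop("pitch_um must be 3 positive values (dz, dx, dy)", call. = FALSE)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (dim(data)[4] != protocol$n_repeats)
    stop(sprintf("t axis length (%d) does not match protocol n_repeats (%d)",
                 dim(data)[4], protocol$n_repeats), call. = FALSE)
  structure(list(data = data, pitch_um = pitch_um, protocol = protocol),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<field_series> %d x %d x %d (z,x,y), %d time points, %s\n",
              d[1], d[2], d[3], d[4], x$protocol$mode))
  invisible(x)
}

#' Dynamic-contrast angiogram volume
#'
#' Nonnegative real dynamic index Id on the `(z, x, y)` grid of its source
#' field series, tagged with the stage that produced it.
#'
#' @param data Nonnegative finite numeric 3-D array `(nz, nx, ny)`.
#' @param pitch_um Voxel pitch `(dz, dx, dy)` in micrometers.
#' @param provenance One of `"omag"`, `"ag1"`, `"fused"`, `"oof"`.
#' @return Object of class `"angiogram"`.
#' @export
angiogram <- function(data, pitch_um,
                      provenance = c("omag", "ag1", "fused", "oof")) {
  provenance <- match.arg(provenance)
  if (!is.numeric(data) || length(dim(data)) != 3L)
    stop("data must be a numeric 3-D array (z, x, y)", call. = FALSE)
  if (any(!is.finite(data)))
    stop("angiogram contains non-finite values", call. = FALSE)
  if (any(data < 0))
    stop("angiogram values must be >= 0", call. = FALSE)
  pitch_um <- as.numeric(pitch_um)
  if (length(pitch_um) != 3L || any(pitch_um <= 0))
    stop("pitch_um must be 3 positive values (dz, dx, dy)", call. = FALSE)
  structure(list(data = data, pitch_um = pitch_um, provenance = provenance),
            class = "angiogram")
}

#' @export
print.angiogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<angiogram:%s> %d x %d x %d (z,x,y), range [%.3g, %.3g]\n",
              x$provenance, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' En-face image
#'
#' A real nonnegative `(x, y)` image, e.g. an axial maximum intensity
#' projection of an [angiogram()].
#'
#' @param data Numeric matrix indexed `(x, y)`.
#' @param pitch_um Pixel pitch `(dx, dy)` in micrometers.
#' @export
enface_image <- function(data, pitch_um) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix (x, y)", call. = FALSE)
  if (any(!is.finite(data)) || any(data < 0))
    stop("en-face image must be finite and >= 0", call. = FALSE)
  pitch_um <- as.numeric(pitch_um)
  stopifnot(length(pitch_um) == 2L, all(pitch_um > 0))
  structure(list(data = data, pitch_um = pitch_um), class = "enface_image")
}

#' Binary en-face mask
#'
#' @param data Logical matrix indexed `(x, y)`.
#' @param pitch_um Pixel pitch `(dx, dy)` in micrometers.
#' @export
binary_mask_2d <- function(data, pitch_um) {
  if (!is.matrix(data) || !is.logical(data))
    stop("mask data must be a logical matrix (x, y)", call. = FALSE)
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  pitch_um <- as.numeric(pitch_um)
  stopifnot(length(pitch_um) == 2L, all(pitch_um > 0))
  structure(list(data = data, pitch_um = pitch_um), class = "binary_mask_2d")
}

#' Binary 3-D projection-column mask
#'
#' An axial extrusion of a [binary_mask_2d()]: every en-face column is
#' constant in z. Constructed via [extrude_axial()]; the constructor verifies
#' the extrusion invariant.
#'
#' @param data Logical 3-D array indexed `(z, x, y)`.
#' @export
binary_mask_3d <- function(data) {
  if (!is.logical(data) || length(dim(data)) != 3L)
    stop("mask data must be a logical 3-D array (z, x, y)", call. = FALSE)
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  col_any <- apply(data, c(2, 3), any)
  col_all <- apply(data, c(2, 3), all)
  if (!identical(col_any, col_all))
    stop("3-D mask must be constant along z in every en-face column",
         call. = FALSE)
  structure(list(data = data), class = "binary_mask_3d")
}

# shared-grid check used by fuse / oof / pipeline stages
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
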