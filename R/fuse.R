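#' Brightness-matching scale between the two sub-volumes
#'
#' The Ag1 and OMAG indices live on different scales; before merging, the
#' Ag1 sub-volume is rescaled so that a high percentile (default p99, robust
#' to the mostly-background voxel population) of its in-mask values matches
#' OMAG's. Returns `s = P_pct(omag in mask) / P_pct(ag1 in mask)`; an empty
#' mask or a zero denominator yields `s = 1` with a warning.
#'
#' @param ag1_vol,omag_vol [angiogram()]s on a shared grid.
#' @param mask3d The large-vessel [binary_mask_3d()].
#' @param percentile Percentile in (50, 100), default 99.
#' @return A positive scale factor.
#' @export
match_brightness <- function(ag1_vol, omag_vol, mask3d, percentile = 99) {
  stopifnot(inherits(ag1_vol, "angiogram"), inherits(omag_vol, "angiogram"),
            inherits(mask3d, "binary_mask_3d"))
  check_same_grid(ag1_vol, omag_vol)
  check_same_grid(ag1_vol, mask3d, "volume and mask")
  if (percentile <= 50 || percentile >= 100)
    stop("percentile must lie in (50, 100)", call. = FALSE)
  inm <- mask3d$data
  if (!any(inm)) {
    warning("empty mask: brightness scale set to 1")
    return(1)
  }
  p <- percentile / 100
  denom <- stats::quantile(ag1_vol$data[inm], p, names = FALSE)
  if (denom == 0) {
    warning("zero in-mask Ag1 percentile: brightness scale set to 1")
    return(1)
  }
  stats::quantile(omag_vol$data[inm], p, names = FALSE) / denom
}

#' Merge Ag1 (inside the projection column) with OMAG (outside)
#'
#' The central fusion step: inside the 3-D large-vessel column the
#' artifact-suppressing Ag1 contrast (times the brightness scale) is used;
#' everywhere else the capillary-sensitive OMAG contrast passes through
#' untouched. With `feather_px = 0` (default) the merge is a hard switch and
#' every output voxel equals exactly one of its two sources; a small linear
#' feather at the column boundary is available for rendering.
#'
#' @param omag_vol,ag1_vol [angiogram()]s on a shared grid.
#' @param mask3d The large-vessel [binary_mask_3d()].
#' @param scale Brightness scale applied to Ag1 (see [match_brightness()]).
#' @param feather_px Linear blend half-width in pixels at the mask boundary.
#' @return An [angiogram()] with provenance `"fused"`.
#' @export
fuse_volumes <- function(omag_vol, ag1_vol, mask3d, scale = 1,
                         feather_px = 0L) {
  stopifnot(inherits(omag_vol, "angiogram"), inherits(ag1_vol, "angiogram"),
            inherits(mask3d, "binary_mask_3d"))
  check_same_grid(omag_vol, ag1_vol)
  check_same_grid(omag_vol, mask3d, "volume and mask")
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (feather_px > 0L) {
    m2 <- mask3d$data[1, , ]
    din <- ebi_mat(EBImage::distmap(m2 * 1))
    dout <- ebi_mat(EBImage::distmap((1 - m2) * 1))
    alpha2 <- pmin(pmax(0.5 + (din - dout) / (2 * feather_px), 0), 1)
    alpha <- array(rep(alpha2, each = dim(mask3d$data)[1]),
                   dim = dim(mask3d$data))
  } else {
    alpha <- mask3d$data * 1
  }
  out <- alpha * (scale * ag1_vol$data) + (1 - alpha) * omag_vol$data
  angiogram(out, omag_vol$pitch_um, "fused")
}
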