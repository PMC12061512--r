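#' Axial maximum intensity projection
#'
#' Collapses an angiogram along depth, producing the top-down en-face vessel
#' map the large-vessel mask is derived from.
#'
#' @param vol An [angiogram()].
#' @param z_range Optional inclusive slice range `c(lo, hi)` (1-based);
#'   `NULL` projects the full depth.
#' @return An [enface_image()].
#' @export
mip_axial <- function(vol, z_range = NULL) {
  stopifnot(inherits(vol, "angiogram"))
  nz <- dim(vol$data)[1]
  if (is.null(z_range)) z_range <- c(1L, nz)
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] < 1L || z_range[2] > nz ||
      z_range[1] > z_range[2])
    stop("z_range must be a nonempty slice range within the volume", call. = FALSE)
  sl <- vol$data[z_range[1]:z_range[2], , , drop = FALSE]
  enface_image(apply(sl, c(2, 3), max), vol$pitch_um[2:3])
}

#' Otsu binarization of an en-face image
#'
#' Parameter-free foreground/background split of the MIP. If the Otsu
#' threshold would put more than half of the pixels in the foreground, the
#' threshold is re-applied at the median so that the kept (brighter) class
#' always occupies at most half the image. A constant image yields an empty
#' mask with a warning.
#'
#' @param img An [enface_image()].
#' @return A [binary_mask_2d()] of vessel-candidate pixels.
#' @export
binarize_enface <- function(img) {
  stopifnot(inherits(img, "enface_image"))
  x <- img$data
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant en-face image: empty mask")
    return(binary_mask_2d(array(FALSE, dim = dim(x)), img$pitch_um))
  }
  xn <- (x - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  fg <- xn > th
  if (mean(fg) > 0.5) {
    th2 <- stats::median(xn)
    fg <- xn > max(th, th2)
  }
  binary_mask_2d(fg, img$pitch_um)
}

# logical matrix shifted by (dr, dc), padding with FALSE
shift_lgl <- function(m, dr, dc) {
  n <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rs_src <- rs - dr; cs_src <- cs - dc
  ok_r <- rs_src >= 1 & rs_src <= nrow(m)
  ok_c <- cs_src >= 1 & cs_src <= ncol(m)
  n[rs[ok_r], cs[ok_c]] <- m[rs_src[ok_r], cs_src[ok_c]]
  n
}

# Zhang-Suen thinning; morphological skeleton of a binary image.
# (No installed package provides 2-D thinning, so it is implemented here.)
zhang_suen_thin <- function(m) {
  mode(m) <- "logical"
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_lgl(m, -1, 0); p3 <- shift_lgl(m, -1, 1)
      p4 <- shift_lgl(m, 0, 1);  p5 <- shift_lgl(m, 1, 1)
      p6 <- shift_lgl(m, 1, 0);  p7 <- shift_lgl(m, 1, -1)
      p8 <- shift_lgl(m, 0, -1); p9 <- shift_lgl(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1L)
        cond <- !(p2 & p4 & p6) & !(p4 & p6 & p8)
      else
        cond <- !(p2 & p4 & p8) & !(p2 & p6 & p8)
      del <- m & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) { m <- m & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  m
}

# geodesic reconstruction: grow seeds by 8-connected dilation inside mask
geodesic_reconstruct <- function(seeds, mask) {
  cur <- seeds & mask
  kern <- EBImage::makeBrush(3, shape = "box")
  repeat {
    grown <- ebi_mat(EBImage::dilate(cur * 1, kern)) > 0.5
    grown <- grown & mask
    if (identical(grown, cur)) return(cur)
    cur <- grown
  }
}

#' Keep only vessels at least a given diameter wide
#'
#' Local vessel diameter is estimated as twice the Euclidean distance
#' transform sampled on the morphological skeleton of the mask; skeleton
#' points with diameter `>= min_diameter_um` (boundary inclusive) seed a
#' geodesic reconstruction restricted to the original foreground, so thin
#' vessels vanish and wide vessels are recovered in full. The output is
#' always a pixelwise subset of the input, and is monotone in the threshold.
#' A 3x3 closing (on by default) bridges 1-pixel speckle gaps before
#' skeletonization; reconstruction stays restricted to the *input* mask.
#'
#' @param mask A [binary_mask_2d()]; en-face pitch must be isotropic.
#' @param min_diameter_um Diameter threshold in micrometers (default 20).
#' @param closing Apply the gap-bridging closing first.
#' @return A [binary_mask_2d()] containing only the large vessels.
#' @export
diameter_filter <- function(mask, min_diameter_um = 20, closing = TRUE) {
  stopifnot(inherits(mask, "binary_mask_2d"))
  if (min_diameter_um <= 0) stop("min_diameter_um must be > 0", call. = FALSE)
  px <- mask$pitch_um
  if (abs(px[1] - px[2]) > 1e-6 * px[1])
    stop("diameter_filter requires isotropic en-face pitch", call. = FALSE)
  m <- mask$data
  if (!any(m)) return(binary_mask_2d(m, px))
  work <- if (closing) {
    kern <- EBImage::makeBrush(3, shape = "box")
    ebi_mat(EBImage::closing(m * 1, kern)) > 0.5
  } else m
  edt <- ebi_mat(EBImage::distmap(work * 1, metric = "euclidean"))
  skel <- zhang_suen_thin(work)
  seeds <- skel & (2 * edt * px[1] >= min_diameter_um - 1e-9)
  out <- geodesic_reconstruct(seeds, m)
  binary_mask_2d(out, px)
}

#' Extrude an en-face mask along depth
#'
#' Projects the large-vessel mask axially into the 3-D projection-column
#' mask: `mask3d[z, x, y] = mask2d[x, y]` for every z.
#'
#' @param mask2d A [binary_mask_2d()].
#' @param nz Number of z slices (>= 1).
#' @return A [binary_mask_3d()].
#' @export
extrude_axial <- function(mask2d, nz) {
  stopifnot(inherits(mask2d, "binary_mask_2d"))
  nz <- as.integer(nz)
  if (nz < 1L) stop("nz must be >= 1", call. = FALSE)
  d2 <- dim(mask2d$data)
  arr <- array(rep(mask2d$data, each = nz), dim = c(nz, d2))
  binary_mask_3d(arr)
}

#' Build the large-vessel projection-column mask from an OMAG volume
#'
#' Chains [mip_axial()], [binarize_enface()], [diameter_filter()], an
#' optional halo-covering dilation, and [extrude_axial()] per the pipeline
#' configuration.
#'
#' @param omag_vol The OMAG [angiogram()].
#' @param config A [pipeline_config()].
#' @return List with `enface`, `mask2d` and `mask3d`.
#' @export
build_vessel_mask <- function(omag_vol, config = pipeline_config()) {
  stopifnot(inherits(omag_vol, "angiogram"))
  mip <- mip_axial(omag_vol, config$mask_z_range)
  cand <- binarize_enface(mip)
  big <- diameter_filter(cand, config$diameter_threshold_um,
                         closing = config$mask_closing)
  if (config$mask_dilate_px > 0L && any(big$data)) {
    kern <- EBImage::makeBrush(2L * config$mask_dilate_px + 1L, shape = "disc")
    big <- binary_mask_2d(ebi_mat(EBImage::dilate(big$data * 1, kern)) > 0.5,
                          big$pitch_um)
  }
  list(enface = mip, mask2d = big,
       mask3d = extrude_axial(big, dim(omag_vol$data)[1]))
}
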