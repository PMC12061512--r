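#' @name oof
#' @title Multiscale optimally-oriented-flux vessel enhancement
#' @description
#' Hessian-eigenvalue tube enhancement: at each scale `r` the volume is
#' smoothed with Gaussian derivatives (`sigma = oof_sigma_factor * r`), the
#' symmetric 3x3 Hessian is assembled per voxel, and the response
#' `-lambda1 / r^2` (with `lambda1` the most negative eigenvalue, strongly
#' negative across the axis of a bright tube) is maximized over scales and
#' clamped at zero. Bright tubular structures of radius near `r` light up;
#' dark tubes and flat background do not.
NULL

# --- separable Gaussian-derivative convolution (reflect boundary) ---------

# Sampled Gaussian-derivative kernels, calibrated so that polynomial inputs
# give exact derivatives: sum(g0)=1; sum(g1*k)=1 (zero-sum); sum(g2*k^2)=2
# (zero-sum). k runs -radius..radius.
gauss_kernels <- function(sigma_vox) {
  rad <- max(3L, ceiling(4 * sigma_vox))
  k <- seq.int(-rad, rad)
  g <- exp(-k^2 / (2 * sigma_vox^2))
  g0 <- g / sum(g)
  g1 <- -k * g
  g1 <- g1 - mean(g1)
  g1 <- g1 / sum(g1 * k)
  g2 <- (k^2 / sigma_vox^2 - 1) * g
  g2 <- g2 - mean(g2)
  g2 <- g2 / (sum(g2 * k^2) / 2)
  list(g0 = g0, g1 = g1, g2 = g2, radius = rad)
}

# Correlate a 3-D array with a 1-D kernel along `axis`, reflect padding
# (edge value repeated: c b a | a b c d | d c b). With `zero_sum = TRUE`
# (derivative kernels) the window is centered on its middle sample before
# weighting, so constant inputs map to exactly zero.
convolve_axis <- function(arr, kernel, axis, zero_sum = FALSE) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  n <- d[axis]
  p <- (length(kernel) - 1L) %/% 2L
  idx_head <- pmin(pmax(seq.int(p, 1L), 1L), n)
  idx_tail <- pmin(pmax(seq.int(n, n - p + 1L), 1L), n)
  xp <- matrix(0, n + 2L * p, prod(d[perm[2:3]]))
  dim(x) <- c(n, prod(d[perm[2:3]]))
  xp[(p + 1L):(p + n), ] <- x
  if (p > 0L) {
    xp[seq_len(p), ] <- x[idx_head, , drop = FALSE]
    xp[(p + n + 1L):(n + 2L * p), ] <- x[idx_tail, , drop = FALSE]
  }
  out <- matrix(0, n, ncol(xp))
  if (zero_sum) {
    ctr <- xp[(p + 1L):(p + n), , drop = FALSE]
    for (j in seq_along(kernel))
      out <- out + kernel[j] * (xp[(j):(j + n - 1L), , drop = FALSE] - ctr)
  } else {
    for (j in seq_along(kernel))
      out <- out + kernel[j] * xp[(j):(j + n - 1L), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Gaussian-smoothed Hessian at one scale
#'
#' Each of the six unique second-derivative components is the volume
#' convolved with the corresponding separable derivative-of-Gaussian kernel
#' at `sigma = sigma_factor * r_um` (converted to voxels per axis via the
#' pitch, so anisotropic grids are handled). Boundary handling is reflect.
#' Scales that are under-resolved on the grid (`sigma < 0.5` voxel on any
#' axis) are rejected.
#'
#' @param vol An [angiogram()].
#' @param r_um Scale radius in micrometers.
#' @param sigma_factor Sigma as a fraction of `r_um` (default 0.5).
#' @return Object of class `"hessian_field"`: list of arrays `xx, yy, zz,
#'   xy, xz, yz` plus the scale.
#' @export
gaussian_hessian <- function(vol, r_um, sigma_factor = 0.5) {
  stopifnot(inherits(vol, "angiogram"))
  if (r_um <= 0) stop("r_um must be > 0", call. = FALSE)
  sig_um <- sigma_factor * r_um
  sig_vox <- sig_um / vol$pitch_um          # (z, x, y)
  if (any(sig_vox < 0.5))
    stop(sprintf("scale %g um under-resolved: sigma %.3g voxel < 0.5",
                 r_um, min(sig_vox)), call. = FALSE)
  kz <- gauss_kernels(sig_vox[1])
  kx <- gauss_kernels(sig_vox[2])
  ky <- gauss_kernels(sig_vox[3])
  f <- vol$data
  # pitch-aware derivatives: voxel-unit kernels divided by pitch powers (um);
  # derivative passes (first one or two kernels) are zero-sum
  d2 <- function(kA, kB, kC, axA, axB, axC, n_deriv = 1L) {
    g <- convolve_axis(f, kA, axA, zero_sum = TRUE)
    g <- convolve_axis(g, kB, axB, zero_sum = n_deriv > 1L)
    convolve_axis(g, kC, axC)
  }
  pz <- vol$pitch_um[1]; px <- vol$pitch_um[2]; py <- vol$pitch_um[3]
  structure(list(
    xx = d2(kx$g2, ky$g0, kz$g0, 2, 3, 1) / px^2,
    yy = d2(ky$g2, kx$g0, kz$g0, 3, 2, 1) / py^2,
    zz = d2(kz$g2, kx$g0, ky$g0, 1, 2, 3) / pz^2,
    xy = d2(kx$g1, ky$g1, kz$g0, 2, 3, 1, n_deriv = 2L) / (px * py),
    xz = d2(kx$g1, kz$g1, ky$g0, 2, 1, 3, n_deriv = 2L) / (px * pz),
    yz = d2(ky$g1, kz$g1, kx$g0, 3, 1, 2, n_deriv = 2L) / (py * pz),
    r_um = r_um, dim = dim(f)), class = "hessian_field")
}

#' Eigendecomposition of a symmetric 3x3 field
#'
#' Closed-form (trigonometric) eigenvalues of the per-voxel symmetric
#' Hessian, sorted ascending by signed value (`lambda1` most negative), with
#' optional unit eigenvectors obtained from cross products of the rows of
#' `H - lambda I` (degenerate voxels fall back to a dense solve).
#'
#' @param H A `"hessian_field"` (or a list with numeric components
#'   `xx, yy, zz, xy, xz, yz` of equal length).
#' @param vectors `"none"`, `"v1"` (eigenvector of lambda1) or `"all"`.
#' @return List of `lambda1, lambda2, lambda3` arrays and, if requested,
#'   `V1` (and `V2`, `V3`) with a trailing length-3 component dimension.
#' @export
eig_symmetric3 <- function(H, vectors = c("none", "v1", "all")) {
  vectors <- match.arg(vectors)
  dm <- if (!is.null(H$dim)) H$dim else dim(as.array(H$xx))
  a11 <- as.vector(H$xx); a22 <- as.vector(H$yy); a33 <- as.vector(H$zz)
  a12 <- as.vector(H$xy); a13 <- as.vector(H$xz); a23 <- as.vector(H$yz)
  n <- length(a11)

  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
        2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1)
  ps <- ifelse(iso, 1, p)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
          b13 * (b12 * b23 - b22 * b13)
  rr <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(rr) / 3
  l3 <- q + 2 * p * cos(phi)                       # largest
  l1 <- q + 2 * p * cos(phi + 2 * pi / 3)          # smallest
  l2 <- 3 * q - l1 - l3
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]

  out <- list(lambda1 = array(l1, dm), lambda2 = array(l2, dm),
              lambda3 = array(l3, dm))
  if (vectors == "none") return(out)

  eigvec <- function(lam) {
    m11 <- a11 - lam; m22 <- a22 - lam; m33 <- a33 - lam
    # cross products of row pairs of (A - lam I)
    c1x <- m22 * m33 - a23 * a23; c1y <- a23 * a13 - a12 * m33
    c1z <- a12 * a23 - m22 * a13
    c2x <- a23 * a13 - a12 * m33; c2y <- m11 * m33 - a13 * a13
    c2z <- a12 * a13 - m11 * a23
    c3x <- a12 * a23 - a13 * m22; c3y <- a13 * a12 - a23 * m11
    c3z <- m11 * m22 - a12 * a12
    n1 <- c1x^2 + c1y^2 + c1z^2
    n2 <- c2x^2 + c2y^2 + c2z^2
    n3 <- c3x^2 + c3y^2 + c3z^2
    pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
    vx <- ifelse(pick == 1, c1x, ifelse(pick == 2, c2x, c3x))
    vy <- ifelse(pick == 1, c1y, ifelse(pick == 2, c2y, c3y))
    vz <- ifelse(pick == 1, c1z, ifelse(pick == 2, c2z, c3z))
    nn <- sqrt(vx^2 + vy^2 + vz^2)
    bad <- nn < .Machine$double.eps
    nn[bad] <- 1
    v <- cbind(vx / nn, vy / nn, vz / nn)
    if (any(bad)) {
      for (i in which(bad)) {   # degenerate: dense solve
        A <- matrix(c(a11[i], a12[i], a13[i],
                      a12[i], a22[i], a23[i],
                      a13[i], a23[i], a33[i]), 3, 3)
        e <- eigen(A, symmetric = TRUE)
        j <- which.min(abs(e$values - lam))
        v[i, ] <- e$vectors[, j]
      }
    }
    array(v, c(dm, 3))
  }
  out$V1 <- eigvec(l1)
  if (vectors == "all") {
    out$V2 <- eigvec(l2)
    out$V3 <- eigvec(l3)
  }
  out
}

#' Multiscale OOF response
#'
#' `P = max(0, max_r(-lambda1(f, r) / r^2))`: the most negative Hessian
#' eigenvalue at each scale, sign-flipped, scale-normalized by `1/r^2`,
#' maximized over the scale set and clamped at zero.
#'
#' @param vol An [angiogram()].
#' @param scales_um Strictly ascending scale radii in micrometers.
#' @param sigma_factor Gaussian sigma per scale (fraction of `r`).
#' @param detail If `TRUE`, also return the per-voxel argmax scale.
#' @return An [angiogram()] with provenance `"oof"`; with `detail = TRUE`, a
#'   list with elements `vol` and `argmax_um`.
#' @export
oof_response <- function(vol, scales_um = c(3, 4.5, 6, 9, 12),
                         sigma_factor = 0.5, detail = FALSE) {
  stopifnot(inherits(vol, "angiogram"))
  if (length(scales_um) == 0 || any(diff(scales_um) <= 0) || any(scales_um <= 0))
    stop("scales_um must be nonempty, positive, strictly ascending", call. = FALSE)
  best <- array(-Inf, dim = dim(vol$data))
  argm <- array(scales_um[1], dim = dim(vol$data))
  for (r in scales_um) {
    H <- gaussian_hessian(vol, r, sigma_factor)
    l1 <- eig_symmetric3(H)$lambda1
    cand <- -l1 / r^2
    upd <- cand > best
    best[upd] <- cand[upd]
    argm[upd] <- r
  }
  best[best < 0] <- 0
  out <- angiogram(best, vol$pitch_um, "oof")
  if (detail) list(vol = out, argmax_um = argm) else out
}

#' Capillary-compartment OOF enhancement
#'
#' OOF response to large vessels fades with increasing scale, so the filter
#' is applied only to the capillary compartment: outside the large-vessel
#' column mask, the fused volume is replaced by its OOF response rescaled to
#' match the fused volume's out-of-mask p99; inside the mask the fused
#' values pass through bit-identically. Set `capillary_only = FALSE` to
#' enhance the whole volume instead.
#'
#' @param fused The fused [angiogram()].
#' @param mask3d The large-vessel [binary_mask_3d()].
#' @param scales_um,sigma_factor See [oof_response()].
#' @param percentile Brightness-matching percentile for the OOF compartment.
#' @param capillary_only Restrict enhancement to outside the mask.
#' @return An [angiogram()] with provenance `"oof"`.
#' @export
apply_oof_capillaries <- function(fused, mask3d,
                                  scales_um = c(3, 4.5, 6, 9, 12),
                                  sigma_factor = 0.5, percentile = 99,
                                  capillary_only = TRUE) {
  stopifnot(inherits(fused, "angiogram"), inherits(mask3d, "binary_mask_3d"))
  check_same_grid(fused, mask3d, "volume and mask")
  outside <- if (capillary_only) !mask3d$data else
    array(TRUE, dim = dim(fused$data))
  if (!any(outside))   # nothing to enhance: fused passes through
    return(angiogram(fused$data, fused$pitch_um, "oof"))
  resp <- oof_response(fused, scales_um, sigma_factor)$data
  p <- percentile / 100
  ref <- stats::quantile(fused$data[outside], p, names = FALSE)
  cur <- stats::quantile(resp[outside], p, names = FALSE)
  s <- if (cur > 0) ref / cur else 1
  out <- fused$data
  out[outside] <- resp[outside] * s
  angiogram(out, fused$pitch_um, "oof")
}
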