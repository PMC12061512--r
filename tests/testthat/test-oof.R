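test_that("gaussian_hessian reproduces analytic derivatives", {
  # constant volume -> all six components 0 everywhere, boundaries included
  cv <- angiogram(array(5, c(16, 16, 16)), c(1, 1, 1), "fused")
  H <- gaussian_hessian(cv, r_um = 2, sigma_factor = 0.5)
  for (k in c("xx", "yy", "zz", "xy", "xz", "yz"))
    expect_lt(max(abs(H[[k]])), 1e-10)

  # separable quadratic f = x^2 (voxel units, unit pitch): d2f/dx2 = 2
  n <- 24L
  xs <- seq_len(n)
  f <- array(rep(rep((xs - n / 2)^2, each = n), n), c(n, n, n))
  qv <- angiogram(f, c(1, 1, 1), "fused")
  Hq <- gaussian_hessian(qv, r_um = 2, sigma_factor = 0.5)
  interior <- 8:17
  expect_equal(max(abs(Hq$xx[interior, interior, interior] - 2)), 0,
               tolerance = 1e-6)
  for (k in c("yy", "zz", "xy", "xz", "yz"))
    expect_lt(max(abs(Hq[[k]][interior, interior, interior])), 1e-6)

  # mirror symmetry in x makes the xy cross-derivative antisymmetric
  set.seed(50)
  half <- array(runif(12 * 6 * 12), c(12, 6, 12))
  sym <- array(0, c(12, 12, 12))
  sym[, 1:6, ] <- half
  sym[, 12:7, ] <- half
  sv <- angiogram(sym, c(1, 1, 1), "fused")
  Hs <- gaussian_hessian(sv, r_um = 2, sigma_factor = 0.5)
  expect_equal(Hs$xy[, 1:6, ], -Hs$xy[, 12:7, ], tolerance = 1e-10)

  # under-resolved scale rejected
  expect_error(gaussian_hessian(cv, r_um = 0.5, sigma_factor = 0.5),
               "under-resolved")
})

test_that("eig_symmetric3 matches the dense solver on 10^4 random matrices", {
  expect_eig <- function(a) {
    H <- list(xx = a[1], yy = a[2], zz = a[3], xy = a[4], xz = a[5],
              yz = a[6], dim = c(1, 1, 1))
    eig_symmetric3(H, vectors = "all")
  }
  # forced diagonal case
  e <- expect_eig(c(-3, -1, 2, 0, 0, 0))
  expect_equal(c(e$lambda1, e$lambda2, e$lambda3), c(-3, -1, 2))
  ez <- expect_eig(rep(0, 6))
  expect_equal(c(ez$lambda1, ez$lambda2, ez$lambda3), c(0, 0, 0))

  set.seed(51)
  n <- 10000L
  comp <- matrix(rnorm(6 * n), n, 6)
  H <- list(xx = comp[, 1], yy = comp[, 2], zz = comp[, 3],
            xy = comp[, 4], xz = comp[, 5], yz = comp[, 6], dim = c(n, 1, 1))
  got <- eig_symmetric3(H, vectors = "all")
  l_got <- cbind(as.vector(got$lambda1), as.vector(got$lambda2),
                 as.vector(got$lambda3))
  worst_val <- 0; worst_rec <- 0; worst_norm <- 0
  V1 <- matrix(got$V1, n); V2 <- matrix(got$V2, n); V3 <- matrix(got$V3, n)
  for (i in seq_len(n)) {
    A <- matrix(c(comp[i, 1], comp[i, 4], comp[i, 5],
                  comp[i, 4], comp[i, 2], comp[i, 6],
                  comp[i, 5], comp[i, 6], comp[i, 3]), 3, 3)
    ref <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    worst_val <- max(worst_val, max(abs(l_got[i, ] - ref)))
    V <- cbind(V1[i, ], V2[i, ], V3[i, ])
    rec <- V %*% diag(l_got[i, ]) %*% t(V)
    worst_rec <- max(worst_rec, max(abs(rec - A)))
    worst_norm <- max(worst_norm, abs(colSums(V^2) - 1))
  }
  expect_lt(worst_val, 1e-9)
  expect_lt(worst_rec, 1e-9)
  expect_lt(worst_norm, 1e-12)
})

test_that("oof_response enhances bright tubes at the matching scale", {
  scales <- c(3, 4.5, 6, 9, 12)
  # constant volume -> response 0 everywhere
  cv <- angiogram(array(3, c(20, 20, 20)), c(1.5, 1.5, 1.5), "fused")
  expect_true(all(oof_response(cv, scales)$data == 0))

  ctr <- 20L  # cylinder axis voxel index (40^3 grid)
  for (rad in c(4, 6, 8)) {
    cyl <- make_cylinder(rad)
    r <- oof_response(cyl, scales, detail = TRUE)
    onax <- r$vol$data[ctr, ctr, ctr]
    am <- r$argmax_um[ctr, ctr, ctr]
    expect_gt(onax, 0)
    # argmax scale within one scale step of the radius
    k <- findInterval(rad, scales)
    allowed <- scales[max(1, k - 1):min(length(scales), k + 1)]
    expect_true(am %in% allowed)
    # far background is quiet (< 5% of the axial peak)
    expect_lt(max(r$vol$data[3:6, 3:6, ctr]), 0.05 * onax)
  }

  # argmax scale increases with radius (scale selectivity)
  am_of <- function(rad) {
    r <- oof_response(make_cylinder(rad), scales, detail = TRUE)
    r$argmax_um[ctr, ctr, ctr]
  }
  expect_lt(am_of(4), am_of(8))

  # dark cylinder on bright background -> response 0 on the axis
  cyl <- make_cylinder(6)
  dark <- angiogram(max(cyl$data) - cyl$data, cyl$pitch_um, "fused")
  rd <- oof_response(dark, scales)
  expect_equal(rd$data[ctr, ctr, ctr], 0)

  # nonnegative everywhere on arbitrary data
  set.seed(52)
  noisy <- angiogram(array(runif(18^3), c(18, 18, 18)), c(1.5, 1.5, 1.5),
                     "fused")
  expect_true(all(oof_response(noisy, scales)$data >= 0))
})

test_that("oof response is invariant under 90-degree axis permutations", {
  scales <- c(3, 4.5, 6, 9)
  cyl <- make_cylinder(6)                       # axis along y
  p0 <- oof_response(cyl, scales)$data[20, 20, 20]
  for (ax in c("x", "z")) {
    alt <- make_cylinder(6, axis = ax)
    pa <- oof_response(alt, scales)$data[20, 20, 20]
    expect_equal(pa, p0, tolerance = 0.05 * p0)
  }
})

test_that("apply_oof_capillaries only touches the capillary compartment", {
  set.seed(53)
  d <- c(10, 16, 16)
  fused <- angiogram(array(runif(prod(d)), d), c(3, 3, 3), "fused")
  m2 <- matrix(FALSE, 16, 16); m2[6:10, ] <- TRUE
  m3 <- extrude_axial(binary_mask_2d(m2, c(3, 3)), d[1])
  out <- apply_oof_capillaries(fused, m3, scales_um = c(3, 4.5, 6))
  inm <- m3$data
  expect_identical(out$data[inm], fused$data[inm])
  # mask all-true -> output identical to fused input
  mT <- extrude_axial(binary_mask_2d(matrix(TRUE, 16, 16), c(3, 3)), d[1])
  outT <- apply_oof_capillaries(fused, mT, scales_um = c(3, 4.5, 6))
  expect_identical(outT$data, fused$data)
  # mask all-false -> rescaled whole-volume OOF response
  mF <- extrude_axial(binary_mask_2d(matrix(FALSE, 16, 16), c(3, 3)), d[1])
  outF <- apply_oof_capillaries(fused, mF, scales_um = c(3, 4.5, 6))
  resp <- oof_response(fused, c(3, 4.5, 6))$data
  p99 <- function(v) stats::quantile(v, 0.99, names = FALSE)
  expect_equal(outF$data, resp * p99(fused$data) / p99(resp), tolerance = 1e-12)
})

test_that("OOF keeps capillary connectivity on the phantom", {
  res <- default_phantom_run()
  lab <- res$truth$label
  cap <- lab == 1L
  # largest 26-connected component of the capillary detection, as a
  # fraction of the true capillary voxels
  lcc <- function(vol) {
    thr <- 0.5 * stats::median(vol[cap])
    dualocta:::largest_component_fraction(cap & (vol >= thr), sum(cap))
  }
  expect_gte(lcc(res$oof$data), lcc(res$fused$data))
  # inside-mask voxels pass through the OOF stage bit-identically
  inm <- res$mask$mask3d$data
  expect_identical(res$oof$data[inm], res$fused$data[inm])
})
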