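test_that("mip_axial projects correctly", {
  vol <- angiogram(array(0, c(6, 5, 4)), c(3, 3, 3), "omag")
  # delta volume
  vol$data[3, 2, 4] <- 7
  img <- mip_axial(vol)
  want <- matrix(0, 5, 4); want[2, 4] <- 7
  expect_equal(img$data, want)
  # single-slice range is that slice
  vol2 <- angiogram(array(runif(6 * 5 * 4), c(6, 5, 4)), c(3, 3, 3), "omag")
  expect_equal(mip_axial(vol2, c(4, 4))$data, vol2$data[4, , ])
  # all-zero volume -> all-zero image
  expect_true(all(mip_axial(angiogram(array(0, c(3, 3, 3)), c(3, 3, 3),
                                      "omag"))$data == 0))
  expect_error(mip_axial(vol2, c(5, 4)), "z_range")
  expect_error(mip_axial(vol2, c(0, 2)), "z_range")
})

test_that("binarize_enface splits a bimodal image and guards degenerate input", {
  set.seed(30)
  img <- matrix(rnorm(64 * 64, 0.1, 0.01), 64, 64)
  img[20:30, ] <- rnorm(11 * 64, 0.9, 0.01)
  img <- pmax(img, 0)
  m <- binarize_enface(enface_image(img, c(3, 3)))
  expect_true(all(m$data[20:30, ]))
  expect_false(any(m$data[c(1:15, 40:64), ]))

  expect_warning(mc <- binarize_enface(enface_image(matrix(1, 8, 8), c(3, 3))),
                 "constant")
  expect_false(any(mc$data))

  # foreground is never the majority class
  for (s in 1:3) {
    set.seed(s)
    r <- matrix(runif(32 * 32), 32, 32)
    mr <- binarize_enface(enface_image(r, c(3, 3)))
    expect_lte(mean(mr$data), 0.5)
  }
})

test_that("diameter_filter keeps wide tubes, drops narrow ones, boundary inclusive", {
  # 30 um and 10 um wide parallel tubes at 2 um pitch
  m <- matrix(FALSE, 80, 80)
  m[20:34, ] <- TRUE   # 15 px * 2 um = 30 um
  m[60:64, ] <- TRUE   # 5 px * 2 um = 10 um
  mask <- binary_mask_2d(m, c(2, 2))
  out <- diameter_filter(mask, 20)
  expect_true(all(out$data[20:34, ]))
  expect_false(any(out$data[60:64, ]))

  # exactly 20 um wide -> kept (>= comparator)
  m2 <- matrix(FALSE, 40, 40)
  m2[15:24, ] <- TRUE  # 10 px * 2 um = 20 um
  out2 <- diameter_filter(binary_mask_2d(m2, c(2, 2)), 20)
  expect_true(any(out2$data))
  expect_true(all(which(out2$data, arr.ind = TRUE)[, 1] %in% 15:24))

  # empty stays empty
  e <- diameter_filter(binary_mask_2d(matrix(FALSE, 10, 10), c(2, 2)), 20)
  expect_false(any(e$data))
})

test_that("diameter_filter output is a subset and monotone in threshold", {
  set.seed(31)
  m <- matrix(runif(96 * 96) > 0.92, 96, 96)
  m[30:44, ] <- TRUE
  m[70:73, 10:80] <- TRUE
  mask <- binary_mask_2d(m, c(3, 3))
  outs <- lapply(c(10, 20, 40), function(th) diameter_filter(mask, th)$data)
  for (o in outs) expect_true(all(!o | m))       # subset of input
  expect_true(all(!outs[[2]] | outs[[1]]))       # 20 um subset of 10 um
  expect_true(all(!outs[[3]] | outs[[2]]))       # 40 um subset of 20 um
})

test_that("extrude_axial builds z-constant columns", {
  m2 <- binary_mask_2d(matrix(FALSE, 4, 5), c(3, 3))
  expect_false(any(extrude_axial(m2, 10L)$data))
  m2$data[2, 3] <- TRUE
  m3 <- extrude_axial(m2, 10L)
  expect_equal(sum(m3$data), 10L)
  for (z in 1:10) expect_equal(m3$data[z, , ], m2$data)
  # constructor rejects non-extruded arrays
  bad <- array(FALSE, c(3, 2, 2)); bad[1, 1, 1] <- TRUE
  expect_error(binary_mask_3d(bad), "constant along z")
})

test_that("phantom mask covers large-vessel columns and spares capillaries", {
  res <- default_phantom_run()
  mm <- dualocta:::mask_column_metrics(res$mask$mask2d, res$truth)
  expect_gte(mm$recall, 0.95)
  expect_lte(mm$capillary_only_cover, 0.05)
})
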