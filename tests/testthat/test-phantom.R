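test_that("rasterization labels lumens, tails only under large vessels", {
  # empty tree -> all static
  empty <- phantom_spec(grid_dim = c(8L, 8L, 8L), segments = list(), seed = 1L)
  t0 <- rasterize_phantom(empty)
  expect_true(all(t0$label == 0L))

  # one axial-orthogonal large segment: tails span ceiling(depth/dz) slices
  spec <- phantom_spec(grid_dim = c(40L, 24L, 24L), pitch_um = c(3, 3, 3),
                       segments = list(vessel_segment(c(30, 36, 0), c(30, 36, 72),
                                                      15, "large")),
                       tail_depth_um = 30, seed = 1L)
  tr <- rasterize_phantom(spec)
  expect_gt(sum(tr$label == 3L), 0)
  # pick a column through the vessel center
  col <- tr$label[, 12, 12]
  zb <- max(which(col == 2L))
  tail_z <- which(col == 3L)
  expect_equal(tail_z, seq(zb + 1L, zb + ceiling(30 / 3)))
  # tails only in columns that contain large lumen
  large_cols <- apply(tr$label == 2L, c(2, 3), any)
  tail_cols <- apply(tr$label == 3L, c(2, 3), any)
  expect_true(all(!tail_cols | large_cols))

  # capillary-only phantom has no tails
  spec_c <- phantom_spec(grid_dim = c(40L, 24L, 24L),
                         segments = list(vessel_segment(c(30, 36, 0),
                                                        c(30, 36, 72), 4,
                                                        "capillary")),
                         seed = 1L)
  expect_equal(sum(rasterize_phantom(spec_c)$label == 3L), 0)

  # out-of-grid segment rejected
  spec_bad <- phantom_spec(grid_dim = c(8L, 8L, 8L),
                           segments = list(vessel_segment(c(10, 10, 10),
                                                          c(10, 10, 99), 4,
                                                          "capillary")),
                           seed = 1L)
  expect_error(rasterize_phantom(spec_bad), "outside grid")
})

test_that("segment class/radius invariants hold", {
  expect_error(vessel_segment(c(0, 0, 0), c(0, 0, 9), 5, "large"), "radius")
  expect_error(vessel_segment(c(0, 0, 0), c(0, 0, 9), 12, "capillary"), "radius")
  expect_equal(vessel_segment(c(0, 0, 0), c(0, 0, 9), 12, "large")$tau_c_ms, 0.05)
  expect_equal(vessel_segment(c(0, 0, 0), c(0, 0, 9), 4, "capillary")$tau_c_ms, 5)
})

test_that("noise-free static voxels are constant in time", {
  spec <- phantom_spec(grid_dim = c(4L, 4L, 4L), segments = list(),
                       noise_sigma = 0, seed = 3L)
  tr <- rasterize_phantom(spec)
  s <- simulate_field_series(tr, spec, protocol_repeated_A(), seed = 3L)
  first <- s$data[, , , 1]
  for (t in 2:dim(s$data)[4]) expect_identical(s$data[, , , t], first)
  # hence OMAG-style differences vanish and |g1| = 1 at every lag
  g <- oracle_g1_voxel(s$data[1, 1, 1, ], 10)
  expect_equal(Mod(g), rep(1, 11), tolerance = 1e-12)
})

test_that("AR(1) lumen voxels reproduce the closed-form g1 decay", {
  # >= 10^3 voxels per class, noise-free; ensemble complex-averaged g1
  n <- 1200L
  mk <- function(tau_c) {
    spec <- phantom_spec(grid_dim = c(1L, n, 1L), pitch_um = c(3, 3, 3),
                         segments = list(), noise_sigma = 0, seed = 5L)
    tr <- rasterize_phantom(spec)
    tr$label[] <- 1L            # all capillary lumen
    tr$tau_c_map[] <- tau_c
    simulate_field_series(tr, spec, protocol_repeated_A(), seed = 5L)
  }
  dt <- 1 / 76
  # capillary: tau_c = 5 ms, |g1| at the last usable lag ~ exp(-0.645/5)
  s_cap <- mk(5)
  g_cap <- ensemble_g1(s_cap, c(5L, 10L, 20L, 25L, 49L))
  expect_lt(max(abs(g_cap - exp(-c(5, 10, 20, 25, 49) * dt / 5))), 0.02)
  # and stays above 0.85 across the whole span
  expect_true(all(g_cap > 0.85))

  # large vessel: tau_c = 0.05 ms, |g1| at lag 10 ~ exp(-0.132/0.05);
  # lag 49 has a single pair per voxel, so only the < 0.1 bound is asserted
  s_lrg <- mk(0.05)
  g_lrg <- ensemble_g1(s_lrg, c(5L, 10L, 20L, 49L))
  expect_lt(max(abs(g_lrg[1:3] - exp(-c(5, 10, 20) * dt / 0.05))), 0.02)
  expect_lt(g_lrg[2], 0.1)
  expect_lt(g_lrg[4], 0.1)
})

test_that("repeated_B interscan time decorrelates both vessel classes", {
  n <- 1000L
  spec <- phantom_spec(grid_dim = c(1L, n, 2L), pitch_um = c(3, 3, 3),
                       segments = list(), noise_sigma = 0, seed = 6L)
  tr <- rasterize_phantom(spec)
  tr$label[] <- 1L
  tr$tau_c_map[, , 1] <- 5      # capillary
  tr$tau_c_map[, , 2] <- 0.05   # large vessel
  s <- simulate_field_series(tr, spec, protocol_repeated_B(), seed = 6L)
  # lag-1 ensemble autocorrelation per class
  x <- s$data
  g1_lag1 <- function(j) {
    num <- mean(Conj(x[, , j, 1:4]) * x[, , j, 2:5])
    num / mean(Mod(x[, , j, ])^2)
  }
  expect_lt(Mod(g1_lag1(1)), 0.15)
  expect_lt(Mod(g1_lag1(2)), 0.15)
})

test_that("simulation is deterministic given the seed", {
  spec <- small_phantom_spec()
  tr <- rasterize_phantom(spec)
  a <- simulate_field_series(tr, spec, protocol_repeated_B(), seed = 21L)
  b <- simulate_field_series(tr, spec, protocol_repeated_B(), seed = 21L)
  expect_identical(a$data, b$data)
  c2 <- simulate_field_series(tr, spec, protocol_repeated_B(), seed = 22L)
  expect_false(identical(a$data, c2$data))
})
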