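make_series_A <- function(m) series_from_matrix(m, protocol_repeated_A())

test_that("autocorrelation_g1 matches closed forms and the loop oracle", {
  # constant series -> g1 == 1 at every lag
  m <- matrix(2 - 1i, 4, 50)
  g <- autocorrelation_g1(make_series_A(m), 49L)
  expect_true(all(abs(g$g1 - (1 + 0i)) < 1e-12))

  # pure oscillation exp(i w t) -> g1(tau) = exp(i w tau), |g1| = 1
  w <- pi / 4
  mo <- matrix(exp(1i * w * (0:49)), 1, 50, byrow = TRUE)
  go <- autocorrelation_g1(make_series_A(mo), 49L)
  taus <- 0:49
  expect_equal(as.vector(go$g1[1, 1, 1, ]), exp(1i * w * taus),
               tolerance = 1e-12)

  # random 10-sample series, max_lag 5, against the brute-force oracle
  set.seed(20)
  n <- 1000L
  mr <- matrix(complex(real = rnorm(n * 10), imaginary = rnorm(n * 10)), n, 10)
  sr <- field_series(array(mr, c(1L, n, 1L, 10L)), c(3, 3, 3),
                     acquisition_protocol("repeated_A", 10L, 1 / 76))
  gr <- autocorrelation_g1(sr, 5L)
  for (v in c(1L, 17L, 500L, 1000L)) {
    want <- oracle_g1_voxel(mr[v, ], 5L)
    expect_lt(max(Mod(gr$g1[1, v, 1, ] - want)), 1e-12)
  }
  # full-volume check
  want_all <- t(vapply(seq_len(n), function(v) oracle_g1_voxel(mr[v, ], 5L),
                       complex(6)))
  got_all <- matrix(gr$g1[1, , 1, ], n, 6)
  expect_lt(max(Mod(got_all - want_all)), 1e-12)

  # g1(0) is exactly 1 and |g1| <= 1 + eps everywhere on random data
  expect_true(all(gr$g1[, , , 1] == 1 + 0i))

  # zero-power voxel: flagged, g1(0) = 1 and 0 beyond
  mz <- matrix(0 + 0i, 2, 10)
  sz <- field_series(array(mz, c(1L, 2L, 1L, 10L)), c(3, 3, 3),
                     acquisition_protocol("repeated_A", 10L, 1 / 76))
  gz <- autocorrelation_g1(sz, 5L)
  expect_true(all(gz$zero_power))
  expect_true(all(gz$g1[, , , 1] == 1 + 0i))
  expect_true(all(gz$g1[, , , -1] == 0 + 0i))
})

test_that("select_ntau keeps drifting voxels long and chaotic voxels short", {
  # pure drift: g1(tau) = exp(i w tau) * decay -> zero variance -> long
  w <- 0.3
  decay <- exp(-(0:49) / 20)
  g1v <- decay * exp(1i * w * (0:49))
  gf <- structure(list(g1 = array(g1v, c(1, 1, 1, 50)),
                       zero_power = array(FALSE, c(1, 1, 1)),
                       ntau_map = NULL, chaos_map = NULL, max_lag = 49L,
                       pitch_um = c(3, 3, 3),
                       protocol = protocol_repeated_A()),
                  class = "g1_field")
  out <- select_ntau(gf, probe_lags = 8L, chaos_threshold = 0.4)
  expect_equal(out$chaos_map[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(out$ntau_map[1, 1, 1], 49L)

  # iid uniform g1 phases -> chaotic -> >= 99% assigned short over 10^3 draws
  set.seed(21)
  nv <- 1000L
  ph <- matrix(runif(nv * 50, -pi, pi), nv, 50)
  g1c <- exp(1i * ph)
  gfc <- structure(list(g1 = aperm(array(g1c, c(nv, 1, 1, 50)), c(2, 3, 1, 4)),
                        zero_power = array(FALSE, c(1, 1, nv)),
                        ntau_map = NULL, chaos_map = NULL, max_lag = 49L,
                        pitch_um = c(3, 3, 3),
                        protocol = protocol_repeated_A()),
                   class = "g1_field")
  outc <- select_ntau(gfc, probe_lags = 8L, chaos_threshold = 0.4)
  expect_gte(mean(outc$ntau_map == 1L), 0.99)
})

test_that("phantom confusion: tails go short, capillaries go long", {
  res <- default_phantom_run()
  lab <- res$truth$label
  nt <- res$g1_maps$ntau
  expect_gte(mean(nt[lab == 3L] == 1L), 0.9)
  expect_gte(mean(nt[lab == 1L] == 49L), 0.9)
})

test_that("ag1_index implements the horizon-min decorrelation exactly", {
  mk_gf <- function(absg1_mat, ntau_vec) {
    nv <- nrow(absg1_mat)
    g1 <- cbind(1, absg1_mat)  # lag 0 prepended
    structure(list(g1 = array(complex(real = g1, imaginary = 0),
                              c(1, nv, 1, ncol(g1))),
                   zero_power = array(FALSE, c(1, nv, 1)),
                   ntau_map = array(as.integer(ntau_vec), c(1, nv, 1)),
                   chaos_map = array(0, c(1, nv, 1)), max_lag = ncol(absg1_mat),
                   pitch_um = c(3, 3, 3), protocol = protocol_repeated_A()),
              class = "g1_field")
  }
  # ntau = 1 -> Id = 0 exactly (tail-suppression mechanism)
  a <- matrix(runif(10 * 20), 10, 20)
  out1 <- ag1_index(mk_gf(a, rep(1L, 10)))
  expect_true(all(out1$data == 0))

  # strictly decreasing |g1|, ntau = 10 -> Id = |g1(1)| - |g1(10)|
  dec <- matrix(rep(seq(0.95, 0.05, length.out = 20), each = 3), 3, 20)
  out2 <- ag1_index(mk_gf(dec, rep(10L, 3)))
  expect_equal(as.vector(out2$data), rep(dec[1, 1] - dec[1, 10], 3),
               tolerance = 1e-14)

  # random |g1| and horizons match the loop oracle within 1e-12
  set.seed(22)
  nv <- 1000L
  am <- matrix(runif(nv * 30), nv, 30)
  nt <- sample(1:30, nv, replace = TRUE)
  out3 <- ag1_index(mk_gf(am, nt))
  want <- vapply(seq_len(nv), function(v) oracle_ag1_voxel(am[v, ], nt[v]),
                 numeric(1))
  expect_lt(max(abs(as.vector(out3$data[1, , 1]) - want)), 1e-12)

  # monotone in the horizon: larger ntau never decreases Id
  out_small <- ag1_index(mk_gf(am, pmax(nt - 5L, 1L)))
  expect_true(all(out3$data - out_small$data >= -1e-15))
})

test_that("Id is bounded by |g1(1)| and by 1 on phantom data", {
  res <- small_phantom_run()
  g1f <- cached("small_g1", {
    spec <- small_phantom_spec()
    tr <- rasterize_phantom(spec)
    sa <- simulate_field_series(tr, spec, protocol_repeated_A(), seed = 12L)
    select_ntau(autocorrelation_g1(sa, 49L))
  })
  id <- ag1_index(g1f)$data
  expect_true(all(id >= 0))
  expect_true(all(id <= Mod(g1f$g1[, , , 2]) + 1e-9))
  expect_true(all(id <= 1 + 1e-9))
})
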