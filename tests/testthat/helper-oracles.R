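# Independent brute-force oracles and shared fixtures.

# round a double vector through IEEE float32
snap_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          size = 4L, n = length(x))
}

snap_complex32 <- function(z) {
  complex(real = snap_float32(Re(z)), imaginary = snap_float32(Im(z)))
}

# loop-written OMAG index for one voxel time series
oracle_omag_voxel <- function(r) {
  n <- length(r)
  acc <- 0
  for (t in seq_len(n - 1)) acc <- acc + Mod(r[t + 1] - r[t])
  acc / (n - 1)
}

# loop-written g1 for one voxel time series
oracle_g1_voxel <- function(r, max_lag) {
  n <- length(r)
  p <- mean(Mod(r)^2)
  g <- complex(max_lag + 1)
  g[1] <- 1 + 0i
  for (tau in seq_len(max_lag)) {
    s <- 0 + 0i
    for (t in seq_len(n - tau)) s <- s + Conj(r[t]) * r[t + tau]
    g[tau + 1] <- s / (n - tau) / p
  }
  g
}

# loop-written Ag1 index from |g1| lags 1..max_lag and a horizon
oracle_ag1_voxel <- function(absg1, ntau) {
  m <- Inf
  for (tau in seq_len(ntau)) m <- min(m, absg1[tau])
  absg1[1] - m
}

# pooled ensemble autocorrelation magnitude over an homogeneous voxel
# population: |sum_{v,t} conj(R) R_shift| / sum |R|^2 (ratio of pooled
# moments, so the per-voxel small-sample normalization bias cancels)
ensemble_g1 <- function(series, lags) {
  x <- series$data
  nt <- dim(x)[4]
  m <- matrix(x, ncol = nt)
  pow <- mean(Mod(m)^2)
  vapply(lags, function(tau)
    Mod(mean(Conj(m[, 1:(nt - tau), drop = FALSE]) *
               m[, (1 + tau):nt, drop = FALSE])) / pow, numeric(1))
}

# wrap a single-voxel time series into a field_series on a tiny grid
series_from_matrix <- function(m, protocol, pitch = c(3, 3, 3)) {
  # m: nvox x nt complex matrix laid out on a (1, nvox, 1) grid
  arr <- array(0i, dim = c(1L, nrow(m), 1L, ncol(m)))
  arr[1, , 1, ] <- m
  field_series(arr, pitch, protocol)
}

# small phantom used by unit tests (fast; same physics as the default)
small_phantom_spec <- function(seed = 11L) {
  phantom_spec(
    grid_dim = c(32L, 64L, 64L),
    segments = list(
      vessel_segment(c(24, 96, 0), c(24, 96, 192), 15, "large"),
      vessel_segment(c(60, 96, 0), c(60, 96, 192), 4, "capillary"),
      vessel_segment(c(45, 9, 30), c(45, 60, 30), 4, "capillary"),
      vessel_segment(c(45, 30, 120), c(45, 30, 180), 4, "capillary")),
    seed = seed)
}

# memoized heavy fixtures shared across test files (testthat loads helpers
# once per run, so the cache lives for the whole suite)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# the seeded default-conditions phantom run (64 x 128 x 128)
default_phantom_run <- function() {
  cached("default_run", {
    run_pipeline(pipeline_config(seed = 42L),
                 phantom = phantom_spec(seed = 42L), verbose = FALSE)
  })
}

small_phantom_run <- function() {
  cached("small_run", {
    run_pipeline(pipeline_config(seed = 11L),
                 phantom = small_phantom_spec(), verbose = FALSE)
  })
}

make_cylinder <- function(radius_um, nz = 40L, nx = 40L, ny = 40L,
                          pitch = 1.5, axis = "y", value = 1) {
  zc <- (seq_len(nz) - 0.5) * pitch
  xc <- (seq_len(nx) - 0.5) * pitch
  yc <- (seq_len(ny) - 0.5) * pitch
  Z <- array(zc, c(nz, nx, ny))
  X <- array(rep(xc, each = nz), c(nz, nx, ny))
  Y <- array(rep(yc, each = nz * nx), c(nz, nx, ny))
  ctr <- c(nz, nx, ny) * pitch / 2
  r2 <- switch(axis,
               y = (Z - ctr[1])^2 + (X - ctr[2])^2,
               x = (Z - ctr[1])^2 + (Y - ctr[3])^2,
               z = (X - ctr[2])^2 + (Y - ctr[3])^2)
  angiogram(value * (r2 <= radius_um^2), rep(pitch, 3), "fused")
}
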