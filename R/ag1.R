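#' Per-voxel field autocorrelation g1(tau)
#'
#' Computes the normalized temporal autocorrelation of the complex field from
#' an M-mode (repeated A-scan) series:
#' `g1(tau) = <Conj(R(t)) R(t+tau)>_t / <|R(t)|^2>_t`,
#' where the lag-`tau` average runs over the `n_repeats - tau` available
#' pairs and the denominator is the full lag-0 power. `|g1|` decays on the
#' field correlation time: fast for large-vessel flow, slowly for capillary
#' flow, and (with chaotic phase) fast in projection-tail voxels.
#'
#' @param series A repeated-A [field_series()].
#' @param max_lag Largest lag computed; must be `< n_repeats`.
#' @return Object of class `"g1_field"` with the complex `g1` array
#'   `(z, x, y, lag)` for lags `0..max_lag`, a `zero_power` flag array, and
#'   empty `ntau_map` / `chaos_map` slots to be filled by [select_ntau()].
#' @export
autocorrelation_g1 <- function(series, max_lag) {
  stopifnot(inherits(series, "field_series"))
  if (series$protocol$mode != "repeated_A")
    stop("autocorrelation_g1 expects a repeated_A series", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= series$protocol$n_repeats)
    stop("max_lag must be in [1, n_repeats - 1]", call. = FALSE)
  res <- .Call(C_g1_autocorr, series$data, dim(series$data), max_lag)
  structure(list(g1 = res$g1,
                 zero_power = array(res$zero_power, dim = dim(series$data)[1:3]),
                 ntau_map = NULL, chaos_map = NULL,
                 max_lag = max_lag, pitch_um = series$pitch_um,
                 protocol = series$protocol),
            class = "g1_field")
}

#' @export
print.g1_field <- function(x, ...) {
  d <- dim(x$g1)
  cat(sprintf("<g1_field> %d x %d x %d, lags 0..%d%s\n", d[1], d[2], d[3],
              x$max_lag,
              if (is.null(x$ntau_map)) "" else " (ntau selected)"))
  invisible(x)
}

#' Select the per-voxel decorrelation horizon from g1 phase stability
#'
#' Projection-tail voxels decorrelate as fast as large-vessel lumens, so
#' `|g1|` decay alone cannot separate them -- but their g1 *phase* is
#' chaotic, whereas flowing blood shows a smooth (Doppler) phase ramp. The
#' statistic is the circular variance of the lag-to-lag phase increments
#' `dphi(tau) = Arg g1(tau+1) - Arg g1(tau)` over `tau = 1..probe_lags`,
#' computed as the sample variance of the increments wrapped to `(-pi, pi]`
#' (units rad^2, so the statistic ranges over `[0, pi^2)`; a constant-drift
#' phase ramp scores exactly 0 however steep).
#' Voxels with variance above `chaos_threshold` are artifact-like
#' and get the short horizon `ntau_short` (with `ntau_short = 1` the
#' decorrelation index is exactly zero there); all others get `ntau_long`,
#' which maximizes dynamic contrast in vessels.
#'
#' @param g1field A [autocorrelation_g1()] result.
#' @param probe_lags Number of phase increments probed
#'   (`probe_lags + 1 <= max_lag`).
#' @param chaos_threshold Phase-variance cut in (0, pi^2) rad^2; default 0.4.
#' @param ntau_short,ntau_long The two horizons (defaults 1 and `max_lag`).
#' @return The `g1_field` with `ntau_map` and `chaos_map` filled.
#' @export
select_ntau <- function(g1field, probe_lags = 8L, chaos_threshold = 0.4,
                        ntau_short = 1L, ntau_long = g1field$max_lag) {
  stopifnot(inherits(g1field, "g1_field"))
  probe_lags <- as.integer(probe_lags)
  ntau_short <- as.integer(ntau_short); ntau_long <- as.integer(ntau_long)
  if (probe_lags < 2L || probe_lags + 1L > g1field$max_lag)
    stop("probe_lags must satisfy 2 <= probe_lags and probe_lags + 1 <= max_lag", call. = FALSE)
  if (!(ntau_short < ntau_long && ntau_long <= g1field$max_lag &&
        ntau_short >= 1L))
    stop("need 1 <= ntau_short < ntau_long <= max_lag", call. = FALSE)
  ph <- Arg(g1field$g1[, , , 2L:(probe_lags + 2L), drop = FALSE])
  d <- dim(ph)
  dphi <- ph[, , , -1L, drop = FALSE] - ph[, , , -d[4], drop = FALSE]
  dphi <- atan2(sin(dphi), cos(dphi))          # wrap to (-pi, pi]
  dim(dphi) <- c(prod(d[1:3]), probe_lags)
  mu <- rowMeans(dphi)
  v <- (rowSums(dphi^2) - probe_lags * mu^2) / (probe_lags - 1L)
  chaos <- array(pmax(v, 0), dim = d[1:3])
  g1field$chaos_map <- chaos
  g1field$ntau_map <- array(ifelse(chaos > chaos_threshold, ntau_short,
                                   ntau_long), dim = d[1:3])
  g1field
}

#' Adaptive decorrelation contrast index (Ag1) from g1
#'
#' Per voxel, `Id = |g1(1)| - min_{1 <= tau <= ntau} |g1(tau)|` -- the
#' maximum decorrelation reached within the per-voxel horizon after the
#' first lag. Since the minimum includes `tau = 1`, `Id >= 0`; a horizon of 1
#' forces `Id = 0` exactly, which is the tail-suppression mechanism.
#'
#' @param g1field A `g1_field` whose `ntau_map` was filled by [select_ntau()].
#' @return An [angiogram()] with provenance `"ag1"`.
#' @export
ag1_index <- function(g1field) {
  stopifnot(inherits(g1field, "g1_field"))
  if (is.null(g1field$ntau_map))
    stop("ntau_map is empty; run select_ntau() first", call. = FALSE)
  d <- dim(g1field$g1)
  nvox <- prod(d[1:3])
  a <- Mod(g1field$g1)
  dim(a) <- c(nvox, d[4])
  a <- a[, -1L, drop = FALSE]                 # lags 1..max_lag
  runmin <- a
  for (tau in 2:ncol(a))
    runmin[, tau] <- pmin(runmin[, tau - 1L], a[, tau])
  ntau <- as.vector(g1field$ntau_map)
  id <- a[, 1L] - runmin[cbind(seq_len(nvox), ntau)]
  id[id < 0] <- 0   # numerical guard; min includes tau = 1
  angiogram(array(id, dim = d[1:3]), g1field$pitch_um, "ag1")
}
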