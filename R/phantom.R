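#' Vessel segment of a phantom
#'
#' A straight cylindrical segment of the synthetic vessel tree. Flow class
#' encodes the decorrelation physics: fast flow in large vessels decorrelates
#' the field quickly (default correlation time 0.05 ms), slow capillary flow
#' decorrelates it far more slowly (default 5 ms). Radii are tied to class:
#' `large` requires a radius >= 10 um (diameter >= 20 um), `capillary` < 10 um.
#'
#' @param p0,p1 Endpoints, numeric length-3 `(z, x, y)` in micrometers.
#' @param radius_um Lumen radius in micrometers.
#' @param flow_class `"large"` or `"capillary"`.
#' @param tau_c_ms Field correlation time in ms; defaults by class.
#' @export
vessel_segment <- function(p0, p1, radius_um,
                           flow_class = c("large", "capillary"),
                           tau_c_ms = NULL) {
  flow_class <- match.arg(flow_class)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3L, length(p1) == 3L)
  if (!is.finite(radius_um) || radius_um <= 0)
    stop("radius_um must be > 0", call. = FALSE)
  if (flow_class == "large" && radius_um < 10)
    stop("large segments need radius_um >= 10 (diameter >= 20 um)", call. = FALSE)
  if (flow_class == "capillary" && radius_um >= 10)
    stop("capillary segments need radius_um < 10", call. = FALSE)
  if (is.null(tau_c_ms))
    tau_c_ms <- if (flow_class == "large") 0.05 else 5
  if (tau_c_ms <= 0) stop("tau_c_ms must be > 0", call. = FALSE)
  structure(list(p0 = p0, p1 = p1, radius_um = radius_um,
                 flow_class = flow_class, tau_c_ms = tau_c_ms),
            class = "vessel_segment")
}

#' Default phantom vessel tree
#'
#' One 30 um-diameter pial vessel plus four 8 um capillaries, one of which
#' runs directly beneath the large vessel inside its projection column (the
#' configuration whose recovery is the whole point of the dual-scheme merge).
#' Coordinates assume the default 64 x 128 x 128 grid at 3 um pitch.
#' @export
default_vessel_tree <- function() {
  list(
    vessel_segment(c(46.5, 192, 0), c(46.5, 192, 384), 15, "large"),
    vessel_segment(c(120, 192, 0), c(120, 192, 384), 4, "capillary"),
    vessel_segment(c(90, 15, 60), c(90, 165, 60), 4, "capillary"),
    vessel_segment(c(105, 300, 30), c(105, 300, 354), 4, "capillary"),
    vessel_segment(c(75, 225, 240), c(75, 369, 339), 4, "capillary")
  )
}

#' Phantom specification
#'
#' Declarative description of a synthetic speckle-field volume: a vessel tree
#' embedded in static scattering tissue, plus the tail-artifact columns that
#' multiply scattered photons paint beneath large vessels. Defaults are the
#' package's reference study conditions: 64 x 128 x 128 voxels at 3 um
#' isotropic pitch, static speckle amplitude 1, additive complex noise 5% of
#' it, tails extending 120 um below the large-vessel lumen at 60% amplitude
#' with fully chaotic phase (2 rad r.m.s. per-step increments).
#'
#' @param grid_dim Integer `(nz, nx, ny)`.
#' @param pitch_um Voxel pitch `(dz, dx, dy)` in micrometers.
#' @param segments List of [vessel_segment()]s.
#' @param static_amp Mean static speckle amplitude (per-voxel r.m.s.).
#' @param noise_sigma Std of the additive circular complex noise.
#' @param tail_depth_um Extent of the artifact column beneath large lumens.
#' @param tail_tau_c_ms Tail field correlation time (matches large vessels,
#'   so magnitude decay alone cannot tell tails apart).
#' @param tail_phase_jitter_rad Std of the per-step random phase increments in
#'   tail voxels -- the "chaotic phase" the adaptive horizon keys on.
#' @param tail_attenuation Multiplicative tail amplitude factor in (0, 1].
#' @param phase_drift_rad_per_ms Deterministic Doppler-like phase drift of
#'   lumen voxels (0.2 rad per M-mode step at the default A-line rate).
#' @param seed Integer seed for [simulate_field_series()].
#' @export
phantom_spec <- function(grid_dim = c(64L, 128L, 128L),
                         pitch_um = c(3, 3, 3),
                         segments = default_vessel_tree(),
                         static_amp = 1,
                         noise_sigma = 0.05,
                         tail_depth_um = 120,
                         tail_tau_c_ms = 0.05,
                         tail_phase_jitter_rad = 2,
                         tail_attenuation = 0.6,
                         phase_drift_rad_per_ms = 15.2,
                         seed = 42L) {
  grid_dim <- as.integer(grid_dim)
  pitch_um <- as.numeric(pitch_um)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 1L),
            length(pitch_um) == 3L, all(pitch_um > 0))
  if (!all(vapply(segments, inherits, TRUE, "vessel_segment")))
    stop("segments must be a list of vessel_segment objects", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (tail_phase_jitter_rad <= 0)
    stop("tail_phase_jitter_rad must be > 0", call. = FALSE)
  if (tail_attenuation <= 0 || tail_attenuation > 1)
    stop("tail_attenuation must lie in (0, 1]", call. = FALSE)
  if (tail_tau_c_ms <= 0 || tail_depth_um < 0 || static_amp <= 0)
    stop("invalid phantom scalar parameter", call. = FALSE)
  structure(list(grid_dim = grid_dim, pitch_um = pitch_um, segments = segments,
                 static_amp = static_amp, noise_sigma = noise_sigma,
                 tail_depth_um = tail_depth_um, tail_tau_c_ms = tail_tau_c_ms,
                 tail_phase_jitter_rad = tail_phase_jitter_rad,
                 tail_attenuation = tail_attenuation,
                 phase_drift_rad_per_ms = phase_drift_rad_per_ms,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build a phantom_spec from a plain list (YAML config)
#' @param x A list as produced by parsing the `phantom:` config section;
#'   segments are lists with `p0`, `p1`, `radius_um`, `flow_class` and
#'   optional `tau_c_ms`.
#' @export
phantom_spec_from_list <- function(x) {
  if (!is.null(x$segments))
    x$segments <- lapply(x$segments, function(s)
      vessel_segment(as.numeric(s$p0), as.numeric(s$p1), s$radius_um,
                     s$flow_class, s$tau_c_ms))
  do.call(phantom_spec, x)
}

# voxel-class codes used in truth volumes
PHANTOM_CLASSES <- c(static = 0L, capillary_lumen = 1L, large_lumen = 2L,
                     tail = 3L)

#' Rasterize a phantom into per-voxel ground truth
#'
#' Voxels whose centers lie within `radius_um` of a segment axis become lumen
#' (large segments take precedence over capillaries in the measure-zero case
#' of an overlap); tail labels are painted beneath the deepest large-lumen
#' voxel of each en-face column, down to `tail_depth_um`, and never override
#' a lumen. Everything else is static tissue.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `"truth_volume"`: integer `label` array
#'   (0 static, 1 capillary lumen, 2 large lumen, 3 tail), a `tau_c_map`
#'   (ms; `Inf` for static), pitch, and the class code table.
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim; p <- spec$pitch_um
  extent <- d * p
  for (s in spec$segments) {
    for (ax in 1:3)
      if (s$p0[ax] < 0 || s$p0[ax] > extent[ax] ||
          s$p1[ax] < 0 || s$p1[ax] > extent[ax])
        stop("segment endpoint outside grid extent", call. = FALSE)
  }
  zc <- (seq_len(d[1]) - 0.5) * p[1]
  xc <- (seq_len(d[2]) - 0.5) * p[2]
  yc <- (seq_len(d[3]) - 0.5) * p[3]
  Z <- array(zc, dim = d)
  X <- array(rep(xc, each = d[1]), dim = d)
  Y <- array(rep(yc, each = d[1] * d[2]), dim = d)

  label <- array(PHANTOM_CLASSES[["static"]], dim = d)
  tau <- array(Inf, dim = d)
  ord <- order(vapply(spec$segments, function(s) s$flow_class == "large", TRUE))
  for (s in spec$segments[ord]) {
    ab <- s$p1 - s$p0
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dist2 <- (Z - s$p0[1])^2 + (X - s$p0[2])^2 + (Y - s$p0[3])^2
    } else {
      tt <- ((Z - s$p0[1]) * ab[1] + (X - s$p0[2]) * ab[2] +
             (Y - s$p0[3]) * ab[3]) / len2
      tt <- pmin(pmax(tt, 0), 1)
      dist2 <- (Z - (s$p0[1] + tt * ab[1]))^2 +
               (X - (s$p0[2] + tt * ab[2]))^2 +
               (Y - (s$p0[3] + tt * ab[3]))^2
    }
    inside <- dist2 <= s$radius_um^2
    code <- PHANTOM_CLASSES[[if (s$flow_class == "large") "large_lumen"
                             else "capillary_lumen"]]
    label[inside] <- code
    tau[inside] <- s$tau_c_ms
  }

  n_tail_slices <- ceiling(spec$tail_depth_um / p[1])
  if (n_tail_slices > 0) {
    is_large <- label == PHANTOM_CLASSES[["large_lumen"]]
    cols <- which(apply(is_large, c(2, 3), any), arr.ind = TRUE)
    for (k in seq_len(nrow(cols))) {
      i <- cols[k, 1]; j <- cols[k, 2]
      zb <- max(which(is_large[, i, j]))
      zr <- seq.int(zb + 1L, min(d[1], zb + n_tail_slices))
      if (zb >= d[1]) next
      free <- zr[label[zr, i, j] == PHANTOM_CLASSES[["static"]]]
      label[free, i, j] <- PHANTOM_CLASSES[["tail"]]
      tau[free, i, j] <- spec$tail_tau_c_ms
    }
  }
  structure(list(label = label, tau_c_map = tau, pitch_um = p,
                 classes = PHANTOM_CLASSES),
            class = "truth_volume")
}

#' @export
print.truth_volume <- function(x, ...) {
  cnt <- table(factor(x$label, levels = PHANTOM_CLASSES,
                      labels = names(PHANTOM_CLASSES)))
  cat("<truth_volume>", paste(dim(x$label), collapse = " x "), "\n")
  print(cnt)
  invisible(x)
}

#' Simulate a complex field series from phantom ground truth
#'
#' Per voxel the field is `R(t) = S + A * D(t) + n(t)`:
#' * static voxels: `S` a fixed circular complex Gaussian speckle draw
#'   (r.m.s. `static_amp`), `D == 0`;
#' * lumen voxels: `S = 0`, `D(t)` a unit-variance complex AR(1) process with
#'   lag-1 coefficient `exp(-dt / tau_c)` (so `E g1(tau) = exp(-tau/tau_c)`
#'   exactly), amplitude `static_amp`, plus a smooth deterministic Doppler
#'   phase drift;
#' * tail voxels: the lumen model with `tau_c = tail_tau_c_ms`, amplitude
#'   scaled by `tail_attenuation`, and an independent random-walk phase with
#'   per-step std `tail_phase_jitter_rad` (chaotic phase);
#' * all voxels receive iid circular complex noise of std `noise_sigma`.
#'
#' Identical `(truth, spec, protocol, seed)` give bit-identical output.
#'
#' @param truth Output of [rasterize_phantom()].
#' @param spec The [phantom_spec()] that produced it.
#' @param protocol An [acquisition_protocol()].
#' @param seed Integer; defaults to `spec$seed`.
#' @return A [field_series()].
#' @export
simulate_field_series <- function(truth, spec, protocol, seed = spec$seed) {
  stopifnot(inherits(truth, "truth_volume"), inherits(spec, "phantom_spec"),
            inherits(protocol, "acquisition_protocol"))
  d <- dim(truth$label)
  nvox <- prod(d)
  nt <- protocol$n_repeats
  dt <- protocol$dt_ms

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  lab <- as.vector(truth$label)
  is_static <- lab == PHANTOM_CLASSES[["static"]]
  is_tail <- lab == PHANTOM_CLASSES[["tail"]]
  is_lumen <- lab == PHANTOM_CLASSES[["capillary_lumen"]] |
              lab == PHANTOM_CLASSES[["large_lumen"]]
  dyn <- which(!is_static)
  n_dyn <- length(dyn)
  n_static <- sum(is_static)

  rho <- exp(-dt / as.vector(truth$tau_c_map)[dyn])
  amp <- ifelse(is_tail[dyn], spec$static_amp * spec$tail_attenuation,
                spec$static_amp)
  drift <- ifelse(is_lumen[dyn], spec$phase_drift_rad_per_ms * dt, 0)
  jitter_idx <- which(is_tail[dyn])
  n_jit <- length(jitter_idx)

  cn <- function(n, sigma = 1) complex(real = stats::rnorm(n, sd = sigma / sqrt(2)),
                                       imaginary = stats::rnorm(n, sd = sigma / sqrt(2)))

  S <- cn(n_static, spec$static_amp)
  D <- cn(n_dyn, 1)
  phi <- numeric(n_dyn)

  out <- array(0i, dim = c(d, nt))
  sq <- sqrt(1 - rho^2)
  for (t in seq_len(nt)) {
    if (t > 1L) {
      D <- rho * D + sq * cn(n_dyn, 1)
      if (n_jit) phi[jitter_idx] <- phi[jitter_idx] +
          stats::rnorm(n_jit, sd = spec$tail_phase_jitter_rad)
    }
    frame <- complex(real = numeric(nvox), imaginary = numeric(nvox))
    frame[is_static] <- S
    frame[dyn] <- amp * D * exp(1i * (phi + drift * (t - 1L)))
    if (spec$noise_sigma > 0) frame <- frame + cn(nvox, spec$noise_sigma)
    out[, , , t] <- frame
  }
  field_series(out, spec$pitch_um, protocol)
}
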