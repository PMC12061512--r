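#' Bulk-motion phase compensation for repeated B-scans
#'
#' Physiological motion between consecutive B-scan frames adds a global phase
#' to each A-line; left uncorrected it inflates the complex-difference
#' contrast everywhere. For each adjacent frame pair `(t, t+1)` and each
#' `(x, y)` A-line a single phase `phi` is estimated as the argument of the
#' depth-sum of `Conj(R(t)) * R(t+1)`, and frame `t+1` is rotated by
#' `exp(-1i * phi)` (cumulatively, so later frames inherit earlier
#' corrections). Magnitudes are untouched. A-lines with zero energy get
#' `phi = 0`.
#'
#' @param series A repeated-B [field_series()].
#' @return A [field_series()] with compensated phases.
#' @export
bulk_phase_correct <- function(series) {
  stopifnot(inherits(series, "field_series"))
  if (series$protocol$mode != "repeated_B")
    stop("bulk_phase_correct expects a repeated_B series", call. = FALSE)
  x <- series$data
  nt <- dim(x)[4]
  for (t in seq_len(nt - 1L)) {
    cross <- colSums(Conj(x[, , , t]) * x[, , , t + 1L])  # sum over z -> (x, y)
    phi <- ifelse(Mod(cross) == 0, 0, Arg(cross))
    rot <- exp(-1i * phi)
    x[, , , t + 1L] <- x[, , , t + 1L] *
      rep(rot, each = dim(x)[1])
  }
  field_series(x, series$pitch_um, series$protocol)
}

#' OMAG dynamic contrast index from repeated B-scans
#'
#' The classic complex-difference contrast: per voxel
#' `Id = (1/(N-1)) * sum_t |R(t+1) - R(t)|` over the N repeated frames.
#' Moving scatterers decorrelate the field between frames and light up;
#' static tissue cancels. Run [bulk_phase_correct()] first on in vivo data.
#'
#' @param series A repeated-B [field_series()] with `N >= 2` repeats.
#' @return An [angiogram()] with provenance `"omag"`.
#' @export
omag_index <- function(series) {
  stopifnot(inherits(series, "field_series"))
  if (series$protocol$mode != "repeated_B")
    stop("omag_index expects a repeated_B series", call. = FALSE)
  x <- series$data
  nt <- dim(x)[4]
  if (nt < 2L) stop("need at least 2 repeats", call. = FALSE)
  acc <- array(0, dim = dim(x)[1:3])
  for (t in seq_len(nt - 1L))
    acc <- acc + Mod(x[, , , t + 1L] - x[, , , t])
  angiogram(acc / (nt - 1L), series$pitch_um, "omag")
}
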