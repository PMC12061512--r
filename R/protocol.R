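#' Acquisition protocol for a repeated-scan OCT field series
#'
#' Describes how the time axis of a [field_series()] was sampled. Two
#' protocols are supported: `"repeated_A"` (M-mode; many A-scans back-to-back
#' at one transverse position, finely sampled but spanning a very short time)
#' and `"repeated_B"` (a handful of repeated B-scan frames with a long
#' inter-frame interval). The default parameters follow the acquisition used
#' throughout this package: 50 repeats at a 76 kHz A-line rate for M-mode,
#' and 5 frames at ~10 ms for repeated B-scans.
#'
#' @param mode `"repeated_A"` or `"repeated_B"`.
#' @param n_repeats Number of time samples per voxel (>= 2).
#' @param dt_ms Inter-sample interval in milliseconds (> 0).
#' @return An object of class `"acquisition_protocol"`.
#' @seealso [observation_span()], [acquisition_lapse()]
#' @export
#' @examples
#' p <- protocol_repeated_A()
#' observation_span(p)  # ~0.645 ms
acquisition_protocol <- function(mode = c("repeated_A", "repeated_B"),
                                 n_repeats, dt_ms) {
  mode <- match.arg(mode)
  n_repeats <- as.integer(n_repeats)
  stopifnot(length(n_repeats) == 1L, length(dt_ms) == 1L)
  if (is.na(n_repeats) || n_repeats < 2L)
    stop("n_repeats must be an integer >= 2", call. = FALSE)
  if (!is.finite(dt_ms) || dt_ms <= 0)
    stop("dt_ms must be > 0", call. = FALSE)
  structure(list(mode = mode, n_repeats = n_repeats, dt_ms = as.numeric(dt_ms)),
            class = "acquisition_protocol")
}

#' @rdname acquisition_protocol
#' @export
protocol_repeated_A <- function(n_repeats = 50L, dt_ms = 1 / 76) {
  acquisition_protocol("repeated_A", n_repeats, dt_ms)
}

#' @rdname acquisition_protocol
#' @export
protocol_repeated_B <- function(n_repeats = 5L, dt_ms = 10) {
  acquisition_protocol("repeated_B", n_repeats, dt_ms)
}

#' Time spanned by a protocol
#'
#' `observation_span()` is the interval between the first and the last sample,
#' `(n_repeats - 1) * dt_ms`; `acquisition_lapse()` is the total time budget of
#' the repeat block, `n_repeats * dt_ms` (the "~0.66 ms vs ~50 ms" comparison
#' between M-mode and repeated B-scans uses the lapse).
#'
#' @param protocol An [acquisition_protocol()].
#' @return Time in milliseconds.
#' @export
observation_span <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  (protocol$n_repeats - 1) * protocol$dt_ms
}

#' @rdname observation_span
#' @export
acquisition_lapse <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$n_repeats * protocol$dt_ms
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %s: %d repeats, dt = %.5g ms (span %.4g ms)\n",
              x$mode, x$n_repeats, x$dt_ms, observation_span(x)))
  invisible(x)
}
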