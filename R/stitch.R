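#' Find the axial offset between two overlapping volumes
#'
#' Multi-focal-depth acquisitions share an axial overlap; the offset is found
#' by maximizing the cosine similarity `<a, b> / (|a| |b|)` over the
#' flattened overlapping slab at each candidate integer offset (volume B's
#' slice 1 aligned to volume A's slice `offset + 1`). Cosine similarity is
#' invariant to positive global scaling of either volume, so exposure
#' differences between focal depths do not bias the search. Ties go to the
#' smallest offset; a zero-norm overlap scores 0.
#'
#' @param volA,volB [angiogram()]s sharing the en-face grid.
#' @param search Integer vector of candidate offsets (default
#'   `0:(nzA - 1)`); every candidate must leave at least one overlapping
#'   slice.
#' @return Object of class `"stitch_result"`: `z_offset`, `similarity` and
#'   the full `profile` (data.frame offset/similarity).
#' @export
best_z_offset <- function(volA, volB, search = NULL) {
  stopifnot(inherits(volA, "angiogram"), inherits(volB, "angiogram"))
  dA <- dim(volA$data); dB <- dim(volB$data)
  if (!identical(dA[2:3], dB[2:3]))
    stop("volumes must share the en-face grid", call. = FALSE)
  if (is.null(search)) search <- 0:(dA[1] - 1L)
  search <- as.integer(search)
  if (any(search < 0L) || any(search >= dA[1]))
    stop("search offsets must leave at least one overlapping slice", call. = FALSE)
  sim <- vapply(search, function(k) {
    n_ov <- min(dA[1] - k, dB[1])
    a <- as.vector(volA$data[(k + 1L):(k + n_ov), , ])
    b <- as.vector(volB$data[1:n_ov, , ])
    na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }, numeric(1))
  best <- which.max(sim)  # first maximum -> smallest offset on ties
  structure(list(z_offset = search[best], similarity = sim[best],
                 profile = data.frame(offset = search, similarity = sim)),
            class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("<stitch_result> z_offset = %d (similarity %.4f over %d candidates)\n",
              x$z_offset, x$similarity, nrow(x$profile)))
  invisible(x)
}

#' Blend a stack of axially offset volumes
#'
#' Concatenates volumes along depth at the given absolute offsets, combining
#' overlapping slices with a linear ramp (the shallower volume's weight
#' falls 1 to 0 across the overlap; `hard_cut = TRUE` switches at the overlap
#' midpoint instead). Successive volumes can be brightness-matched on the
#' overlap with the same percentile scaler used by the fusion stage.
#'
#' @param vols Ordered (shallow to deep) list of [angiogram()]s on a shared
#'   en-face grid.
#' @param offsets Integer absolute z offsets, one per volume, first must
#'   be 0; a gap (offset beyond the end of the previous stack) is an error.
#' @param hard_cut Replace the linear ramp by a midpoint switch.
#' @param match_brightness Rescale each incoming volume so its overlap p99
#'   matches the accumulated stack's.
#' @return An [angiogram()] with depth `last offset + last volume depth`.
#' @export
blend_stack <- function(vols, offsets, hard_cut = FALSE,
                        match_brightness = FALSE) {
  stopifnot(length(vols) >= 1L, length(offsets) == length(vols))
  lapply(vols, function(v) stopifnot(inherits(v, "angiogram")))
  offsets <- as.integer(offsets)
  if (offsets[1] != 0L) stop("first offset must be 0", call. = FALSE)
  if (any(diff(offsets) < 0L)) stop("offsets must be nondecreasing", call. = FALSE)
  d2 <- dim(vols[[1]]$data)[2:3]
  acc <- vols[[1]]$data
  prov <- vols[[1]]$provenance
  for (i in seq_along(vols)[-1]) {
    v <- vols[[i]]$data
    if (!identical(dim(v)[2:3], d2))
      stop("volumes must share the en-face grid", call. = FALSE)
    k <- offsets[i]
    n_acc <- dim(acc)[1]
    ov <- n_acc - k
    if (ov < 0L)
      stop(sprintf("offset %d leaves a gap after depth %d", k, n_acc),
           call. = FALSE)
    if (ov > dim(v)[1]) stop("volume fully contained in the stack", call. = FALSE)
    if (match_brightness && ov > 0L) {
      pa <- stats::quantile(acc[(k + 1L):n_acc, , ], 0.99, names = FALSE)
      pb <- stats::quantile(v[seq_len(ov), , ], 0.99, names = FALSE)
      if (pb > 0) v <- v * (pa / pb)
    }
    if (ov > 0L) {
      wB <- if (ov == 1L) 0.5 else seq(0, 1, length.out = ov)
      if (hard_cut) wB <- as.numeric(wB >= 0.5)
      wArr <- array(rep(wB, times = prod(d2)), dim = c(ov, d2))
      acc[(k + 1L):n_acc, , ] <- (1 - wArr) * acc[(k + 1L):n_acc, , ] +
        wArr * v[seq_len(ov), , ]
    }
    if (dim(v)[1] > ov) {
      tail_part <- v[(ov + 1L):dim(v)[1], , , drop = FALSE]
      new_acc <- array(0, dim = c(n_acc + dim(tail_part)[1], d2))
      new_acc[seq_len(n_acc), , ] <- acc
      new_acc[(n_acc + 1L):dim(new_acc)[1], , ] <- tail_part
      acc <- new_acc
    }
  }
  angiogram(acc, vols[[1]]$pitch_um, prov)
}
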