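#' Evaluate reconstructed angiograms against phantom truth
#'
#' Detection masks are obtained by thresholding each volume at half its
#' median over the *true* lumen voxels of the class being scored (a
#' truth-conditioned threshold, so no tuning on the output itself), then
#' scored with the Dice coefficient `2|A^B| / (|A| + |B|)`. Tail suppression
#' is the ratio of the output's mean index over true tail voxels to OMAG's.
#'
#' @param output The volume under evaluation (fused or OOF [angiogram()]).
#' @param omag_vol,ag1_vol The single-scheme [angiogram()]s.
#' @param truth A [rasterize_phantom()] truth volume.
#' @return Object of class `"octa_report"`.
#' @export
evaluate_angiograms <- function(output, omag_vol, ag1_vol, truth) {
  stopifnot(inherits(output, "angiogram"), inherits(truth, "truth_volume"))
  check_same_grid(output, omag_vol)
  check_same_grid(output, ag1_vol)
  if (!identical(dim(output$data), dim(truth$label)))
    stop("output and truth are on different grids", call. = FALSE)
  lab <- truth$label
  cap <- lab == PHANTOM_CLASSES[["capillary_lumen"]]
  lrg <- lab == PHANTOM_CLASSES[["large_lumen"]]
  tail_m <- lab == PHANTOM_CLASSES[["tail"]]
  if (!any(cap) && !any(lrg))
    stop("truth volume contains no lumen voxels", call. = FALSE)

  omag_tail <- mean(omag_vol$data[tail_m])
  structure(list(
    tail_suppression_ratio = if (any(tail_m) && omag_tail > 0)
      mean(output$data[tail_m]) / omag_tail else NA_real_,
    capillary_dice = dice_class(output$data, cap),
    large_vessel_dice = dice_class(output$data, lrg),
    capillary_dice_omag = dice_class(omag_vol$data, cap),
    capillary_dice_ag1 = dice_class(ag1_vol$data, cap),
    large_vessel_dice_omag = dice_class(omag_vol$data, lrg),
    large_vessel_dice_ag1 = dice_class(ag1_vol$data, lrg),
    mask_column_recall = NA_real_, mask_column_precision = NA_real_,
    runtimes = NULL), class = "octa_report")
}

# Dice between a detection (volume thresholded at half its class-conditional
# median) and the true class mask.
dice_class <- function(vol, class_mask) {
  if (!any(class_mask)) return(NA_real_)
  thr <- 0.5 * stats::median(vol[class_mask])
  det <- vol >= thr
  dice_masks(det, class_mask)
}

#' Dice coefficient between two logical masks
#' @param a,b Logical arrays of identical shape.
#' @export
dice_masks <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}

#' @export
print.octa_report <- function(x, ...) {
  cat("<octa_report>\n")
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1, TRUE)
  for (k in names(x)[num])
    cat(sprintf("  %-26s %s\n", k, format(x[[k]], digits = 4)))
  if (!is.null(x$runtimes)) {
    cat("  stage runtimes (s):\n")
    for (k in names(x$runtimes))
      cat(sprintf("    %-24s %.2f\n", k, x$runtimes[[k]]))
  }
  invisible(x)
}

# largest 26-connected component of a 3-D logical array, as a fraction of
# `total` voxels (flood fill; intended for sparse detection masks)
largest_component_fraction <- function(det, total = sum(det)) {
  if (!any(det) || total == 0) return(0)
  d <- dim(det)
  lab <- array(0L, d)
  idx <- which(det)
  nb <- as.matrix(expand.grid(dz = -1:1, dx = -1:1, dy = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  best <- 0L
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      ai <- arrayInd(v, d)
      for (k in seq_len(nrow(nb))) {
        p <- ai + nb[k, ]
        if (any(p < 1L) || any(p > d)) next
        li <- p[1] + (p[2] - 1L) * d[1] + (p[3] - 1L) * d[1] * d[2]
        if (det[li] && lab[li] == 0L) {
          lab[li] <- cur
          queue <- c(queue, li)
        }
      }
    }
    best <- max(best, size)
  }
  best / total
}

# en-face column recall/precision of the mask vs large-lumen truth columns
mask_column_metrics <- function(mask2d, truth) {
  lrg_col <- apply(truth$label == PHANTOM_CLASSES[["large_lumen"]], c(2, 3), any)
  cap_col <- apply(truth$label == PHANTOM_CLASSES[["capillary_lumen"]], c(2, 3), any)
  m <- mask2d$data
  list(recall = if (any(lrg_col)) sum(m & lrg_col) / sum(lrg_col) else NA_real_,
       precision = if (any(m)) sum(m & lrg_col) / sum(m) else NA_real_,
       capillary_only_cover = if (any(cap_col & !lrg_col))
         sum(m & cap_col & !lrg_col) / sum(cap_col & !lrg_col) else NA_real_)
}

#' Run the full dual-scheme reconstruction pipeline
#'
#' Orchestrates: (phantom simulation or container input) -> OMAG contrast
#' (with bulk-phase compensation) -> g1 autocorrelation + adaptive-horizon
#' Ag1 contrast -> large-vessel projection-column mask from the OMAG MIP ->
#' brightness-matched fusion (Ag1 inside the column, OMAG outside) -> OOF
#' capillary enhancement -> evaluation against truth (when available).
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param phantom A [phantom_spec()]; mutually exclusive with the two paths.
#' @param field_a_path,field_b_path HDF5 container paths (repeated_A and
#'   repeated_B on the same grid) if no phantom is given.
#' @param protocol_a,protocol_b Protocols used when simulating the phantom.
#' @param outdir Optional output directory for TIFF volumes and the JSON
#'   report.
#' @param verbose Log one line per stage.
#' @return List with angiograms `omag`, `ag1`, `fused`, `oof`, the `mask`
#'   stage list, `g1_maps` (ntau + chaos), `truth` (or NULL) and `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), phantom = NULL,
                         field_a_path = NULL, field_b_path = NULL,
                         protocol_a = protocol_repeated_A(),
                         protocol_b = protocol_repeated_B(),
                         outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  runtimes <- list()
  truth <- NULL

  t0 <- tic()
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "phantom_spec"))
    truth <- rasterize_phantom(phantom)
    series_a <- simulate_field_series(truth, phantom, protocol_a,
                                      seed = config$seed + 1L)
    series_b <- simulate_field_series(truth, phantom, protocol_b,
                                      seed = config$seed + 2L)
    log_stage("phantom: grid %s, %d segments, seed %d",
              paste(phantom$grid_dim, collapse = "x"),
              length(phantom$segments), config$seed)
  } else {
    if (is.null(field_a_path) || is.null(field_b_path))
      stop("provide either a phantom spec or both container paths", call. = FALSE)
    series_a <- read_field_series(field_a_path)
    series_b <- read_field_series(field_b_path)
    if (!identical(dim(series_a$data)[1:3], dim(series_b$data)[1:3]))
      stop("repeated_A and repeated_B volumes are on different grids",
           call. = FALSE)
  }
  runtimes$input <- tic() - t0

  t0 <- tic()
  omag_vol <- omag_index(bulk_phase_correct(series_b))
  rm(series_b)
  log_stage("omag: N = %d, grid %s, %.2fs", protocol_b$n_repeats,
            paste(dim(omag_vol$data), collapse = "x"), tic() - t0)
  runtimes$omag <- tic() - t0

  t0 <- tic()
  max_lag <- min(config$ag1_max_lag, series_a$protocol$n_repeats - 1L)
  g1f <- autocorrelation_g1(series_a, max_lag)
  rm(series_a); gc(verbose = FALSE)
  g1f <- select_ntau(g1f, probe_lags = config$ag1_probe_lags,
                     chaos_threshold = config$ag1_chaos_threshold,
                     ntau_short = config$ag1_ntau_short,
                     ntau_long = min(config$ag1_ntau_long, max_lag))
  ag1_vol <- ag1_index(g1f)
  g1_maps <- list(ntau = g1f$ntau_map, chaos = g1f$chaos_map)
  rm(g1f); gc(verbose = FALSE)
  log_stage("ag1: max_lag %d, probe %d, chaos > %.2f -> ntau %d else %d",
            max_lag, config$ag1_probe_lags, config$ag1_chaos_threshold,
            config$ag1_ntau_short, min(config$ag1_ntau_long, max_lag))
  runtimes$ag1 <- tic() - t0

  t0 <- tic()
  mask <- build_vessel_mask(omag_vol, config)
  log_stage("mask: threshold %g um, %d/%d columns kept",
            config$diameter_threshold_um, sum(mask$mask2d$data),
            length(mask$mask2d$data))
  runtimes$mask <- tic() - t0

  t0 <- tic()
  s <- match_brightness(ag1_vol, omag_vol, mask$mask3d,
                        percentile = config$fusion_percentile)
  fused <- fuse_volumes(omag_vol, ag1_vol, mask$mask3d, scale = s,
                        feather_px = config$feather_px)
  log_stage("fuse: p%g brightness scale %.3f", config$fusion_percentile, s)
  runtimes$fuse <- tic() - t0

  t0 <- tic()
  oof_vol <- apply_oof_capillaries(fused, mask$mask3d,
                                   scales_um = config$oof_scales_um,
                                   sigma_factor = config$oof_sigma_factor,
                                   percentile = config$fusion_percentile,
                                   capillary_only = config$oof_capillary_only)
  log_stage("oof: scales {%s} um, sigma factor %.2f",
            paste(config$oof_scales_um, collapse = ", "),
            config$oof_sigma_factor)
  runtimes$oof <- tic() - t0

  report <- NULL
  if (!is.null(truth)) {
    report <- evaluate_angiograms(fused, omag_vol, ag1_vol, truth)
    mm <- mask_column_metrics(mask$mask2d, truth)
    report$mask_column_recall <- mm$recall
    report$mask_column_precision <- mm$precision
    report$capillary_only_column_cover <- mm$capillary_only_cover
    report$brightness_scale <- s
    report$runtimes <- runtimes
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    save_angiogram(omag_vol, file.path(outdir, "omag.tif"))
    save_angiogram(ag1_vol, file.path(outdir, "ag1.tif"))
    save_angiogram(fused, file.path(outdir, "fused.tif"))
    save_angiogram(oof_vol, file.path(outdir, "oof.tif"))
    save_mask(mask$mask3d, file.path(outdir, "mask.tif"))
    if (!is.null(report)) {
      rep_json <- report[vapply(report, function(v)
        is.numeric(v) || is.list(v), TRUE)]
      jsonlite::write_json(rep_json, file.path(outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  list(omag = omag_vol, ag1 = ag1_vol, mask = mask, fused = fused,
       oof = oof_vol, g1_maps = g1_maps, truth = truth, report = report)
}
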