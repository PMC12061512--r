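#' Pipeline run configuration
#'
#' Collects every tunable knob of the reconstruction chain with its default.
#' Defaults mirror the reference acquisition: a 20 um diameter threshold for
#' the large-vessel mask, a 49-lag g1 horizon for the 50-repeat M-mode
#' protocol, and a p99 brightness match between the two sub-volumes.
#'
#' @param diameter_threshold_um Minimum vessel diameter kept by the
#'   large-vessel mask (um), default 20.
#' @param oof_scales_um Strictly ascending radii (um) for the multiscale
#'   optimally-oriented-flux filter.
#' @param oof_sigma_factor Gaussian-derivative sigma per scale, as a fraction
#'   of the scale radius.
#' @param oof_capillary_only Apply the OOF enhancement only outside the
#'   large-vessel column mask (default) or to the whole volume.
#' @param ag1_max_lag Upper bound of the g1 lag axis; must stay below the
#'   repeated-A `n_repeats`.
#' @param ag1_probe_lags Number of lag-to-lag phase increments used for the
#'   phase-chaos statistic.
#' @param ag1_chaos_threshold Circular-variance threshold in (0, pi^2) above
#'   which a voxel is treated as artifact-like.
#' @param ag1_ntau_short,ag1_ntau_long Decorrelation horizons assigned to
#'   artifact-like and vessel-like voxels respectively.
#' @param fusion_percentile Percentile in (50, 100) used to match sub-volume
#'   brightness before merging.
#' @param mask_closing Bridge 1-pixel speckle gaps before skeletonization.
#' @param mask_dilate_px Margin (pixels) added around the reconstructed
#'   large-vessel mask to cover the projection halo.
#' @param mask_z_range Optional `c(lo, hi)` z slab for the en-face MIP;
#'   `NULL` uses the full depth.
#' @param feather_px Optional linear feather (pixels) at the fusion boundary;
#'   0 keeps voxel provenance exact.
#' @param seed Integer seed controlling every stochastic component.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(diameter_threshold_um = 20,
                            oof_scales_um = c(3, 4.5, 6, 9, 12),
                            oof_sigma_factor = 0.5,
                            oof_capillary_only = TRUE,
                            ag1_max_lag = 49L,
                            ag1_probe_lags = 8L,
                            ag1_chaos_threshold = 0.4,
                            ag1_ntau_short = 1L,
                            ag1_ntau_long = 49L,
                            fusion_percentile = 99,
                            mask_closing = TRUE,
                            mask_dilate_px = 1L,
                            mask_z_range = NULL,
                            feather_px = 0L,
                            seed = 42L) {
  cfg <- list(diameter_threshold_um = as.numeric(diameter_threshold_um),
              oof_scales_um = as.numeric(oof_scales_um),
              oof_sigma_factor = as.numeric(oof_sigma_factor),
              oof_capillary_only = isTRUE(oof_capillary_only),
              ag1_max_lag = as.integer(ag1_max_lag),
              ag1_probe_lags = as.integer(ag1_probe_lags),
              ag1_chaos_threshold = as.numeric(ag1_chaos_threshold),
              ag1_ntau_short = as.integer(ag1_ntau_short),
              ag1_ntau_long = as.integer(ag1_ntau_long),
              fusion_percentile = as.numeric(fusion_percentile),
              mask_closing = isTRUE(mask_closing),
              mask_dilate_px = as.integer(mask_dilate_px),
              mask_z_range = if (!is.null(mask_z_range)) as.integer(mask_z_range),
              feather_px = as.integer(feather_px),
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!is.finite(cfg$diameter_threshold_um) || cfg$diameter_threshold_um <= 0)
    stop("diameter_threshold_um must be > 0", call. = FALSE)
  s <- cfg$oof_scales_um
  if (length(s) == 0 || any(!is.finite(s)) || any(s <= 0) ||
      (length(s) > 1 && any(diff(s) <= 0)))
    stop("oof_scales_um must be nonempty, positive and strictly ascending",
         call. = FALSE)
  if (cfg$oof_sigma_factor <= 0)
    stop("oof_sigma_factor must be > 0", call. = FALSE)
  if (cfg$ag1_max_lag < 1L)
    stop("ag1_max_lag must be >= 1", call. = FALSE)
  if (cfg$ag1_chaos_threshold <= 0 || cfg$ag1_chaos_threshold >= pi^2)
    stop("ag1_chaos_threshold must lie in (0, pi^2)", call. = FALSE)
  if (!(cfg$ag1_ntau_short < cfg$ag1_ntau_long))
    stop("ag1_ntau_short must be < ag1_ntau_long", call. = FALSE)
  if (cfg$ag1_ntau_long > cfg$ag1_max_lag)
    stop("ag1_ntau_long must be <= ag1_max_lag", call. = FALSE)
  if (cfg$ag1_probe_lags < 2L || cfg$ag1_probe_lags + 1L > cfg$ag1_max_lag)
    stop("ag1_probe_lags must satisfy probe_lags + 1 <= ag1_max_lag",
         call. = FALSE)
  if (cfg$fusion_percentile <= 50 || cfg$fusion_percentile >= 100)
    stop("fusion_percentile must lie in (50, 100)", call. = FALSE)
  if (cfg$mask_dilate_px < 0L)
    stop("mask_dilate_px must be >= 0", call. = FALSE)
  if (!is.null(cfg$mask_z_range) &&
      (length(cfg$mask_z_range) != 2L ||
       cfg$mask_z_range[1] > cfg$mask_z_range[2]))
    stop("mask_z_range must be c(lo, hi) with lo <= hi", call. = FALSE)
  if (cfg$feather_px < 0L) stop("feather_px must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Absent keys fall back to the [pipeline_config()] defaults (e.g. an empty
#' file yields `diameter_threshold_um = 20`); all invariants are enforced
#' after merging. Unknown keys are an error, so typos do not silently become
#' defaults.
#'
#' @param path Path to a YAML key-value file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: '%s'", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), c(known, "phantom"))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  cfg <- do.call(pipeline_config, vals[intersect(names(vals), known)])
  if (!is.null(vals$phantom))
    attr(cfg, "phantom") <- phantom_spec_from_list(vals$phantom)
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
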