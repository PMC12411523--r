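#' Load an analysis or simulation configuration from YAML
#'
#' A flat key-value YAML file; keys map one-to-one onto the arguments of
#' [analysis_config()] or [simulation_config()]. The optional key `type`
#' (`"analysis"`, the default, or `"simulation"`) selects the schema.
#' Missing keys take the study defaults; unknown keys are rejected with a
#' message listing them.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return An `analysis_config` or `sim_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  type <- raw$type %||% "analysis"
  raw$type <- NULL
  ctor <- switch(type,
                 analysis = analysis_config,
                 simulation = simulation_config,
                 stop("config `type` must be \"analysis\" or \"simulation\""))
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(ctor, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest
#'
#' Snapshot of everything needed to reproduce a run exactly: the
#' configuration, input file MD5 hashes, the package version, the RNG
#' seed and a timestamp.
#'
#' @param config An `analysis_config` or `sim_config`.
#' @param inputs Character vector of input file paths (hashed), or `NULL`.
#' @param seed RNG seed used for the run, or `NULL`.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, inputs = NULL, seed = NULL) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs)
    as.list(stats::setNames(unname(h), basename(inputs)))
  }
  structure(
    list(tool = "mpscorr",
         version = as.character(utils::packageVersion("mpscorr")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         config = unclass(config),
         input_hashes = hashes),
    class = "run_manifest"
  )
}

write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

# Fixed column order and 6-significant-digit floats keep result CSVs
# byte-stable across runs for regression diffing.
write_result_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.csv(df, path, row.names = FALSE, na = "NaN")
  invisible(path)
}

#' Analyze an image file end to end
#'
#' Reads a single- or two-channel TIFF, obtains a mask (from a mask TIFF
#' or by smoothing/thresholding one channel), runs [analyze_image()], and
#' writes the per-grid results, the per-angle audit table and a run
#' manifest to `out_dir`.
#'
#' @param image_path Path to the image TIFF (one page per channel).
#' @param pixels_per_um Physical pixel pitch.
#' @param out_dir Output directory (created if needed).
#' @param mask_path Optional mask TIFF (0 background / 255 foreground).
#' @param threshold,smooth_radius Used with [make_mask()] on
#'   `threshold_channel` when no mask file is given.
#' @param threshold_channel Channel used for thresholding (default 1, the
#'   channel with the best contrast should be chosen).
#' @param config An [analysis_config()] or path to a YAML config.
#' @return Invisibly, a list with the output file paths and the analysis
#'   result.
#' @export
analyze_image_file <- function(image_path, pixels_per_um, out_dir,
                               mask_path = NULL, threshold = NULL,
                               smooth_radius = 0, threshold_channel = 1,
                               config = analysis_config()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "analysis_config"))
  img <- read_image_tiff(image_path, pixels_per_um)
  if (!is.null(mask_path)) {
    mask <- read_mask_tiff(mask_path)
    if (!identical(dim(mask), dim(img$mask))) {
      stop("mask shape does not match image shape")
    }
  } else if (!is.null(threshold)) {
    mask <- make_mask(img$channels[[threshold_channel]], threshold,
                      smooth_radius)
  } else {
    stop("either `mask_path` or `threshold` must be supplied")
  }
  img <- masked_image(img$channels, mask, pixels_per_um)
  res <- analyze_image(img, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    per_grid = file.path(out_dir, "per_grid.csv"),
    per_angle = file.path(out_dir, "per_angle.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  pg <- res$per_grid
  if (res$n_channels == 1L) {
    pg <- pg[, c("grid_index", "best_angle_deg", "amp_ch1", "freq_ch1_nm")]
  }
  write_result_csv(pg, paths$per_grid)
  write_result_csv(res$per_angle, paths$per_angle)
  write_manifest(run_manifest(config, c(image_path, mask_path)),
                 paths$manifest)
  invisible(c(paths, list(result = res)))
}

#' Simulate images to a directory
#'
#' Renders a single-channel image (or a two-channel pair) with the given
#' configuration and writes per-channel TIFFs, the zone map, a
#' ground-truth CSV and a run manifest. Image intensities are rescaled to
#' `[0, 1]` for TIFF export (negative noise excursions clipped); the
#' scale factor is recorded in the manifest.
#'
#' @param cfg A [simulation_config()] or path to a YAML config.
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param pattern `NULL` for a single channel, else `"overlapping"` or
#'   `"alternating"`.
#' @param mask_args Extra arguments for [synthetic_axon_mask()].
#' @return Invisibly, the list of written paths plus the simulation.
#' @export
simulate_to_dir <- function(cfg = simulation_config(), out_dir, seed = 1,
                            pattern = NULL, mask_args = list()) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (is.null(pattern)) {
    simulate_image(cfg, seed = seed, mask_args = mask_args)
  } else {
    simulate_pair(cfg, pattern = pattern, seed = seed, mask_args = mask_args)
  }
  chans <- sim$image$channels
  scale <- max(1e-12, max(vapply(chans, max, numeric(1))))
  paths <- list()
  for (i in seq_along(chans)) {
    p <- file.path(out_dir, sprintf("channel%d.tif", i))
    tiff::writeTIFF(pmin(pmax(chans[[i]] / scale, 0), 1), p,
                    bits.per.sample = 16L)
    paths[[sprintf("channel%d", i)]] <- p
  }
  zm <- if (is.null(pattern)) sim$zone_map else sim$zone_maps$base
  paths$zones <- file.path(out_dir, "zones.tif")
  tiff::writeTIFF(zm$zones / 2, paths$zones, bits.per.sample = 8L)
  paths$truth <- file.path(out_dir, "truth.csv")
  truth <- as.data.frame(sim$truth[!vapply(sim$truth, is.null, logical(1))])
  truth$intensity_scale <- scale
  write_result_csv(truth, paths$truth)
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  man <- run_manifest(cfg, NULL, seed)
  man$intensity_scale <- scale
  write_manifest(man, paths$manifest)
  invisible(c(paths, list(simulation = sim)))
}
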