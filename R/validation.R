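#' Precompute zone maps for a set of synthetic study masks
#'
#' Generates `n_masks` synthetic axon masks, extracts their backbones and
#' builds the base (and optionally the half-period-shifted alternating)
#' zone maps once, so that experiments sweeping the periodic localization
#' percentage can re-render points on identical geometry.
#'
#' @param n_masks Number of masks.
#' @param cfg A [simulation_config()] (pixel pitch, spacing, stripe width).
#' @param seed Base RNG seed; mask `i` uses a child seed derived from it.
#' @param mask_args Extra arguments for [synthetic_axon_mask()].
#' @param alternating Also build the shifted map per mask.
#' @return A list of `list(base =, alt =)` zone-map pairs (`alt` is `NULL`
#'   unless requested).
#' @export
study_zone_maps <- function(n_masks, cfg = simulation_config(), seed = 1,
                            mask_args = list(), alternating = FALSE) {
  lapply(seq_len(n_masks), function(i) {
    mask <- do.call(synthetic_axon_mask,
                    c(list(pixels_per_um = cfg$pixels_per_um,
                           seed = child_seed(seed, i)), mask_args))
    bb <- backbone_from_mask(mask)
    base <- build_zone_map(mask, bb, cfg$spacing_nm, cfg$line_halfwidth_px,
                           cfg$pixels_per_um)
    alt <- if (alternating) {
      alternating_zone_map(mask, bb, cfg$spacing_nm,
                           shift_nm = cfg$spacing_nm / 2,
                           line_halfwidth_px = cfg$line_halfwidth_px,
                           pixels_per_um = cfg$pixels_per_um)
    }
    list(base = base, alt = alt)
  })
}

#' Amplitude sensitivity to the periodic localization percentage
#'
#' Simulates single-channel images at each periodic localization level on
#' a shared set of masks, runs the full analysis pipeline, and collects
#' the per-grid best-angle autocorrelation amplitudes. Every pair of
#' levels is compared with a two-sided Mann-Whitney U test; p-values are
#' reported raw (no multiplicity correction).
#'
#' @param plp_levels Numeric vector of periodic localization percentages
#'   (at least two).
#' @param n_masks Masks per level (shared across levels).
#' @param cfg A [simulation_config()].
#' @param acfg An [analysis_config()].
#' @param seed Base RNG seed.
#' @param mask_args Extra arguments for [synthetic_axon_mask()].
#' @param zone_maps Optional precomputed [study_zone_maps()] output.
#' @return List with `amplitudes` (long data frame: `plp`, `mask`,
#'   `grid_index`, `amplitude`, `frequency_nm`) and `pvalues` (symmetric
#'   matrix over levels).
#' @export
amplitude_sensitivity_experiment <- function(plp_levels, n_masks = 10,
                                             cfg = simulation_config(),
                                             acfg = analysis_config(),
                                             seed = 1, mask_args = list(),
                                             zone_maps = NULL) {
  stopifnot(length(plp_levels) >= 2L)
  if (is.null(zone_maps)) {
    zone_maps <- study_zone_maps(n_masks, cfg, seed, mask_args)
  }
  rows <- list()
  for (m in seq_along(zone_maps)) {
    for (p in plp_levels) {
      cfgp <- cfg; cfgp$plp <- p
      sim <- simulate_image(cfgp, zone_map = zone_maps[[m]]$base,
                            seed = child_seed(seed, m * 1009L + round(p)))
      res <- analyze_image(sim$image, acfg)
      if (nrow(res$per_grid) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        plp = p, mask = m, grid_index = res$per_grid$grid_index,
        amplitude = res$per_grid$amp_ch1,
        frequency_nm = res$per_grid$freq_ch1_nm
      )
    }
  }
  amps <- do.call(rbind, rows)
  k <- length(plp_levels)
  pv <- matrix(NA_real_, k, k, dimnames = list(plp_levels, plp_levels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      a <- amps$amplitude[amps$plp == plp_levels[i]]
      b <- amps$amplitude[amps$plp == plp_levels[j]]
      pv[i, j] <- pv[j, i] <- stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
  }
  diag(pv) <- 1
  list(amplitudes = amps, pvalues = pv)
}

#' Cross-correlation classification accuracy
#'
#' For every combination of per-channel periodic localization percentages
#' and generated pattern, simulates two-channel images on a shared mask
#' set, runs the two-channel pipeline, and scores the
#' overlapping/alternating calls against the generated ground truth.
#' Optionally applies the autocorrelation amplitude threshold before
#' scoring; cells with fewer grids than `acfg$min_datapoints` are flagged.
#'
#' @param plp_grid Two-column data frame (or matrix) of `plp_ch1`,
#'   `plp_ch2` combinations.
#' @param patterns Character vector of generated patterns to test.
#' @param n_masks Masks per cell (shared across cells).
#' @param cfg A [simulation_config()].
#' @param acfg An [analysis_config()]; its `ac_amplitude_threshold` (when
#'   set) is applied to the per-grid tables before scoring.
#' @param seed Base RNG seed.
#' @param mask_args Extra arguments for [synthetic_axon_mask()].
#' @param zone_maps Optional precomputed [study_zone_maps()] output (must
#'   include alternating maps).
#' @return Data frame with one row per cell: `plp_ch1`, `plp_ch2`,
#'   `pattern`, `n_grids`, `n_correct`, `accuracy` (percent, `NA` when no
#'   grid was classified) and `passed_min_datapoints`.
#' @export
cross_accuracy_experiment <- function(plp_grid,
                                      patterns = c("overlapping", "alternating"),
                                      n_masks = 10,
                                      cfg = simulation_config(),
                                      acfg = analysis_config(),
                                      seed = 1, mask_args = list(),
                                      zone_maps = NULL) {
  plp_grid <- as.data.frame(plp_grid)
  names(plp_grid)[1:2] <- c("plp_ch1", "plp_ch2")
  stopifnot(all(plp_grid$plp_ch1 >= 50 & plp_grid$plp_ch1 <= 100),
            all(plp_grid$plp_ch2 >= 50 & plp_grid$plp_ch2 <= 100))
  if (is.null(zone_maps)) {
    zone_maps <- study_zone_maps(n_masks, cfg, seed, mask_args,
                                 alternating = TRUE)
  }
  label_for <- c(overlapping = "Overlapping", alternating = "Alternating")
  cells <- list()
  for (ci in seq_len(nrow(plp_grid))) {
    for (pat in patterns) {
      n_grids <- 0L; n_correct <- 0L
      for (m in seq_along(zone_maps)) {
        sim <- simulate_pair(
          cfg, pattern = pat,
          plp_ch1 = plp_grid$plp_ch1[ci], plp_ch2 = plp_grid$plp_ch2[ci],
          zone_maps = zone_maps[[m]],
          seed = child_seed(seed, (ci * 131L + m) * 17L +
                              ifelse(pat == "overlapping", 0L, 1L))
        )
        res <- analyze_image(sim$image, acfg)
        pg <- res$per_grid
        pg <- pg[!is.na(pg$class), , drop = FALSE]
        n_grids <- n_grids + nrow(pg)
        n_correct <- n_correct + sum(pg$class == label_for[[pat]])
      }
      cells[[length(cells) + 1L]] <- data.frame(
        plp_ch1 = plp_grid$plp_ch1[ci], plp_ch2 = plp_grid$plp_ch2[ci],
        pattern = pat, n_grids = n_grids, n_correct = n_correct,
        accuracy = if (n_grids > 0L) 100 * n_correct / n_grids else NA_real_,
        passed_min_datapoints = n_grids >= acfg$min_datapoints
      )
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

# Table of the one-factor-at-a-time simulation parameters and their levels.
sweep_parameter_levels <- function() {
  list(
    point_density = c(25, 50, 100, 200, 300),
    kernel = c("RED", "ORANGE"),
    signal_variance = c("constant", "uniform-0.3-1"),
    noise_pct = c(0, 5, 10, 20, 30),
    pixels_per_um = c(50, 100)
  )
}

#' One-factor-at-a-time parameter impact sweep
#'
#' Varies one simulation parameter at a time over its study levels while
#' holding the others at their defaults, simulates at each periodic
#' localization level on a shared mask set, and collects per-grid
#' amplitudes plus per-level interquartile-range summaries.
#'
#' @param plp_levels Periodic localization percentages to simulate.
#' @param parameters Character vector naming which parameters to sweep
#'   (default: all of point density, kernel, signal variance, noise and
#'   pixel size).
#' @param n_masks Masks per level.
#' @param acfg An [analysis_config()].
#' @param seed Base RNG seed.
#' @param mask_args Extra arguments for [synthetic_axon_mask()].
#' @return List with `results` (long data frame: `parameter`, `level`,
#'   `plp`, `mask`, `grid_index`, `amplitude`) and `summary` (median and
#'   IQR per parameter level and plp).
#' @export
parameter_impact_sweep <- function(plp_levels = c(50, 100),
                                   parameters = names(sweep_parameter_levels()),
                                   n_masks = 10,
                                   acfg = analysis_config(),
                                   seed = 1, mask_args = list()) {
  levels_tab <- sweep_parameter_levels()
  parameters <- match.arg(parameters, names(levels_tab), several.ok = TRUE)
  maps_by_ppm <- new.env(parent = emptyenv())
  get_maps <- function(cfg) {
    key <- as.character(cfg$pixels_per_um)
    if (is.null(maps_by_ppm[[key]])) {
      maps_by_ppm[[key]] <- study_zone_maps(n_masks, cfg, seed, mask_args)
    }
    maps_by_ppm[[key]]
  }
  rows <- list()
  for (par in parameters) {
    for (lev in levels_tab[[par]]) {
      cfg <- simulation_config()
      cfg[[par]] <- lev
      maps <- get_maps(cfg)
      for (p in plp_levels) {
        cfgp <- cfg; cfgp$plp <- p
        for (m in seq_along(maps)) {
          sim <- simulate_image(cfgp, zone_map = maps[[m]]$base,
                                seed = child_seed(seed, m * 7919L + round(p) +
                                                    match(lev, levels_tab[[par]])))
          res <- analyze_image(sim$image, acfg)
          if (nrow(res$per_grid) == 0L) next
          rows[[length(rows) + 1L]] <- data.frame(
            parameter = par, level = as.character(lev), plp = p, mask = m,
            grid_index = res$per_grid$grid_index,
            amplitude = res$per_grid$amp_ch1
          )
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(results, list(results$parameter, results$level, results$plp),
          drop = TRUE),
    function(d) data.frame(
      parameter = d$parameter[1L], level = d$level[1L], plp = d$plp[1L],
      n = nrow(d), median = stats::median(d$amplitude),
      iqr = unname(diff(stats::quantile(d$amplitude, c(0.25, 0.75))))
    )
  ))
  rownames(agg) <- NULL
  list(results = results, summary = agg)
}
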