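# Independent brute-force oracles and shared fixtures.

# Naive double-loop normalized autocorrelation (population sigma).
bf_autocorr <- function(x) {
  n <- length(x)
  sig <- sqrt(mean(x^2))
  vapply(0:(n - 1L), function(k) sum(x[1:(n - k)] * x[(1 + k):n]),
         numeric(1)) / (n * sig^2)
}

# Naive two-sided normalized cross-correlation; positive lags advance y,
# negative lags from the role-swapped sum.
bf_crosscorr <- function(x, y) {
  n <- length(x)
  s1 <- sqrt(mean(x^2)); s2 <- sqrt(mean(y^2))
  pos <- vapply(0:(n - 1L), function(k) sum(x[1:(n - k)] * y[(1 + k):n]),
                numeric(1))
  neg <- vapply(1:(n - 1L), function(k) sum(y[1:(n - k)] * x[(1 + k):n]),
                numeric(1))
  c(rev(neg), pos) / (n * s1 * s2)
}

# Per-column masked-mean profile (the angle-0 oracle).
bf_column_profile <- function(intens, mask) {
  means <- vapply(seq_len(ncol(intens)), function(j) {
    v <- intens[mask[, j], j]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  keep <- range(which(!is.na(means)))
  means[keep[1]:keep[2]]
}

# A full-mask masked_image containing a stripe pattern perpendicular to
# `angle_deg` with the given period (px).
striped_image <- function(nr, nc, period_px, angle_deg = 0, ppm = 100,
                          phase = 0) {
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  proj <- cc * cos(th) - r * sin(th)
  img <- 1 + cos(2 * pi * (proj - phase) / period_px)
  masked_image(img, matrix(TRUE, nr, nc), ppm)
}

# Lazily built pool of study zone maps shared by the expensive acceptance
# checks (identical geometry across criteria, fresh point draws per use).
.study_cache <- new.env(parent = emptyenv())

study_maps_pool <- function(n, seed = 20260101) {
  key <- sprintf("maps_%d", seed)
  have <- .study_cache[[key]]
  if (is.null(have) || length(have) < n) {
    .study_cache[[key]] <- study_zone_maps(n, simulation_config(),
                                           seed = seed, alternating = TRUE)
  }
  .study_cache[[key]][seq_len(n)]
}

# Single-channel per-grid results at one periodic localization level over
# a set of shared masks.
run_single_level <- function(maps, plp, seed, cfg = simulation_config(),
                             acfg = analysis_config()) {
  cfgp <- cfg
  cfgp$plp <- plp
  out <- list()
  for (m in seq_along(maps)) {
    sim <- simulate_image(cfgp, zone_map = maps[[m]]$base,
                          seed = seed + 37L * m)
    res <- analyze_image(sim$image, acfg)
    if (nrow(res$per_grid)) {
      res$per_grid$mask <- m
      out[[length(out) + 1L]] <- res$per_grid
    }
  }
  do.call(rbind, out)
}

# Two-channel classification outcomes for one plp pair and pattern.
run_pair_level <- function(maps, plp1, plp2, pattern, seed,
                           cfg = simulation_config(),
                           acfg = analysis_config()) {
  out <- list()
  for (m in seq_along(maps)) {
    sim <- simulate_pair(cfg, pattern = pattern, plp_ch1 = plp1,
                         plp_ch2 = plp2, zone_maps = maps[[m]],
                         seed = seed + 53L * m)
    res <- analyze_image(sim$image, acfg)
    if (nrow(res$per_grid)) {
      res$per_grid$mask <- m
      out[[length(out) + 1L]] <- res$per_grid
    }
  }
  do.call(rbind, out)
}
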