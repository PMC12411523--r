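#' Simulation configuration
#'
#' Parameter set for the STED-like image simulator. Defaults follow the
#' simulation study's baseline: RED kernel, no added noise, 100 pixels/um,
#' 100 points/um^2, constant signal intensity, and fully periodic point
#' placement (periodic localization percentage 100). The study's
#' one-factor-at-a-time design varies kernel (RED, ORANGE), noise (0, 5,
#' 10, 20, 30 % of the kernel maximum), pixel size (50, 100 px/um), point
#' density (25, 50, 100, 200, 300 points/um^2) and signal variance
#' (constant vs. uniform in 0.3-1).
#'
#' @param kernel `"RED"` or `"ORANGE"` point-spread kernel.
#' @param noise_pct Gaussian noise standard deviation as a percentage of
#'   the kernel's maximum intensity (0 disables noise).
#' @param pixels_per_um Pixel pitch of the simulated image.
#' @param point_density Points per um^2 spawned over the mask.
#' @param signal_variance `"constant"` (every point has intensity 1) or
#'   `"uniform-0.3-1"` (intensities drawn uniformly from 0.3-1).
#' @param plp Periodic localization percentage in `[50, 100]`: 50 spawns
#'   points uniformly over the mask, 100 exclusively in the on-line zones.
#' @param spacing_nm Ring spacing along the backbone (default 200 nm).
#' @param line_halfwidth_px Dilation half-width of the on-line stripes.
#' @param kernel_fwhm_nm Optional kernel FWHM override in nm (defaults:
#'   RED 60, ORANGE 90).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(kernel = c("RED", "ORANGE"),
                              noise_pct = 0,
                              pixels_per_um = 100,
                              point_density = 100,
                              signal_variance = c("constant", "uniform-0.3-1"),
                              plp = 100,
                              spacing_nm = 200,
                              line_halfwidth_px = 2,
                              kernel_fwhm_nm = NULL) {
  kernel <- match.arg(kernel)
  signal_variance <- match.arg(signal_variance)
  stopifnot(noise_pct >= 0, pixels_per_um > 0, point_density > 0,
            plp >= 50, plp <= 100, spacing_nm > 0, line_halfwidth_px >= 0)
  structure(
    list(kernel = kernel, noise_pct = noise_pct,
         pixels_per_um = pixels_per_um, point_density = point_density,
         signal_variance = signal_variance, plp = plp,
         spacing_nm = spacing_nm,
         line_halfwidth_px = as.integer(line_halfwidth_px),
         kernel_fwhm_nm = kernel_fwhm_nm),
    class = "sim_config"
  )
}

#' Synthetic axon mask
#'
#' Generates a smoothly curving band emulating the region of interest of an
#' axon (initial segment) in a super-resolution image. The centerline is a
#' gently tilted, low-frequency random walk whose local slope stays
#' monotone in sign, so each 1 um analysis slab intersects the band in one
#' contiguous stretch; the band's perpendicular width is constant.
#' `curvature = 0` produces a straight horizontal band.
#'
#' @param length_um Band length along the image columns (>= 5).
#' @param width_um Band width perpendicular to the centerline (>= 0.3).
#' @param curvature Dimensionless slope scale of the centerline (typical
#'   values 0-0.2; the default 0.12 keeps local tilts within about 10
#'   degrees of the column axis).
#' @param pixels_per_um Pixel pitch.
#' @param seed RNG seed; identical seeds give identical masks.
#' @return A logical mask matrix.
#' @export
synthetic_axon_mask <- function(length_um = 20, width_um = 0.6,
                                curvature = 0.12, pixels_per_um = 100,
                                seed = NULL) {
  stopifnot(length_um >= 5, width_um >= 0.3)
  nc <- as.integer(round(length_um * pixels_per_um))
  with_seed(seed, {
    if (curvature == 0) {
      slope <- rep(0, nc)
    } else {
      sgn <- sample(c(-1, 1), 1L)
      k <- 6L
      knots <- seq(1, nc, length.out = k)
      gvals <- runif(k, 0.4, 1.5)
      g <- stats::spline(knots, gvals, xout = seq_len(nc))$y
      g <- pmin(pmax(g, 0.25), 1.6)
      slope <- sgn * curvature * g
    }
    y <- cumsum(slope)
    hw <- (width_um / 2) * pixels_per_um * sqrt(1 + slope^2)
    pad <- max(hw) + 4
    y0 <- y - min(y) + pad
    nr <- as.integer(ceiling(max(y0) + pad))
    rows <- matrix(seq_len(nr), nr, nc)
    ctr <- matrix(y0, nr, nc, byrow = TRUE)
    hwm <- matrix(hw, nr, nc, byrow = TRUE)
    abs(rows - ctr) <= hwm
  })
}

#' Extract the backbone of a mask
#'
#' Thins the mask to a one-pixel-wide skeleton (2-D parallel medial-axis
#' thinning) and keeps the longest geodesic path between skeleton
#' endpoints, found with two breadth-first searches over the 8-connected
#' skeleton graph.
#'
#' @param mask Logical matrix, a single connected component.
#' @return Integer matrix of ordered (row, col) backbone pixels, oriented
#'   from the smaller to the larger column end.
#' @export
backbone_from_mask <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask), any(mask))
  skel <- thin_mask_cpp(mask)
  idx <- which(skel)
  n <- length(idx)
  if (n < 2L) mps_error("mpscorr_degenerate_mask", "skeleton has < 2 pixels")
  nr <- nrow(skel)
  id <- integer(length(skel)); id[idx] <- seq_len(n)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1L]; c2 <- c + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
    nb <- integer(n); nb[ok] <- id[(c2[ok] - 1L) * nr + r2[ok]]
    has <- which(nb > 0L)
    if (length(has)) edges[[length(edges) + 1L]] <- cbind(has, nb[has])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  d1 <- igraph::distances(g, v = 1L)[1L, ]
  if (any(is.infinite(d1))) {
    mps_error("mpscorr_disconnected_mask", "mask is not a single connected component")
  }
  u <- which.max(d1)
  d2 <- igraph::distances(g, v = u)[1L, ]
  v <- which.max(d2)
  path <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1L]]
  path <- as.integer(path)
  bb <- cbind(row = r[path], col = c[path])
  # thinning retracts the skeleton from the mask ends by about half the
  # band width; extend the path to the mask margin along the end tangents
  bb <- extend_to_mask(bb, mask)
  if (bb[1L, 2L] > bb[nrow(bb), 2L]) bb <- bb[nrow(bb):1L, , drop = FALSE]
  bb
}

# March from `p` along direction (dr, dc) while staying inside the mask;
# returns the visited pixels (excluding `p`).
march_in_mask <- function(p, dr, dc, mask) {
  nrm <- max(abs(dr), abs(dc))
  if (nrm == 0) return(NULL)
  sr <- dr / nrm; sc <- dc / nrm
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list(); t <- 1
  prev <- p
  repeat {
    r <- as.integer(round(p[1] + t * sr))
    c <- as.integer(round(p[2] + t * sc))
    if (r < 1L || r > nr || c < 1L || c > nc || !mask[r, c]) break
    if (r != prev[1L] || c != prev[2L]) {
      out[[length(out) + 1L]] <- c(r, c)
      prev <- c(r, c)
    }
    t <- t + 1
  }
  if (length(out)) do.call(rbind, out) else NULL
}

extend_to_mask <- function(bb, mask) {
  n <- nrow(bb)
  span <- min(5L, n)
  head_dir <- bb[1L, ] - bb[span, ]
  tail_dir <- bb[n, ] - bb[n - span + 1L, ]
  pre <- march_in_mask(bb[1L, ], head_dir[1L], head_dir[2L], mask)
  post <- march_in_mask(bb[n, ], tail_dir[1L], tail_dir[2L], mask)
  out <- rbind(if (!is.null(pre)) pre[nrow(pre):1L, , drop = FALSE], bb, post)
  colnames(out) <- c("row", "col")
  out
}

# Running-mean smoothing of a pixel polyline. The 8-connected skeleton is
# a staircase whose cumulated Euclidean length overestimates the true arc
# length by up to ~8%; smoothing the coordinates before measuring arc
# length removes that bias so anchor spacing matches the nominal ring
# spacing.
smooth_polyline <- function(bb, window = 7L) {
  n <- nrow(bb)
  if (n <= window) return(bb * 1.0)
  w <- rep(1 / window, window)
  sm <- cbind(stats::filter(bb[, 1L], w, sides = 2),
              stats::filter(bb[, 2L], w, sides = 2))
  na <- is.na(sm[, 1L])
  sm[na, ] <- bb[na, ]
  sm
}

# Point and local tangent at a set of arc-length targets, interpolated
# linearly along the (smoothed) polyline.
polyline_at <- function(bb, s, targets, tangent_halfspan = 3L) {
  n <- nrow(bb)
  i <- findInterval(targets, s, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  frac <- (targets - s[i]) / pmax(s[i + 1L] - s[i], 1e-12)
  pos <- bb[i, , drop = FALSE] +
    (bb[i + 1L, , drop = FALSE] - bb[i, , drop = FALSE]) * frac
  lo <- pmax(1L, i - tangent_halfspan)
  hi <- pmin(n, i + tangent_halfspan)
  tan_rc <- bb[hi, , drop = FALSE] - bb[lo, , drop = FALSE]
  list(pos = pos, tangent = tan_rc)
}

#' Periodic zone map of a mask
#'
#' Places anchor points along the backbone at arc-length multiples of the
#' ring spacing, draws a Bresenham line through each anchor perpendicular
#' to the local tangent (estimated from the three bidirectional backbone
#' neighbors), dilates the lines by `line_halfwidth_px`, and clips them to
#' the mask. Dilated line pixels form the on-line zone (1); the remaining
#' mask pixels the off-line zone (2); background is 0.
#'
#' @param mask Logical mask matrix.
#' @param backbone Ordered (row, col) matrix from [backbone_from_mask()].
#' @param spacing_nm Ring spacing in nm (default 200).
#' @param line_halfwidth_px Dilation half-width in pixels.
#' @param pixels_per_um Pixel pitch.
#' @param shift_nm Arc-length offset of the first anchor (used to build
#'   alternating maps).
#' @return A `zone_map`: list with `zones` (integer matrix), `backbone`,
#'   `spacing_nm`, `anchors`, `line_halfwidth_px`, `pixels_per_um`.
#' @export
build_zone_map <- function(mask, backbone, spacing_nm = 200,
                           line_halfwidth_px = 2, pixels_per_um = 100,
                           shift_nm = 0) {
  stopifnot(is.matrix(backbone), ncol(backbone) == 2L)
  sm <- smooth_polyline(backbone)
  steps <- sqrt(diff(sm[, 1L])^2 + diff(sm[, 2L])^2)
  s <- c(0, cumsum(steps))
  send <- s[length(s)]
  spacing_px <- spacing_nm / 1000 * pixels_per_um
  shift_px <- shift_nm / 1000 * pixels_per_um
  if (send < spacing_px) mps_error("mpscorr_short_backbone",
                                   "backbone shorter than ring spacing")
  targets <- seq(shift_px %% spacing_px, send, by = spacing_px)
  if (length(targets) < 2L) mps_error("mpscorr_short_backbone",
                                      "fewer than 2 anchors")
  at <- polyline_at(sm, s, targets)
  nr <- nrow(mask); ncm <- ncol(mask)
  anchors <- matrix(as.integer(round(at$pos)), ncol = 2L)
  line_px <- list()
  for (i in seq_len(nrow(anchors))) {
    p <- anchors[i, ]
    if (p[1L] < 1L || p[1L] > nr || p[2L] < 1L || p[2L] > ncm ||
        !mask[p[1L], p[2L]]) next
    dr <- at$tangent[i, 1L]; dc <- at$tangent[i, 2L]
    nrm <- sqrt(dr^2 + dc^2)
    if (nrm == 0) next
    # perpendicular to the local tangent
    line_px[[length(line_px) + 1L]] <-
      bresenham_walk(p, -dc / nrm, dr / nrm, mask)
  }
  if (length(line_px) < 2L) mps_error("mpscorr_short_backbone",
                                      "fewer than 2 anchors")
  px <- do.call(rbind, line_px)
  on_idx <- unique((px[, 2L] - 1L) * nr + px[, 1L])
  hw <- as.integer(line_halfwidth_px)
  if (hw > 0L) {
    r0 <- (on_idx - 1L) %% nr + 1L
    c0 <- (on_idx - 1L) %/% nr + 1L
    offs <- expand.grid(dr = -hw:hw, dc = -hw:hw)
    allr <- rep(r0, nrow(offs)) + rep(offs$dr, each = length(r0))
    allc <- rep(c0, nrow(offs)) + rep(offs$dc, each = length(r0))
    ok <- allr >= 1L & allr <= nr & allc >= 1L & allc <= ncm
    on_idx <- unique((allc[ok] - 1L) * nr + allr[ok])
  }
  on_idx <- on_idx[mask[on_idx]]
  zones <- matrix(0L, nr, ncm)
  zones[mask] <- 2L
  zones[on_idx] <- 1L
  structure(list(zones = zones, backbone = backbone, spacing_nm = spacing_nm,
                 anchors = anchors, line_halfwidth_px = hw,
                 pixels_per_um = pixels_per_um),
            class = "zone_map")
}

#' Alternating zone map
#'
#' Identical construction to [build_zone_map()] with every anchor advanced
#' along the backbone by `shift_nm` (default 100 nm, half the ring
#' spacing), producing stripes offset by half a period.
#'
#' @inheritParams build_zone_map
#' @param shift_nm Arc-length shift of the anchors in nm.
#' @return A `zone_map`.
#' @export
alternating_zone_map <- function(mask, backbone, spacing_nm = 200,
                                 shift_nm = 100, line_halfwidth_px = 2,
                                 pixels_per_um = 100) {
  build_zone_map(mask, backbone, spacing_nm, line_halfwidth_px,
                 pixels_per_um, shift_nm = shift_nm)
}

#' Point counts per zone
#'
#' The total point count follows the configured density over the mask
#' area, \eqn{P_{total} = D (A_{on} + A_{off}) / PPM^2}, and is split
#' between zones by the periodic localization percentage `F`:
#' \eqn{P_{on} = P_{total} A_{on} F / (A_{on} F + A_{off} (100 - F))},
#' with the off-line count taken as the remainder so the split always
#' conserves the total. Totals and on-line counts are rounded half up.
#'
#' @param zone_map A [build_zone_map()] result.
#' @param cfg A [simulation_config()].
#' @return A `spawn_counts` list: `P_total`, `P_on`, `P_off`, `A_on`,
#'   `A_off`.
#' @export
spawn_counts <- function(zone_map, cfg) {
  A_on <- sum(zone_map$zones == 1L)
  A_off <- sum(zone_map$zones == 2L)
  ppm2 <- cfg$pixels_per_um^2
  F <- cfg$plp
  P_total <- round_half_up(cfg$point_density * (A_on + A_off) / ppm2)
  P_on <- round_half_up(P_total * A_on * F / (A_on * F + A_off * (100 - F)))
  P_on <- min(P_on, P_total)
  structure(list(P_total = P_total, P_on = P_on, P_off = P_total - P_on,
                 A_on = A_on, A_off = A_off),
            class = "spawn_counts")
}

#' Parametric point-spread kernel
#'
#' Unit-peak isotropic Gaussian kernel truncated at three standard
#' deviations. The RED kernel (default FWHM 60 nm) emulates the narrower,
#' higher-resolution fluorophore spot; ORANGE (default FWHM 90 nm) the
#' broader one.
#'
#' @param kind `"RED"` or `"ORANGE"`.
#' @param pixels_per_um Pixel pitch.
#' @param fwhm_nm Full width at half maximum in nm; per-kind default when
#'   `NULL`.
#' @return A numeric kernel matrix with peak value 1 at its center.
#' @export
make_kernel <- function(kind = c("RED", "ORANGE"), pixels_per_um = 100,
                        fwhm_nm = NULL) {
  kind <- match.arg(kind)
  if (is.null(fwhm_nm)) fwhm_nm <- if (kind == "RED") 60 else 90
  fwhm_px <- fwhm_nm / 1000 * pixels_per_um
  if (fwhm_px < 2) stop("kernel FWHM must be at least 2 px at this pixel pitch")
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  rad <- as.integer(ceiling(3 * sigma))
  ax <- -rad:rad
  d2 <- outer(ax^2, ax^2, `+`)
  exp(-d2 / (2 * sigma^2))
}

# Add `kern` centered at each of `idx` (linear indices) scaled by `vals`.
stamp_kernel <- function(nr, nc, idx, vals, kern) {
  img <- matrix(0, nr, nc)
  rad <- (nrow(kern) - 1L) %/% 2L
  r0 <- (idx - 1L) %% nr + 1L
  c0 <- (idx - 1L) %/% nr + 1L
  for (i in seq_along(idx)) {
    rr <- (r0[i] - rad):(r0[i] + rad)
    cc <- (c0[i] - rad):(c0[i] + rad)
    rok <- rr >= 1L & rr <= nr
    cok <- cc >= 1L & cc <= nc
    img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] +
      vals[i] * kern[rok, cok, drop = FALSE]
  }
  img
}

#' Render a simulated image from a zone map
#'
#' Draws `P_on` pixels without replacement from the on-line zone and
#' `P_off` from the off-line zone, assigns each point an intensity (1, or
#' uniform in 0.3-1 under the variable-signal setting), convolves the
#' point image with the configured kernel, and adds zero-mean Gaussian
#' noise with standard deviation `noise_pct`% of the kernel maximum over
#' the whole frame. Noise is not clipped at zero.
#'
#' @param zone_map A [build_zone_map()] result.
#' @param counts A [spawn_counts()] result.
#' @param cfg A [simulation_config()].
#' @param seed RNG seed.
#' @return Intensity matrix; attributes `points_on` / `points_off` carry
#'   the realized point indices.
#' @export
render <- function(zone_map, counts, cfg, seed = NULL) {
  zones <- zone_map$zones
  on_pool <- which(zones == 1L)
  off_pool <- which(zones == 2L)
  if (counts$P_on > length(on_pool) || counts$P_off > length(off_pool)) {
    mps_error("mpscorr_overfull_zone", "point count exceeds zone pixel count")
  }
  with_seed(seed, {
    on_idx <- if (counts$P_on > 0)
      on_pool[sample.int(length(on_pool), counts$P_on)] else integer()
    off_idx <- if (counts$P_off > 0)
      off_pool[sample.int(length(off_pool), counts$P_off)] else integer()
    idx <- c(on_idx, off_idx)
    vals <- if (cfg$signal_variance == "constant") rep(1, length(idx))
            else runif(length(idx), 0.3, 1)
    kern <- make_kernel(cfg$kernel, cfg$pixels_per_um, cfg$kernel_fwhm_nm)
    img <- stamp_kernel(nrow(zones), ncol(zones), idx, vals, kern)
    if (cfg$noise_pct > 0) {
      img <- img + rnorm(length(img), 0, cfg$noise_pct / 100 * max(kern))
    }
    attr(img, "points_on") <- on_idx
    attr(img, "points_off") <- off_idx
    img
  })
}

#' Simulate a single-channel image
#'
#' Convenience wrapper running mask generation (unless a mask or zone map
#' is supplied), backbone extraction, zone mapping, point spawning and
#' rendering. Fully reproducible from `seed`.
#'
#' @param cfg A [simulation_config()].
#' @param mask Optional logical mask; generated with
#'   [synthetic_axon_mask()] when `NULL`.
#' @param zone_map Optional precomputed [build_zone_map()]; skips backbone
#'   extraction (useful when simulating many periodic localization levels
#'   on one mask).
#' @param seed RNG seed.
#' @param mask_args List of extra arguments for [synthetic_axon_mask()].
#' @return List with `image` (a [masked_image()]), `zone_map`, `counts`
#'   and `truth` (configuration snapshot).
#' @export
simulate_image <- function(cfg = simulation_config(), mask = NULL,
                           zone_map = NULL, seed = NULL, mask_args = list()) {
  if (is.null(zone_map)) {
    if (is.null(mask)) {
      mask <- do.call(synthetic_axon_mask,
                      c(list(pixels_per_um = cfg$pixels_per_um,
                             seed = child_seed(seed, 1L)), mask_args))
    }
    bb <- backbone_from_mask(mask)
    zone_map <- build_zone_map(mask, bb, cfg$spacing_nm,
                               cfg$line_halfwidth_px, cfg$pixels_per_um)
  }
  mask <- zone_map$zones != 0L
  counts <- spawn_counts(zone_map, cfg)
  img <- render(zone_map, counts, cfg, seed = child_seed(seed, 2L))
  list(
    image = masked_image(img, mask, cfg$pixels_per_um),
    zone_map = zone_map, counts = counts,
    truth = list(plp = cfg$plp, spacing_nm = cfg$spacing_nm, seed = seed,
                 kernel = cfg$kernel, noise_pct = cfg$noise_pct,
                 point_density = cfg$point_density,
                 signal_variance = cfg$signal_variance,
                 line_halfwidth_px = cfg$line_halfwidth_px)
  )
}

#' Simulate a two-channel image pair
#'
#' Channel 1 is rendered from the base zone map; channel 2 either from the
#' same map (`"overlapping"`) or from a map whose anchors are advanced
#' 100 nm along the backbone (`"alternating"`), with independent point
#' draws in both cases.
#'
#' @param cfg A [simulation_config()].
#' @param pattern `"overlapping"` or `"alternating"`.
#' @param plp_ch1,plp_ch2 Periodic localization percentage per channel.
#' @param mask,zone_maps Optional mask / precomputed list
#'   `list(base =, alt =)` of zone maps.
#' @param seed RNG seed.
#' @param mask_args Extra arguments for [synthetic_axon_mask()].
#' @return List with `image` (two-channel [masked_image()]), `zone_maps`,
#'   `counts` (per channel) and `truth` (includes the generated pattern).
#' @export
simulate_pair <- function(cfg = simulation_config(),
                          pattern = c("overlapping", "alternating"),
                          plp_ch1 = cfg$plp, plp_ch2 = cfg$plp,
                          mask = NULL, zone_maps = NULL, seed = NULL,
                          mask_args = list()) {
  pattern <- match.arg(pattern)
  if (is.null(zone_maps)) {
    if (is.null(mask)) {
      mask <- do.call(synthetic_axon_mask,
                      c(list(pixels_per_um = cfg$pixels_per_um,
                             seed = child_seed(seed, 1L)), mask_args))
    }
    bb <- backbone_from_mask(mask)
    base <- build_zone_map(mask, bb, cfg$spacing_nm,
                           cfg$line_halfwidth_px, cfg$pixels_per_um)
    alt <- alternating_zone_map(mask, bb, cfg$spacing_nm,
                                shift_nm = cfg$spacing_nm / 2,
                                line_halfwidth_px = cfg$line_halfwidth_px,
                                pixels_per_um = cfg$pixels_per_um)
    zone_maps <- list(base = base, alt = alt)
  }
  mask <- zone_maps$base$zones != 0L
  cfg1 <- cfg; cfg1$plp <- plp_ch1
  cfg2 <- cfg; cfg2$plp <- plp_ch2
  map2 <- if (pattern == "overlapping") zone_maps$base else zone_maps$alt
  cnt1 <- spawn_counts(zone_maps$base, cfg1)
  cnt2 <- spawn_counts(map2, cfg2)
  ch1 <- render(zone_maps$base, cnt1, cfg1, seed = child_seed(seed, 2L))
  ch2 <- render(map2, cnt2, cfg2, seed = child_seed(seed, 3L))
  list(
    image = masked_image(list(ch1, ch2), mask, cfg$pixels_per_um),
    zone_maps = zone_maps, counts = list(cnt1, cnt2),
    truth = list(pattern = pattern, plp_ch1 = plp_ch1, plp_ch2 = plp_ch2,
                 spacing_nm = cfg$spacing_nm, seed = seed)
  )
}
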