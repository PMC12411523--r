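#' Gradient label layer for oriented profile extraction
#'
#' Assigns every pixel of a grid to one of a family of parallel lines
#' rasterized with Bresenham's algorithm, perpendicular to the profile
#' direction. Consecutive lines are shifted by one pixel along the column
#' axis and carry consecutive integer labels, so averaging intensities per
#' label reduces the grid to a 1-D profile along the chosen direction.
#'
#' Angle 0 means the profile runs along the grid's column (x) axis, so lines
#' of constant label are columns; positive angles rotate the profile
#' direction counter-clockwise (toward decreasing row index). Labels form
#' the contiguous range `0 .. n_labels - 1` and each pixel carries exactly
#' one label.
#'
#' @param shape Integer vector `(rows, cols)`.
#' @param angle_deg Profile direction in degrees, `|angle_deg| < 90`.
#' @return A `label_layer`: list with `labels` (integer matrix, 0-based),
#'   `angle_deg` and `n_labels`.
#' @export
gradient_label_layer <- function(shape, angle_deg) {
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nr < 2L || nc < 2L) stop("degenerate shape: both dimensions must be >= 2")
  if (!is_scalar_number(angle_deg) || abs(angle_deg) >= 90) {
    stop("|angle_deg| must be < 90")
  }
  off <- bresenham_offsets(nr, angle_deg)
  labels <- matrix(rep.int(0L:(nc - 1L), rep.int(nr, nc)), nr, nc)
  labels <- labels - off  # off recycles down columns (row-wise offset)
  labels <- labels - min(labels)
  n_labels <- max(labels) + 1L
  cov <- tabulate(as.vector(labels) + 1L, nbins = n_labels)
  if (any(cov == 0L)) stop("label layer has gaps; grid too narrow for this angle")
  structure(list(labels = labels, angle_deg = angle_deg, n_labels = n_labels),
            class = "label_layer")
}

#' Reduce a grid to a 1-D mean-intensity profile
#'
#' Averages the intensity of mask-true pixels per label of a gradient label
#' layer. Labels with no mask-true pixel at either end of the profile are
#' trimmed; empty labels in the interior are filled by linear interpolation
#' so the profile the correlation stage consumes is gap-free. Background
#' pixels never contribute zeros to the means.
#'
#' @param grid An `mps_grid` from [partition_grids()].
#' @param channel Channel index (1 or 2).
#' @param layer A [gradient_label_layer()] of the grid's shape.
#' @return An `intensity_profile`: list with `values`, `angle_deg`,
#'   `step_um` (physical spacing between labels) and `n_points`.
#'   Signals a `mpscorr_profile_too_short` error when fewer than two labels
#'   contain mask pixels.
#' @export
extract_profile <- function(grid, channel, layer) {
  stopifnot(inherits(grid, "mps_grid"), inherits(layer, "label_layer"))
  m <- grid_mask(grid)
  if (!identical(dim(m), dim(layer$labels))) {
    stop("layer shape must equal grid shape")
  }
  intens <- grid_channel(grid, channel)
  idx <- which(m)
  profile_from_labels(intens[idx], layer$labels[idx], layer$n_labels,
                      layer$angle_deg, 1 / grid$parent$pixels_per_um)
}

# Shared reduction core: masked per-label means, end trimming, interior
# interpolation. `labs` are 0-based labels of the mask-true pixels.
profile_from_labels <- function(vals_px, labs, nb, angle_deg, step_um) {
  counts <- tabulate(labs + 1L, nbins = nb)
  nonempty <- which(counts > 0L)
  if (length(nonempty) < 2L) {
    mps_error("mpscorr_profile_too_short",
              "fewer than 2 labels contain mask pixels")
  }
  rs <- rowsum(vals_px, labs)
  sums <- numeric(nb)
  sums[as.integer(rownames(rs)) + 1L] <- rs[, 1L]
  k0 <- nonempty[1L]; k1 <- nonempty[length(nonempty)]
  vals <- rep(NA_real_, nb)
  vals[nonempty] <- sums[nonempty] / counts[nonempty]
  vals <- vals[k0:k1]
  if (anyNA(vals)) {
    xs <- which(!is.na(vals))
    vals <- stats::approx(xs, vals[xs], xout = seq_along(vals))$y
  }
  structure(
    list(values = vals, angle_deg = angle_deg, step_um = step_um,
         n_points = length(vals), label_start = k0 - 1L),
    class = "intensity_profile"
  )
}

#' Sweep profile angles over a grid
#'
#' Extracts one intensity profile per channel for every angle
#' `lo, lo + step, ...` up to `hi`. Both channels of a two-channel image
#' share the identical label layer at each angle, which keeps their profile
#' points paired for cross-correlation.
#'
#' @param grid An `mps_grid`.
#' @param angle_range Length-2 numeric `(lo, hi)` in degrees, `lo <= hi`.
#' @param angle_step Positive step in degrees.
#' @return A list with one element per angle: `list(angle_deg, profiles)`
#'   where `profiles` is a list with one `intensity_profile` per channel, or
#'   `NULL` when the grid is unusable at that angle (profile too short).
#' @export
sweep_angles <- function(grid, angle_range = c(-20, 20), angle_step = 1) {
  stopifnot(inherits(grid, "mps_grid"))
  lo <- angle_range[1]; hi <- angle_range[2]
  if (!(lo <= hi) || angle_step <= 0) stop("invalid angle range or step")
  angles <- seq(lo, hi, by = angle_step)
  if (length(angles) == 0L) stop("empty angle sweep")
  nch <- length(grid$parent$channels)
  # hoist the per-grid work out of the angle loop: masked pixel positions
  # and intensities do not change with the angle, only the labels do
  m <- grid_mask(grid)
  idx <- which(m)
  nr <- nrow(m)
  ridx <- (idx - 1L) %% nr          # 0-based rows of mask-true pixels
  cidx <- (idx - 1L) %/% nr         # 0-based cols
  px <- lapply(seq_len(nch), function(ch) grid_channel(grid, ch)[idx])
  step_um <- 1 / grid$parent$pixels_per_um
  lapply(angles, function(a) {
    off <- bresenham_offsets(nr, a)
    labs <- cidx - off[ridx + 1L]
    labs <- labs - min(labs)
    nb <- max(labs) + 1L
    profs <- tryCatch(
      lapply(px, function(v) profile_from_labels(v, labs, nb, a, step_um)),
      mpscorr_profile_too_short = function(e) NULL
    )
    list(angle_deg = a, profiles = profs)
  })
}
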