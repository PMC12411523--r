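#' Masked super-resolution image
#'
#' Bundles one or two intensity channels with a binary region-of-interest
#' mask and the physical pixel pitch. Every downstream stage (grid
#' partitioning, profile extraction, correlation) consumes this container.
#'
#' @param channels A numeric matrix or a list of one or two numeric matrices
#'   (identical dimensions), rows indexing image rows.
#' @param mask Logical matrix of the same dimensions; `TRUE` marks signal.
#' @param pixels_per_um Positive number of pixels per micrometre.
#' @return An object of class `masked_image`.
#' @examples
#' img <- masked_image(matrix(runif(100), 10), matrix(TRUE, 10, 10), 100)
#' dim(img$mask)
#' @export
masked_image <- function(channels, mask, pixels_per_um) {
  if (is.matrix(channels)) channels <- list(channels)
  if (!is.list(channels) || length(channels) < 1L || length(channels) > 2L) {
    stop("`channels` must be one or two matrices")
  }
  channels <- lapply(channels, function(ch) {
    stopifnot(is.matrix(ch), is.numeric(ch))
    storage.mode(ch) <- "double"
    ch
  })
  d <- dim(channels[[1L]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) stop("all channels must share one shape")
  }
  if (!is.matrix(mask) || !identical(dim(mask), d)) {
    stop("mask shape must equal channel shape")
  }
  mask <- mask & !is.na(mask)
  if (!is_scalar_number(pixels_per_um) || pixels_per_um <= 0) {
    stop("pixels_per_um must be a positive number")
  }
  structure(
    list(channels = channels, mask = mask, pixels_per_um = pixels_per_um),
    class = "masked_image"
  )
}

#' @export
print.masked_image <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<masked_image> %d x %d px, %d channel(s), %.5g px/um, %d mask px\n",
    d[1], d[2], length(x$channels), x$pixels_per_um, sum(x$mask)
  ))
  invisible(x)
}

#' Build a binary mask by smoothing and thresholding
#'
#' Applies a mean filter of the given radius to one channel and marks pixels
#' whose smoothed value is greater than or equal to `threshold`. Radius 0
#' disables smoothing, making the operation a direct per-pixel comparison.
#'
#' @param image Numeric matrix (one intensity channel).
#' @param threshold Threshold on the (smoothed) intensity.
#' @param smooth_radius Non-negative integer radius of the mean filter; the
#'   filter window is `(2 * radius + 1)^2` with zero padding at the borders.
#' @return Logical matrix of the same shape.
#' @seealso [edit_mask()], [partition_grids()]
#' @export
make_mask <- function(image, threshold, smooth_radius = 0) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is_scalar_number(smooth_radius) || smooth_radius < 0) {
    stop("smooth_radius must be >= 0")
  }
  smooth_radius <- as.integer(smooth_radius)
  sm <- image
  if (smooth_radius > 0) {
    w <- 2L * smooth_radius + 1L
    kern <- matrix(1 / (w * w), w, w)
    sm <- conv2_same(image, kern)
  }
  mask <- sm >= threshold
  if (!any(mask)) {
    mps_error("mpscorr_empty_mask", "thresholding produced an empty mask")
  }
  mask
}

#' Manually edit a binary mask
#'
#' Sets the listed pixels to foreground (`add`) or background (`erase`);
#' when a pixel appears in both sets, erasing wins.
#'
#' @param mask Logical matrix.
#' @param add,erase Two-column integer matrices of (row, col) coordinates,
#'   or `NULL`.
#' @return The edited logical matrix.
#' @export
edit_mask <- function(mask, add = NULL, erase = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  check <- function(px) {
    if (is.null(px) || nrow(px) == 0L) return(NULL)
    px <- matrix(as.integer(px), ncol = 2)
    if (any(px[, 1] < 1L | px[, 1] > nrow(mask) |
            px[, 2] < 1L | px[, 2] > ncol(mask))) {
      stop("mask edit coordinate out of bounds")
    }
    px
  }
  add <- check(add); erase <- check(erase)
  if (!is.null(add)) mask[add] <- TRUE
  if (!is.null(erase)) mask[erase] <- FALSE
  mask
}

#' Partition a masked image into analysis grids
#'
#' Tiles the image from the top-left in row-major order into rectangles of
#' the requested pixel height and width. A trailing partial grid at the
#' bottom or right edge is kept when it contains mask pixels; grids whose
#' mask region is entirely background are dropped.
#'
#' @param img A [masked_image()].
#' @param grid_height_px Grid height in pixels (>= 2).
#' @param grid_width_px Grid width in pixels (>= 2), or `"image-width"` to
#'   span the full image width (the default used throughout the validation
#'   study).
#' @return A list of `mps_grid` objects, each holding the half-open pixel
#'   ranges (`row0`, `row1`, `col0`, `col1`; 0-based, end-exclusive), the
#'   parent image, and a sequential `index`.
#' @export
partition_grids <- function(img, grid_height_px, grid_width_px = "image-width") {
  stopifnot(inherits(img, "masked_image"))
  d <- dim(img$mask)
  if (identical(grid_width_px, "image-width")) grid_width_px <- d[2]
  grid_height_px <- as.integer(grid_height_px)
  grid_width_px <- as.integer(grid_width_px)
  if (grid_height_px < 2L || grid_width_px < 2L) {
    stop("grid dimensions must be at least 2 px")
  }
  row_starts <- seq.int(0L, d[1] - 1L, by = grid_height_px)
  col_starts <- seq.int(0L, d[2] - 1L, by = grid_width_px)
  grids <- list()
  idx <- 0L
  for (r0 in row_starts) {
    r1 <- min(r0 + grid_height_px, d[1])
    for (c0 in col_starts) {
      c1 <- min(c0 + grid_width_px, d[2])
      sub <- img$mask[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
      if (!any(sub)) next
      idx <- idx + 1L
      grids[[idx]] <- structure(
        list(row0 = r0, row1 = r1, col0 = c0, col1 = c1,
             index = idx, parent = img),
        class = "mps_grid"
      )
    }
  }
  grids
}

#' @export
print.mps_grid <- function(x, ...) {
  cat(sprintf("<mps_grid #%d> rows [%d,%d) cols [%d,%d)\n",
              x$index, x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}

# Submatrix views of a grid.
grid_channel <- function(grid, channel) {
  grid$parent$channels[[channel]][(grid$row0 + 1L):grid$row1,
                                  (grid$col0 + 1L):grid$col1, drop = FALSE]
}

grid_mask <- function(grid) {
  grid$parent$mask[(grid$row0 + 1L):grid$row1,
                   (grid$col0 + 1L):grid$col1, drop = FALSE]
}

#' Read a single- or multi-page TIFF as a masked image
#'
#' Each TIFF page becomes one channel (at most two). The pixel pitch is
#' taken from the caller, never from TIFF metadata (metadata dialects vary
#' between acquisition software packages).
#'
#' @param path Path to a TIFF file.
#' @param pixels_per_um Physical pixel pitch, pixels per micrometre.
#' @param mask Optional logical matrix; if `NULL`, the full frame is used
#'   and a mask should be supplied later via [make_mask()]/[edit_mask()].
#' @return A [masked_image()].
#' @export
read_image_tiff <- function(path, pixels_per_um, mask = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # grayscale stored as RGB
    as.matrix(p)
  })
  if (is.null(mask)) mask <- matrix(TRUE, nrow(chans[[1]]), ncol(chans[[1]]))
  masked_image(chans, mask, pixels_per_um)
}

#' Read or write a binary mask as 8-bit TIFF
#'
#' Masks are stored with 0 = background and 255 = foreground.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `write_mask_tiff()` returns `path` invisibly; `read_mask_tiff()`
#'   returns a logical matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m >= 0.5
}
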