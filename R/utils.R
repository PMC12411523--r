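# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic entry points funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a base seed and an index, staying
# within the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(index)) %% 2147483647L) + 1L
}

# Round half away from zero (used where spawn-count conservation requires a
# fixed rounding direction; base round() is round-half-even).
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Classed error helper so pipeline stages can be skipped selectively.
mps_error <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mpscorr_error"), call = call))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# 2-D linear convolution with zero padding, "same"-size output, via FFT.
# Small kernels on large images: pad to fast sizes for the composite FFT.
conv2_same <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- stats::nextn(nr + kr - 1L, c(2, 3, 5))
  pc <- stats::nextn(nc + kc - 1L, c(2, 3, 5))
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- img
  B <- matrix(0, pr, pc); B[seq_len(kr), seq_len(kc)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (pr * pc)
  r0 <- floor((kr - 1L) / 2L)
  c0 <- floor((kc - 1L) / 2L)
  full[r0 + seq_len(nr), c0 + seq_len(nc)]
}

# Column offsets of a Bresenham line of slope tan(angle) sampled at integer
# row steps 0..(n-1). Integer error accumulation; exact for |angle| < 90.
bresenham_offsets <- function(n, angle_deg) {
  slope <- tan(angle_deg * pi / 180)
  # midpoint rounding with a fixed tie direction (toward +inf), the same
  # convention Bresenham's integer update realises for rational slopes
  r <- seq_len(n) - 1L
  as.integer(floor(slope * r + 0.5))
}

# Rasterize a straight line from point p (row, col) along unit direction
# (dr, dc), walking both ways while `keep` (a logical matrix) is TRUE.
# Returns an integer matrix of (row, col) pixels.
bresenham_walk <- function(p, dr, dc, keep) {
  nrm <- max(abs(dr), abs(dc))
  if (nrm == 0) return(matrix(p, ncol = 2))
  sr <- dr / nrm; sc <- dc / nrm
  nr <- nrow(keep); nc <- ncol(keep)
  out <- list(matrix(as.integer(p), ncol = 2))
  for (dir in c(1, -1)) {
    t <- 1
    repeat {
      r <- as.integer(round(p[1] + dir * t * sr))
      c <- as.integer(round(p[2] + dir * t * sc))
      if (r < 1L || r > nr || c < 1L || c > nc || !keep[r, c]) break
      out[[length(out) + 1L]] <- matrix(c(r, c), ncol = 2)
      t <- t + 1
    }
  }
  do.call(rbind, out)
}
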