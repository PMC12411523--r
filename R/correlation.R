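#' Center an intensity profile
#'
#' Subtracts the profile mean from every point so that the correlation
#' profiles computed downstream are centered around zero.
#'
#' @param p An `intensity_profile` or a numeric vector.
#' @return The same type, with mean-zero `values`.
#' @export
normalize_profile <- function(p) {
  if (inherits(p, "intensity_profile")) {
    p$values <- p$values - mean(p$values)
    p
  } else {
    p - mean(p)
  }
}

# Population (divide-by-N) standard deviation of a centered profile. The
# population estimator is what makes the normalized autocorrelation exactly
# 1 at lag 0.
pop_sd <- function(x) sqrt(mean(x^2))

# Linear (zero-padded) correlation sums via FFT.
# Returns S(k) = sum_i x[i] * y[i + k] for k = 0 .. n-1 when `onesided`,
# else for k = -(n-1) .. (n-1).
fft_corr <- function(x, y, onesided = TRUE) {
  n <- length(x)
  m <- stats::nextn(2L * n - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  z <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  pos <- z[1:n]                      # lags 0 .. n-1
  if (onesided) return(pos)
  neg <- z[m:(m - n + 2L)]           # lags -1 .. -(n-1)
  c(rev(neg), pos)                   # lags -(n-1) .. (n-1)
}

new_correlogram <- function(lags, values, step_um, sigma, type) {
  structure(list(lags = as.integer(lags), values = values,
                 step_um = step_um, sigma = sigma, type = type),
            class = "correlogram")
}

#' Normalized autocorrelation of a centered profile
#'
#' Computes the raw autocorrelation
#' \deqn{A(k) = \sum_{i=1}^{N-k} n'_i \, n'_{i+k}, \quad k = 0 \ldots N-1,}
#' and normalizes it by \eqn{N \sigma^2}, with \eqn{\sigma} the population
#' standard deviation of the centered profile. No per-lag length correction
#' is applied (a biased estimator): values taper toward large lags, and the
#' value at lag 0 is exactly 1.
#'
#' @param nprime A centered `intensity_profile` (see [normalize_profile()])
#'   or a centered numeric vector.
#' @param step_um Physical lag pitch in micrometres (taken from the profile
#'   when one is supplied).
#' @return A one-sided `correlogram` (lags `0 .. N-1`). Signals
#'   `mpscorr_zero_variance` for a constant profile.
#' @export
autocorrelate <- function(nprime, step_um = NULL) {
  if (inherits(nprime, "intensity_profile")) {
    step_um <- nprime$step_um
    x <- nprime$values
  } else {
    x <- nprime
  }
  n <- length(x)
  stopifnot(n >= 2L)
  sigma <- pop_sd(x)
  if (sigma == 0) {
    mps_error("mpscorr_zero_variance", "constant profile has zero variance")
  }
  vals <- fft_corr(x, x, onesided = TRUE) / (n * sigma^2)
  new_correlogram(0:(n - 1L), vals, step_um, sigma, "auto")
}

#' Normalized two-sided cross-correlation of two centered profiles
#'
#' Positive lags follow
#' \deqn{C(k) = \sum_{i=1}^{N-k} n'_{1,i} \, n'_{2,i+k},}
#' normalized by \eqn{N \sigma_1 \sigma_2}; negative lags are defined by
#' swapping the channel roles, \eqn{C(-k) = \sum_i n'_{2,i} n'_{1,i+k}}, so
#' that maxima exist on both sides of lag zero for shift extraction. A
#' positive lag means channel 2's pattern leads channel 1's along
#' increasing label index; the downstream half-period folding makes the
#' sign immaterial to classification.
#'
#' @param n1prime,n2prime Centered profiles of equal length
#'   (`intensity_profile` or numeric).
#' @param step_um Physical lag pitch; taken from the profiles when supplied.
#' @return A two-sided `correlogram` (lags `-(N-1) .. N-1`). Signals
#'   `mpscorr_zero_variance` if either profile is constant.
#' @export
crosscorrelate <- function(n1prime, n2prime, step_um = NULL) {
  if (inherits(n1prime, "intensity_profile")) {
    step_um <- n1prime$step_um
    x <- n1prime$values
  } else {
    x <- n1prime
  }
  y <- if (inherits(n2prime, "intensity_profile")) n2prime$values else n2prime
  n <- length(x)
  if (length(y) != n) stop("profiles must have equal length")
  s1 <- pop_sd(x); s2 <- pop_sd(y)
  if (s1 == 0 || s2 == 0) {
    mps_error("mpscorr_zero_variance", "constant profile has zero variance")
  }
  vals <- fft_corr(x, y, onesided = FALSE) / (n * s1 * s2)
  new_correlogram(-(n - 1L):(n - 1L), vals, step_um, c(s1, s2), "cross")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram:%s> %d lags, step %.4g um\n",
              x$type, length(x$lags), x$step_um))
  invisible(x)
}

#' Plot a correlogram
#'
#' @param x A `correlogram`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$lags * x$step_um * 1000, x$values, type = "l",
                 xlab = "lag (nm)", ylab = "normalized correlation", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Local extrema of a correlogram
#'
#' Finds interior points where the first difference of the correlation
#' values changes sign. A plateau (run of equal values) bounded by a rise
#' and a fall reports a single extremum at the run's center, rounded down.
#' Endpoints are never extrema.
#'
#' @param c A `correlogram` (or list with `lags` and `values`).
#' @return List of two data frames, `maxima` and `minima`, each with
#'   columns `lag` and `value`, ordered by lag. Either may be empty.
#' @export
find_extrema <- function(c) {
  v <- c$values
  lags <- c$lags
  stopifnot(length(v) >= 3L)
  d <- sign(diff(v))
  nz <- which(d != 0)
  empty <- data.frame(lag = integer(), value = numeric())
  if (length(nz) < 2L) return(list(maxima = empty, minima = empty))
  i <- nz[-length(nz)]
  k <- nz[-1L]
  turn <- d[i] != d[k]
  i <- i[turn]; k <- k[turn]
  centers <- (i + 1L + k) %/% 2L  # plateau spans value indices i+1 .. k
  is_max <- d[i] > 0
  list(
    maxima = data.frame(lag = lags[centers[is_max]],
                        value = v[centers[is_max]]),
    minima = data.frame(lag = lags[centers[!is_max]],
                        value = v[centers[!is_max]])
  )
}

#' Periodicity frequency and amplitude from an autocorrelation
#'
#' The peak at lag 0 counts as the first maximum, so the frequency is the
#' lag of the first interior maximum (the profile's "second maximum"),
#' converted to nanometres. The amplitude is the correlation difference
#' between that maximum and the first interior minimum. When either is
#' missing the frequency is undefined (`NA`) and the amplitude is 0.
#'
#' @param c A one-sided autocorrelation `correlogram`.
#' @return List with `frequency_nm` and `amplitude`.
#' @export
auto_features <- function(c) {
  stopifnot(identical(c$type, "auto"))
  ex <- find_extrema(c)
  if (nrow(ex$maxima) < 1L || nrow(ex$minima) < 1L) {
    return(list(frequency_nm = NA_real_, amplitude = 0))
  }
  m2 <- ex$maxima[1L, ]
  m1 <- ex$minima[1L, ]
  list(
    frequency_nm = m2$lag * c$step_um * 1000,
    amplitude = m2$value - m1$value
  )
}

#' Cross-correlation shift
#'
#' Among all local maxima of the two-sided cross-correlation, takes the
#' nearest maximum at lag <= 0 and the nearest at lag >= 0, and returns the
#' lag of whichever has the larger correlation value. Ties break toward the
#' smaller absolute lag, then toward the non-negative lag.
#'
#' @param c A two-sided cross-correlation `correlogram`.
#' @return List with `shift_lag` (signed integer) and `shift_nm`. Signals
#'   `mpscorr_no_shift` when the correlogram has no local maxima.
#' @export
cross_shift <- function(c) {
  stopifnot(identical(c$type, "cross"))
  mx <- find_extrema(c)$maxima
  if (nrow(mx) == 0L) {
    mps_error("mpscorr_no_shift", "cross-correlogram has no local maxima")
  }
  neg <- mx[mx$lag <= 0L, ]
  pos <- mx[mx$lag >= 0L, ]
  cand <- rbind(
    if (nrow(neg)) neg[which.max(neg$lag), ],
    if (nrow(pos)) pos[which.min(pos$lag), ]
  )
  cand <- unique(cand)
  ord <- order(-cand$value, abs(cand$lag), -sign(cand$lag))
  lag <- cand$lag[ord[1L]]
  list(shift_lag = as.integer(lag), shift_nm = lag * c$step_um * 1000)
}

#' Export a correlogram as a data frame
#'
#' @param x A `correlogram`.
#' @param ... Unused.
#' @return Data frame with columns `lag_px`, `lag_nm`, `value`.
#' @export
as.data.frame.correlogram <- function(x, ...) {
  data.frame(lag_px = x$lags, lag_nm = x$lags * x$step_um * 1000,
             value = x$values)
}
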