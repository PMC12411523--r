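#' Analysis configuration
#'
#' Collects the tunable parameters of the grid analysis pipeline with the
#' defaults used throughout the validation study: grid height 1 um, grid
#' width equal to the image width, frequency filter 170-230 nm, angle sweep
#' -20 to +20 degrees in 1 degree steps, no amplitude threshold, and a
#' minimum of 10 data points per accuracy bin.
#'
#' @param angle_range_deg Length-2 numeric, sweep limits in degrees.
#' @param angle_step_deg Positive sweep step in degrees.
#' @param freq_range_nm Length-2 numeric frequency filter in nanometres, or
#'   `NULL` for an unrestricted analysis.
#' @param grid_height_um Grid height in micrometres.
#' @param grid_width Grid width in micrometres, or `"image-width"`.
#' @param ac_amplitude_threshold Minimum autocorrelation amplitude required
#'   on both channels for a grid to enter the cross-correlation results, or
#'   `NULL` to disable thresholding.
#' @param min_datapoints Minimum number of grids for an accuracy cell to be
#'   considered reliable.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(angle_range_deg = c(-20, 20),
                            angle_step_deg = 1,
                            freq_range_nm = c(170, 230),
                            grid_height_um = 1,
                            grid_width = "image-width",
                            ac_amplitude_threshold = NULL,
                            min_datapoints = 10) {
  stopifnot(length(angle_range_deg) == 2L,
            angle_range_deg[1] <= angle_range_deg[2],
            angle_step_deg > 0, grid_height_um > 0, min_datapoints >= 1)
  if (!is.null(freq_range_nm)) {
    stopifnot(length(freq_range_nm) == 2L)
    if (!(freq_range_nm[1] <= freq_range_nm[2])) {
      stop("freq_range_nm must be ordered (lo <= hi)")
    }
  }
  if (!is.null(ac_amplitude_threshold)) {
    if (!is_scalar_number(ac_amplitude_threshold) ||
        ac_amplitude_threshold < 0 || ac_amplitude_threshold > 1) {
      stop("ac_amplitude_threshold must lie in [0, 1]")
    }
  }
  if (!identical(grid_width, "image-width") && !is_scalar_number(grid_width)) {
    stop("grid_width must be a number (um) or \"image-width\"")
  }
  structure(
    list(angle_range_deg = as.numeric(angle_range_deg),
         angle_step_deg = angle_step_deg,
         freq_range_nm = if (is.null(freq_range_nm)) NULL else as.numeric(freq_range_nm),
         grid_height_um = grid_height_um,
         grid_width = grid_width,
         ac_amplitude_threshold = ac_amplitude_threshold,
         min_datapoints = as.integer(min_datapoints)),
    class = "analysis_config"
  )
}

# Rows of a per-angle feature table surviving the angle and frequency
# filters. An undefined frequency is always discarded while a frequency
# filter is active.
surviving_entries <- function(df, cfg) {
  keep <- df$angle_deg >= cfg$angle_range_deg[1] &
    df$angle_deg <= cfg$angle_range_deg[2]
  if (!is.null(cfg$freq_range_nm)) {
    keep <- keep & !is.na(df$frequency_nm) &
      df$frequency_nm >= cfg$freq_range_nm[1] &
      df$frequency_nm <= cfg$freq_range_nm[2]
  }
  df[keep & !is.na(df$amplitude), , drop = FALSE]
}

# Deterministic tie-break: highest amplitude, then angle nearest 0, then
# smaller signed angle.
best_entry <- function(df) {
  df[order(-df$amplitude, abs(df$angle_deg), df$angle_deg), , drop = FALSE][1L, ]
}

#' Best-angle autocorrelation features for one grid and channel
#'
#' Discards per-angle entries outside the configured angle and frequency
#' ranges, then retains the entry with the highest autocorrelation
#' amplitude. When no entry survives the grid receives an undefined (`NA`)
#' frequency and an amplitude of 0.
#'
#' @param records Data frame with columns `angle_deg`, `frequency_nm`,
#'   `amplitude` for a single grid and channel.
#' @param cfg An [analysis_config()].
#' @return List with `angle_deg`, `frequency_nm`, `amplitude`.
#' @export
filter_auto <- function(records, cfg) {
  s <- surviving_entries(records, cfg)
  if (nrow(s) == 0L) {
    return(list(angle_deg = NA_real_, frequency_nm = NA_real_, amplitude = 0))
  }
  b <- best_entry(s)
  list(angle_deg = b$angle_deg, frequency_nm = b$frequency_nm,
       amplitude = b$amplitude)
}

#' Select the cross-correlation angle for one grid
#'
#' Applies the angle and frequency filters per channel; an angle is
#' eligible only when both channels survive there. Among eligible angles,
#' the one maximizing the mean autocorrelation amplitude of the two
#' channels is selected and its cross-correlation shift returned.
#'
#' @param records Data frame with columns `angle_deg`, `channel`,
#'   `frequency_nm`, `amplitude`, `shift_nm` (the shift may be `NA` on
#'   rows of channel 2; it is read from the selected angle's rows).
#' @param cfg An [analysis_config()].
#' @return List with `angle_deg`, `shift_nm`, `amp1`, `amp2`, `freq1_nm`,
#'   `freq2_nm`, or `NULL` when no angle is eligible (grid excluded from
#'   the cross-correlation analysis).
#' @export
select_cross_angle <- function(records, cfg) {
  ch1 <- surviving_entries(records[records$channel == 1L, , drop = FALSE], cfg)
  ch2 <- surviving_entries(records[records$channel == 2L, , drop = FALSE], cfg)
  common <- intersect(ch1$angle_deg, ch2$angle_deg)
  common <- common[!is.na(common)]
  if (length(common) == 0L) return(NULL)
  i1 <- match(common, ch1$angle_deg)
  i2 <- match(common, ch2$angle_deg)
  joint <- data.frame(
    angle_deg = common,
    amplitude = (ch1$amplitude[i1] + ch2$amplitude[i2]) / 2
  )
  a <- best_entry(joint)$angle_deg
  j1 <- ch1[ch1$angle_deg == a, ][1L, ]
  j2 <- ch2[ch2$angle_deg == a, ][1L, ]
  shift <- records$shift_nm[records$angle_deg == a & !is.na(records$shift_nm)]
  if (length(shift) == 0L) return(NULL)
  list(angle_deg = a, shift_nm = shift[1L],
       amp1 = j1$amplitude, amp2 = j2$amplitude,
       freq1_nm = j1$frequency_nm, freq2_nm = j2$frequency_nm)
}

#' Amplitude-threshold a per-grid result table
#'
#' A grid survives when the smaller of its two channel amplitudes at the
#' selected cross-correlation angle reaches the threshold.
#'
#' @param grid_records Data frame with columns `cross_amp_ch1`,
#'   `cross_amp_ch2` (as produced by [analyze_image()]).
#' @param thr Threshold in `[0, 1]`.
#' @return The filtered data frame.
#' @export
apply_amplitude_threshold <- function(grid_records, thr) {
  stopifnot(is_scalar_number(thr), thr >= 0, thr <= 1)
  keep <- !is.na(grid_records$cross_amp_ch1) &
    !is.na(grid_records$cross_amp_ch2) &
    pmin(grid_records$cross_amp_ch1, grid_records$cross_amp_ch2) >= thr
  grid_records[keep, , drop = FALSE]
}

#' Fold a cross-correlation shift onto a half period
#'
#' Computes the half-period midpoint \eqn{L = (F_1 + F_2) / 4} and the
#' normalized shift \eqn{S' = L - |(S \bmod 2L) - L|} with a floored
#' modulo, so the result lies in `[0, L]` regardless of the sign of `S`.
#'
#' @param S_nm Cross-correlation shift in nanometres (signed).
#' @param F1_nm,F2_nm Autocorrelation frequencies of the two channels (nm).
#' @return List with `L_nm` and `Sprime_nm`.
#' @export
normalize_shift <- function(S_nm, F1_nm, F2_nm) {
  stopifnot(F1_nm > 0, F2_nm > 0)
  L <- (F1_nm + F2_nm) / 4
  m <- S_nm %% (2 * L)  # floored modulo: result in [0, 2L)
  list(L_nm = L, Sprime_nm = L - abs(m - L))
}

#' Classify a normalized shift as overlapping or alternating
#'
#' Strictly below the quarter-period boundary (`S' < L/2`) the two periodic
#' patterns are called overlapping; at or above it, alternating.
#'
#' @param Sprime_nm Normalized shift in `[0, L]`.
#' @param L_nm Half-period midpoint.
#' @return `"Overlapping"` or `"Alternating"`.
#' @export
classify_shift <- function(Sprime_nm, L_nm) {
  stopifnot(Sprime_nm >= 0, Sprime_nm <= L_nm + 1e-9)
  if (Sprime_nm < L_nm / 2) "Overlapping" else "Alternating"
}
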