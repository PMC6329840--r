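# Type-7 percentile (linear interpolation between order statistics) via a
# partial sort; matches stats::quantile(type = 7) and is the percentile rule
# used for all thresholds and reference quartiles in this package.
.percentile7 <- function(x, p) {
  n <- length(x)
  if (n == 0L) stop("empty sample in percentile computation")
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  s <- sort(x, partial = unique(c(lo, hi)))
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Calendar-day 90th-percentile threshold climatology
#'
#' For every calendar day d (365-day no-leap calendar), the threshold is the
#' chosen percentile of all reference-period values falling in a window of
#' `window` days centred on d, pooled across reference years. Windows wrap
#' across the year boundary (day 365 is adjacent to day 1).
#'
#' @param tmax Either a matrix `365 x years` (one cell) or an array
#'   `c(365, years, ncell)` from [generate_climate()].
#' @param percentile Threshold percentile (default 90, the heatwave
#'   definition's local threshold).
#' @param window Window width in days (odd; default 31).
#' @return Numeric vector of length 365 (one cell) or matrix `365 x ncell`.
#' @export
compute_thresholds <- function(tmax, percentile = 90, window = 31) {
  stopifnot(window %% 2 == 1, percentile > 0, percentile < 100)
  if (is.matrix(tmax)) tmax <- array(tmax, dim = c(dim(tmax), 1L))
  stopifnot(length(dim(tmax)) == 3, dim(tmax)[1] == 365)
  ny <- dim(tmax)[2]
  if (ny < 10) stop("reference period must contain at least 10 years")
  ncell <- dim(tmax)[3]
  hw <- (window - 1L) / 2L
  p <- percentile / 100
  win_idx <- lapply(seq_len(365), function(d)
    (((d - hw):(d + hw)) - 1L) %% 365L + 1L)
  out <- matrix(NA_real_, 365, ncell)
  for (c in seq_len(ncell)) {
    mat <- tmax[, , c]
    for (d in seq_len(365))
      out[d, c] <- .percentile7(mat[win_idx[[d]], ], p)
  }
  if (ncell == 1L) drop(out) else out
}

#' Reference quartiles of annual maximum temperature
#'
#' The 25th and 75th percentiles of the reference-period annual-maximum Tmax
#' series; their difference (the interquartile range) is the temperature
#' scale that standardizes daily heatwave magnitudes, which is what makes
#' the magnitude index comparable across climates of different variability.
#'
#' @param tmax Array `c(365, years, ncell)` or matrix `365 x years`.
#' @return List with vectors `t25` and `t75` (length ncell).
#' @export
reference_quartiles <- function(tmax) {
  if (is.matrix(tmax)) tmax <- array(tmax, dim = c(dim(tmax), 1L))
  amax <- apply(tmax, c(2, 3), max)
  list(t25 = apply(amax, 2, .percentile7, p = 0.25),
       t75 = apply(amax, 2, .percentile7, p = 0.75))
}

#' Detect heatwave events in one year of daily Tmax
#'
#' A heatwave is a maximal run of at least `min_duration` consecutive days
#' with Tmax strictly above the calendar-day threshold. Events are
#' non-overlapping and ordered by start day.
#'
#' @param series Numeric vector of length 365 (one year of daily Tmax).
#' @param thresholds Numeric vector of length 365 (calendar-day thresholds).
#' @param min_duration Minimum event length in days (default 3).
#' @return Data frame with columns `start`, `end`, `duration`; zero rows if
#'   no event.
#' @export
detect_heatwaves <- function(series, thresholds, min_duration = 3) {
  if (length(series) != 365 || length(thresholds) != 365)
    stop("series and thresholds must both have length 365")
  r <- rle(series > thresholds)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  data.frame(start = starts[keep], end = ends[keep],
             duration = r$lengths[keep])
}

#' Annual Heat Wave Magnitude Index daily (HWMId)
#'
#' Each heatwave day contributes a magnitude
#' `Md = max(0, (Td - T25p)) / (T75p - T25p)`, the daily anomaly above the
#' 25th percentile of reference annual maxima scaled by their interquartile
#' range; an event's magnitude is the sum of its daily magnitudes and the
#' annual index is the largest event magnitude (0 if no heatwave). Duration
#' and intensity therefore enter a single dimensionless number. If
#' `t75 == t25` (degenerate reference, e.g. constant input) the index is
#' defined as 0 and the condition is flagged via attribute `degenerate`.
#'
#' @param series One year (365 values) of daily Tmax.
#' @param thresholds Calendar-day thresholds from [compute_thresholds()].
#' @param t25,t75 Reference quartiles from [reference_quartiles()].
#' @param min_duration Minimum heatwave length (default 3 days).
#' @return Scalar HWMId (>= 0).
#' @export
hwmid_annual <- function(series, thresholds, t25, t75, min_duration = 3) {
  ev <- detect_heatwaves(series, thresholds, min_duration)
  if (nrow(ev) == 0L) return(0)
  if (t75 <= t25) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mag <- vapply(seq_len(nrow(ev)), function(k) {
    d <- ev$start[k]:ev$end[k]
    sum(pmax(0, series[d] - t25)) / (t75 - t25)
  }, numeric(1))
  max(mag)
}

#' Annual TX5x index
#'
#' The annual maximum of the 5-day running mean of daily maximum
#' temperature; a purely temperature-based validation index for the
#' magnitude-based HWMId.
#'
#' @param series Daily Tmax, length >= 5.
#' @param window Averaging window in days (default 5).
#' @return Scalar TX5x (degC).
#' @export
tx5x_annual <- function(series, window = 5) {
  if (length(series) < window)
    stop("series shorter than the averaging window")
  cs <- cumsum(series)
  n <- length(series)
  means <- (cs[window:n] - c(0, cs[seq_len(n - window)])) / window
  max(means)
}

#' Annual index series for a gridded ensemble
#'
#' Applies [hwmid_annual()] (or [tx5x_annual()]) to every year and cell of a
#' climate array, against a fixed threshold climatology and reference
#' quartiles (computed from the present-climate state, the hazard baseline).
#'
#' @param tmax Array `c(365, years, ncell)`.
#' @param thresholds Matrix `365 x ncell` from [compute_thresholds()].
#' @param quartiles List from [reference_quartiles()].
#' @param index `"hwmid"` or `"tx5x"`.
#' @param min_duration Minimum heatwave length (HWMId only).
#' @return Matrix `years x ncell` of annual index values.
#' @export
annual_index_series <- function(tmax, thresholds, quartiles = NULL,
                                index = c("hwmid", "tx5x"),
                                min_duration = 3) {
  index <- match.arg(index)
  stopifnot(length(dim(tmax)) == 3, dim(tmax)[1] == 365)
  ny <- dim(tmax)[2]
  ncell <- dim(tmax)[3]
  out <- matrix(NA_real_, ny, ncell)
  for (c in seq_len(ncell)) {
    for (y in seq_len(ny)) {
      out[y, c] <- if (index == "hwmid") {
        hwmid_annual(tmax[, y, c], thresholds[, c],
                     quartiles$t25[c], quartiles$t75[c], min_duration)
      } else {
        tx5x_annual(tmax[, y, c])
      }
    }
  }
  out
}
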