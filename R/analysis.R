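#' Add multiplicative assay noise to a measured series
#'
#' Emulates intra-assay measurement error: each value is multiplied by
#' `1 + cv * z` with `z` standard normal (typical coefficients of variation:
#' 1\% for glycemia, 5.8\% for insulinemia).  Results are floored at 0, since
#' concentrations cannot be negative.
#'
#' @param series Numeric vector.
#' @param cv Coefficient of variation (fraction, >= 0).
#' @param seed Optional integer seed.
#' @return Noisy series of the same length.
#' @export
add_assay_noise <- function(series, cv, seed = NULL) {
  stopifnot(cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (cv == 0) return(series)
  pmax(series * (1 + cv * stats::rnorm(length(series))), 0)
}

#' Three-point moving-average low-pass filter
#'
#' Centred 3-point mean; the two endpoints are copied unchanged.
#'
#' @param series Numeric vector, length >= 3.
#' @return Filtered series of the same length.
#' @export
moving_average_3 <- function(series) {
  stopifnot(length(series) >= 3)
  out <- as.numeric(stats::filter(series, rep(1 / 3, 3), sides = 2))
  out[1] <- series[1]
  out[length(series)] <- series[length(series)]
  out
}

#' Detect pulses in a uniformly sampled hormone series
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` times the standard deviation of the series.
#' Prominence of a peak is its height above the higher of the two lowest
#' points separating it from higher terrain (or the series boundary) on
#' either side.
#'
#' When fast pulses ride on a slower large-amplitude wave (e.g. minute-scale
#' insulin pulses on top of ultradian oscillations), detection should be run
#' on the detrended series: set `detrend_window` to subtract a moving mean of
#' that width first, so prominence and the SD threshold refer to the fast
#' component only.
#'
#' @param series Numeric vector, uniformly sampled.
#' @param dt Sampling interval, min.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   series SD (default 0.5).
#' @param detrend_window Optional moving-mean window (min) subtracted before
#'   detection; `NULL` (default) detects on the raw series.
#' @param min_prominence_abs Optional absolute prominence floor, in the units
#'   of `series` (default 0: inactive).  Peaks must clear both thresholds.
#' @return A tibble of class `"pulse_set"` with columns `time` (min),
#'   `height` (on the scale detection ran on), and `interval` (min; time
#'   since the previous pulse, `NA` for the first).
#' @export
detect_pulses <- function(series, dt, min_prominence_frac = 0.5,
                          detrend_window = NULL, min_prominence_abs = 0) {
  stopifnot(dt > 0, min_prominence_frac >= 0, min_prominence_abs >= 0)
  if (!is.null(detrend_window)) {
    w <- max(1L, as.integer(round(detrend_window / dt)))
    if (w %% 2 == 0) w <- w + 1L
    trend <- as.numeric(stats::filter(series, rep(1 / w, w), sides = 2))
    trend[is.na(trend)] <- mean(series)
    series <- series - trend
  }
  n <- length(series)
  s <- stats::sd(series)
  empty <- tibble::tibble(time = numeric(0), height = numeric(0),
                          interval = numeric(0))
  class(empty) <- c("pulse_set", class(empty))
  if (n < 3 || !is.finite(s) || s == 0) return(empty)

  is_max <- which(diff(sign(diff(series))) < 0) + 1
  # plateau maxima: strictly greater than some earlier point and >= neighbours
  if (length(is_max) == 0) return(empty)

  prominence <- vapply(is_max, function(i) {
    h <- series[i]
    left_min <- h
    j <- i - 1
    while (j >= 1 && series[j] <= h) {
      left_min <- min(left_min, series[j]); j <- j - 1
    }
    if (j < 1) left_min <- min(series[1:i])
    right_min <- h
    j <- i + 1
    while (j <= n && series[j] <= h) {
      right_min <- min(right_min, series[j]); j <- j + 1
    }
    if (j > n) right_min <- min(series[i:n])
    h - max(left_min, right_min)
  }, numeric(1))

  keep <- is_max[prominence >= min_prominence_frac * s &
                   prominence >= min_prominence_abs]
  out <- tibble::tibble(time = (keep - 1) * dt, height = series[keep])
  out$interval <- c(NA_real_, diff(out$time))
  class(out) <- c("pulse_set", class(out))
  out
}

#' Estimate the dominant oscillation period of a series
#'
#' Detrends the series by subtracting a `detrend_window`-minute moving mean,
#' then locates the first prominent local maximum of the autocorrelation
#' function beyond lag zero.  The white-noise significance band is
#' Bonferroni-corrected over the searched lags; if no autocorrelation peak
#' exceeds it, the series is flagged as having no significant period and
#' `NA` is returned.
#'
#' The estimate is invariant to affine transforms of the series.  For runs
#' that start with a large onset transient (e.g. the first infusion of a
#' forcing protocol), set `settle` to drop the initial minutes before
#' estimation — the transient otherwise dominates the autocorrelation.
#'
#' @param series Numeric vector, uniformly sampled; should span at least
#'   three putative periods.
#' @param dt Sampling interval, min.
#' @param detrend_window Moving-mean window for detrending, min (default 60).
#' @param max_period Largest period searched, min (default one third of the
#'   series span).
#' @param settle Initial stretch discarded before estimation, min (default 0).
#' @return The dominant period in min, or `NA_real_` if none is significant.
#' @export
estimate_period <- function(series, dt, detrend_window = 60,
                            max_period = NULL, settle = 0) {
  stopifnot(dt > 0, length(series) > 3, settle >= 0)
  if (settle > 0) {
    series <- series[-seq_len(min(length(series) - 4, round(settle / dt)))]
  }
  n <- length(series)
  span <- n * dt
  if (is.null(max_period)) max_period <- span / 3
  w <- max(1L, as.integer(round(detrend_window / dt)))
  if (w %% 2 == 0) w <- w + 1L
  trend <- as.numeric(stats::filter(series, rep(1 / w, w), sides = 2))
  # extend the trend into the window-truncated ends
  trend[is.na(trend)] <- mean(series)
  x <- series - trend

  max_lag <- min(n - 2L, as.integer(round(max_period / dt)))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE, type = "correlation")$acf[, 1, 1]
  # local maxima of the ACF at positive lags
  lag_idx <- which(diff(sign(diff(ac))) < 0) + 1
  lag_idx <- lag_idx[lag_idx > 1]
  if (length(lag_idx) == 0) return(NA_real_)
  sig <- stats::qnorm(1 - 0.025 / max_lag) / sqrt(n)
  lag_idx <- lag_idx[ac[lag_idx] > sig]
  if (length(lag_idx) == 0) return(NA_real_)
  # first prominent peak = dominant period
  (lag_idx[1] - 1) * dt
}

#' 1:1 entrainment ratio of a pulse train to a forcing period
#'
#' Partitions the observation span into consecutive forcing periods
#' `[k T, (k+1) T)` and returns the fraction of periods containing exactly
#' one detected pulse: 1 means perfect 1:1 entrainment.
#'
#' @param pulses A `"pulse_set"` from [detect_pulses()].
#' @param T_forcing Forcing period, min (> 0).
#' @param span Observation span, min; defaults to the last pulse time
#'   rounded up to a whole period.
#' @return A fraction in \[0, 1\].
#' @export
entrainment_ratio <- function(pulses, T_forcing, span = NULL) {
  stopifnot(T_forcing > 0)
  if (nrow(pulses) == 0) return(0)
  if (is.null(span)) span <- ceiling(max(pulses$time) / T_forcing) * T_forcing
  n_periods <- max(1, floor(span / T_forcing))
  counts <- tabulate(pmin(floor(pulses$time / T_forcing) + 1, n_periods),
                     nbins = n_periods)
  mean(counts == 1)
}

#' Fast insulin-pulse metrics of an in vivo insulinemia series
#'
#' Standard pipeline for minute-scale insulin pulsatility, applied uniformly
#' to all in vivo runs:
#' 1. the per-minute insulinemia series is low-pass filtered with the
#'    three-point moving average used for all measured in vivo signals;
#' 2. the ultradian component is removed by subtracting a 10-min moving mean;
#' 3. pulses are called where the detrended prominence exceeds what the
#'    insulin assay could resolve on the filtered signal: the intra-assay CV
#'    (5.8\%) is reduced by \eqn{\sqrt 3} by the moving average, so the floor
#'    is `assay_cv / sqrt(3)` times the mean insulin level.  A secretory
#'    burst smaller than measurement uncertainty is not an appreciable pulse.
#'
#' The mean inter-pulse interval is computed after discarding gaps longer
#' than 1.5 times the median interval (occasional missed detections otherwise
#' bias the mean upward).
#'
#' @param insulin Insulinemia sampled every `dt` minutes, pM.
#' @param dt Sampling interval, min (default 1).
#' @param T_forcing Optional forcing period (min) for the entrainment ratio.
#' @param assay_cv Assay coefficient of variation defining the pulse floor.
#' @param detrend_window Moving-mean window for detrending, min.
#' @return A one-row tibble: `n_pulses`, `mean_interval` (min, gap-robust),
#'   `entrainment_ratio` (`NA` unless `T_forcing` given).
#' @export
insulin_pulse_metrics <- function(insulin, dt = 1, T_forcing = NULL,
                                  assay_cv = 0.058, detrend_window = 10) {
  filtered <- moving_average_3(insulin)
  pulses <- detect_pulses(filtered, dt = dt, min_prominence_frac = 0,
                          detrend_window = detrend_window,
                          min_prominence_abs = assay_cv / sqrt(3) * mean(filtered))
  span <- length(insulin) * dt
  iv <- pulses$interval[!is.na(pulses$interval)]
  if (length(iv) > 1) iv <- iv[iv <= 1.5 * stats::median(iv)]
  tibble::tibble(
    n_pulses = nrow(pulses),
    mean_interval = if (length(iv) > 0) mean(iv) else NA_real_,
    entrainment_ratio = if (is.null(T_forcing)) NA_real_
                        else entrainment_ratio(pulses, T_forcing, span = span))
}

#' First/second-phase metrics of a step-stimulated secretion profile
#'
#' Quantifies the biphasic pattern of insulin secretion after a step increase
#' in glucose: the first-phase peak (maximum ISR within `peak_window` minutes
#' of the step onset), the nadir following the peak (minimum within
#' `nadir_window` minutes after the peak), and the second-phase slope (linear
#' trend of ISR over the `slope_window` minutes following the nadir).
#'
#' @param series ISR series, uniformly sampled.
#' @param dt Sampling interval, min.
#' @param onset Step onset time, min.
#' @param peak_window,nadir_window,slope_window Analysis windows, min.
#' @return A one-row tibble with `peak_time`, `peak`, `nadir_time`, `nadir`,
#'   `second_phase_slope`, and `degenerate` (`TRUE` when the series is flat
#'   and the metrics are meaningless).
#' @export
phase_metrics <- function(series, dt, onset = 0, peak_window = 5,
                          nadir_window = 15, slope_window = 30) {
  stopifnot(dt > 0)
  t <- (seq_along(series) - 1) * dt
  if (stats::sd(series) == 0) {
    return(tibble::tibble(peak_time = NA_real_, peak = NA_real_,
                          nadir_time = NA_real_, nadir = NA_real_,
                          second_phase_slope = NA_real_, degenerate = TRUE))
  }
  in_peak <- t >= onset & t <= onset + peak_window
  if (!any(in_peak)) stop("no samples within the peak window", call. = FALSE)
  i_peak <- which(in_peak)[which.max(series[in_peak])]
  peak_time <- t[i_peak]

  in_nadir <- t > peak_time & t <= peak_time + nadir_window
  i_nadir <- if (any(in_nadir)) which(in_nadir)[which.min(series[in_nadir])] else NA
  nadir_time <- if (is.na(i_nadir)) NA_real_ else t[i_nadir]

  slope <- NA_real_
  if (!is.na(i_nadir)) {
    in_slope <- t >= nadir_time & t <= nadir_time + slope_window
    if (sum(in_slope) >= 3) {
      slope <- unname(stats::coef(stats::lm(series[in_slope] ~ t[in_slope]))[2])
    }
  }
  tibble::tibble(peak_time = peak_time, peak = series[i_peak],
                 nadir_time = nadir_time,
                 nadir = if (is.na(i_nadir)) NA_real_ else series[i_nadir],
                 second_phase_slope = slope, degenerate = FALSE)
}
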