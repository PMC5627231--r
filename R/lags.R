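#' Time at which a series attains its global maximum
#'
#' Ties are broken to the earliest time point.
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric vector, same length as `times`.
#' @return The time of the global maximum.
#' @export
#' @examples
#' peak_time(0:10, -(0:10 - 4)^2)  # 4
peak_time <- function(times, values) {
  if (length(times) == 0 || length(times) != length(values))
    stop("peak_time: times and values must be non-empty and equal length")
  if (any(diff(times) <= 0)) stop("peak_time: times must be strictly increasing")
  times[which.max(values)]
}

#' Peak-time lags of the regulation cascade
#'
#' For each pathway, locates the times at which the internal resource pool,
#' the transcript pool, and the enzyme pool reach their global maxima, and
#' reports the pairwise lags: resource-to-transcript (`lag_RT`),
#' transcript-to-enzyme (`lag_TE`), and resource-to-enzyme
#' (`lag_RE = lag_RT + lag_TE`). Peak times are rounded to `resolution`
#' before differencing, so the additivity of the lags is exact at the
#' reported precision.
#'
#' A regulatory series whose maximum falls on the final grid point has not
#' yet peaked within the simulated horizon; this raises an error naming the
#' series rather than reporting a truncated lag.
#'
#' @param traj an `rscm_trajectory` covering the full dynamic episode.
#' @param resolution rounding step for reported peak times, days
#'   (default 0.1 d, the precision at which cascade lags are customarily
#'   quoted). Use a smaller value for raw grid-level peaks.
#' @return A data frame with one row per pathway and columns `pathway`,
#'   `t_peak_rho`, `t_peak_tau`, `t_peak_e`, `lag_RT`, `lag_TE`, `lag_RE`
#'   (all in days).
#' @export
lag_table <- function(traj, resolution = 0.1) {
  series <- c("rho1", "tau1", "e1", "rho2", "tau2", "e2")
  n <- nrow(traj)
  peaks <- vapply(series, function(nm) {
    v <- traj[[nm]]
    if (which.max(v) == n)
      stop("lag_table: series '", nm, "' is still rising at the horizon; ",
           "its peak is inconclusive")
    peak_time(traj$time, v)
  }, numeric(1))
  pk <- round(peaks / resolution) * resolution
  out <- data.frame(
    pathway = c(1L, 2L),
    t_peak_rho = c(pk[["rho1"]], pk[["rho2"]]),
    t_peak_tau = c(pk[["tau1"]], pk[["tau2"]]),
    t_peak_e = c(pk[["e1"]], pk[["e2"]])
  )
  out$lag_RT <- out$t_peak_tau - out$t_peak_rho
  out$lag_TE <- out$t_peak_e - out$t_peak_tau
  out$lag_RE <- out$t_peak_e - out$t_peak_rho
  out
}

#' Time at which a series is depleted below a threshold fraction
#'
#' Finds the earliest time after the series' global maximum at which the
#' value falls below `fraction` times a reference level, interpolating
#' linearly between grid points. The reference is the initial value for
#' species present at time zero (e.g. NO3-) and the maximum value for
#' transient species that start at zero (e.g. NO2-).
#'
#' @param times strictly increasing numeric vector, days.
#' @param values non-negative numeric series attaining a positive maximum.
#' @param fraction threshold fraction of the reference level, in `(0, 1)`;
#'   default 0.01 (1% is below typical measurement noise and the resulting
#'   time is insensitive over 0.5-2%).
#' @return Crossing time in days, or `NA_real_` if the threshold is never
#'   crossed within the series.
#' @export
#' @examples
#' t <- seq(0, 10, 0.01)
#' depletion_time(t, exp(-t), 0.01)  # ~ log(100) = 4.605
depletion_time <- function(times, values, fraction = 0.01) {
  if (length(times) == 0 || length(times) != length(values))
    stop("depletion_time: times and values must be non-empty and equal length")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("depletion_time: fraction must be in (0, 1)")
  vmax <- max(values)
  if (vmax <= 0) stop("depletion_time: series never attains a positive maximum")
  ref <- if (values[1] > 0) values[1] else vmax
  thr <- fraction * ref
  i0 <- which.max(values)
  idx <- which(values < thr)
  idx <- idx[idx > i0]
  if (length(idx) == 0) return(NA_real_)
  j <- idx[1]
  # linear interpolation over the bracketing interval
  t0 <- times[j - 1]; t1 <- times[j]
  v0 <- values[j - 1]; v1 <- values[j]
  t0 + (v0 - thr) / (v0 - v1) * (t1 - t0)
}

#' Correlation of two series after removing a known time lag
#'
#' Shifts the lagging series earlier by `lag` days (rounded to the common
#' grid), truncates both to the overlapping window, and returns the Pearson
#' correlation coefficient. This is the numerical form of a phase diagram
#' whose time axes have been aligned on the peak-time lag.
#'
#' @param times common uniform time grid, days.
#' @param series_a leading series (e.g. transcript abundance).
#' @param series_b lagging series (e.g. enzyme concentration).
#' @param lag time shift in days by which `series_b` trails `series_a`;
#'   `|lag|` must be smaller than the grid span.
#' @return Pearson correlation coefficient of the aligned pair.
#' @export
align_and_correlate <- function(times, series_a, series_b, lag) {
  n <- length(times)
  if (n == 0 || length(series_a) != n || length(series_b) != n)
    stop("align_and_correlate: series must share the time grid")
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-8 * dt[1]))
    stop("align_and_correlate: time grid must be uniform")
  k <- as.integer(round(lag / dt[1]))
  if (abs(k) >= n) stop("align_and_correlate: lag exceeds the grid span")
  if (k >= 0) {
    a <- series_a[seq_len(n - k)]
    b <- series_b[seq_len(n - k) + k]
  } else {
    a <- series_a[seq_len(n + k) - k]
    b <- series_b[seq_len(n + k)]
  }
  if (length(a) < 10)
    stop("align_and_correlate: aligned overlap shorter than 10 grid points")
  stats::cor(a, b)
}

#' Cascade lag report as a long table
#'
#' Flattens [lag_table()] into one row per (pathway, quantity) for writing
#' as delimited text.
#'
#' @inheritParams lag_table
#' @return Data frame with columns `quantity`, `pathway`, `value_days`.
#' @export
lag_report <- function(traj, resolution = 0.1) {
  lt <- lag_table(traj, resolution)
  qty <- c("t_peak_rho", "t_peak_tau", "t_peak_e", "lag_RT", "lag_TE", "lag_RE")
  data.frame(
    quantity = rep(qty, times = 2),
    pathway = rep(lt$pathway, each = length(qty)),
    value_days = as.vector(t(as.matrix(lt[, qty])))
  )
}
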