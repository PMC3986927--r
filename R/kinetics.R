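#' Baseline-transform a kinetic series
#'
#' Subtracts the first time point's signal from the whole curve and floors
#' the result at zero, so every curve starts at 0 in the instrument's
#' arbitrary units and early-read artefacts below the starting level are
#' clipped rather than propagated as negative metabolic output.
#'
#' @param series A [pm_series].
#' @return A [pm_series] with transformed signals; times unchanged.
#' @export
baseline_transform <- function(series) {
  stopifnot(inherits(series, "pm_series"))
  series$signals <- pmax(series$signals - series$signals[1L], 0)
  series
}

# centred moving average with truncated edge windows: position i averages the
# points of the centred span of width w that fall inside the curve
moving_average <- function(x, w) {
  if (w == 1L) return(x)
  n <- length(x)
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a kinetic curve to monotone non-decreasing form
#'
#' Applies a centred moving average, sequentially increasing the window over
#' odd widths 1, 3, 5, ... until no negative slope remains, capped at
#' `w_max` (default 25 points, i.e. about 6 h on a 15-min grid). Edge
#' windows truncate to the points available. If the cap is reached and
#' negative slopes persist, their count is recorded and a final
#' running-maximum pass enforces monotonicity so downstream endpoint reads
#' are always taken from a non-decreasing curve.
#'
#' @param series A baseline-transformed [pm_series].
#' @param w_max Maximum window width; odd integer >= 1.
#' @return A `pm_smooth` object (also a `pm_series`) with fields `window`
#'   (the window used), `residual_neg_slopes` (negative slopes remaining at
#'   the cap before the running-maximum pass) and `corrected_points`
#'   (points raised by that pass).
#' @export
smooth_monotone <- function(series, w_max = 25L) {
  stopifnot(inherits(series, "pm_series"))
  if (!is.numeric(w_max) || length(w_max) != 1L || w_max < 1 ||
      w_max != round(w_max) || w_max %% 2 == 0)
    stop("w_max must be an odd integer >= 1")
  x <- series$signals
  window <- NA_integer_
  sm <- x
  for (w in seq(1L, as.integer(w_max), by = 2L)) {
    sm <- moving_average(x, w)
    if (!any(diff(sm) < -1e-9)) {
      window <- w
      break
    }
  }
  residual <- 0L
  corrected <- 0L
  if (is.na(window)) {
    window <- as.integer(w_max)
    residual <- sum(diff(sm) < -1e-9)
    fixed <- cummax(sm)
    corrected <- sum(fixed > sm + 1e-12)
    sm <- fixed
  }
  out <- series
  out$signals <- sm
  out$window <- window
  out$residual_neg_slopes <- residual
  out$corrected_points <- corrected
  class(out) <- c("pm_smooth", "pm_series")
  out
}

#' Average replicate kinetic series
#'
#' Pointwise arithmetic mean of replicates sharing a strain, condition and
#' time grid; the result carries replicate label `"mean"`.
#'
#' @param series_group List of [pm_series] (length >= 1) with identical
#'   strain, condition and time grids.
#' @return A [pm_series] with replicate `"mean"`.
#' @export
aggregate_replicates <- function(series_group) {
  if (!length(series_group)) stop("empty replicate group")
  ref <- series_group[[1L]]
  for (s in series_group) {
    if (s$strain_id != ref$strain_id || s$condition_id != ref$condition_id)
      stop("replicates must share strain and condition (got ",
           series_key(s), " with ", series_key(ref), ")")
    if (length(s$times) != length(ref$times) ||
        max(abs(s$times - ref$times)) > 1e-9)
      stop("mismatched time grids in replicate group for ",
           series_label(ref$strain_id, ref$condition_id, "mean"))
  }
  sig <- rowMeans(vapply(series_group, function(s) s$signals,
                         numeric(length(ref$times))))
  pm_series(ref$strain_id, ref$condition_id, "mean", ref$times, sig)
}

#' Signal at an assay endpoint
#'
#' Returns the signal at the latest sampled time at or before `t_end`
#' (no interpolation). On the standard 0.25 h grid the 50 h and 24 h
#' endpoints fall exactly on grid points.
#'
#' @param curve A [pm_series] (raw or smoothed).
#' @param t_end Endpoint time in hours; must be at or after the first sample.
#' @return The signal value at the endpoint.
#' @export
endpoint_signal <- function(curve, t_end) {
  stopifnot(inherits(curve, "pm_series"))
  ok <- which(curve$times <= t_end + 1e-9)
  if (!length(ok))
    stop("t_end = ", t_end, " h precedes the first sample of ",
         series_key(curve))
  curve$signals[max(ok)]
}

#' Estimate the time shift between two progress curves
#'
#' Finds the delay (in hours, >= 0) of `curve_test` relative to `curve_ref`
#' by exhaustive search over grid shifts: the shift minimising the mean
#' squared difference between the test curve and the delayed reference over
#' their overlapping window. Resolution equals the sampling step, matching
#' the precision at which fermentation slow-downs are reported. Both curves
#' must be cumulative (non-decreasing) progress curves on the same grid;
#' mild measurement noise is tolerated via `monotone_tol`, a fraction of
#' the curve range below which isolated decreases are ignored.
#'
#' @param curve_ref,curve_test [pm_series] on identical time grids.
#' @param max_shift_h Largest shift searched (default: half the run).
#' @param monotone_tol Largest single-step decrease tolerated, as a fraction
#'   of the curve's range (default 0.05).
#' @return Shift in hours (a multiple of the grid step); 0 for identical
#'   curves. Ties resolve to the smallest shift.
#' @export
estimate_time_shift <- function(curve_ref, curve_test, max_shift_h = NULL,
                                monotone_tol = 0.05) {
  stopifnot(inherits(curve_ref, "pm_series"), inherits(curve_test, "pm_series"))
  if (length(curve_ref$times) != length(curve_test$times) ||
      max(abs(curve_ref$times - curve_test$times)) > 1e-9)
    stop("curves must share a time grid")
  for (cv in list(ref = curve_ref, test = curve_test)) {
    rng <- diff(range(cv$signals))
    if (any(diff(cv$signals) < -monotone_tol * max(rng, .Machine$double.eps)))
      stop("non-monotone progress curve: ", series_key(cv))
  }
  step <- grid_step(curve_ref)
  n <- length(curve_ref$times)
  k_max <- if (is.null(max_shift_h)) (n - 2L) %/% 2L
           else min(n - 2L, as.integer(round(max_shift_h / step)))
  ref <- curve_ref$signals
  test <- curve_test$signals
  mse <- vapply(0:k_max, function(k) {
    idx <- (k + 1L):n
    mean((test[idx] - ref[idx - k])^2)
  }, numeric(1L))
  (which.min(mse) - 1L) * step
}
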