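#' Construct a kinetic series
#'
#' A kinetic series holds one well's time-resolved redox signal for a strain
#' under one condition: a uniformly spaced time grid in hours (15-min plate
#' photography gives a 0.25 h step) and the matching signal vector in the
#' instrument's arbitrary redox-intensity units.
#'
#' @param strain_id Strain identifier (non-empty string).
#' @param condition_id Condition identifier (non-empty string).
#' @param replicate Replicate label: a positive integer, or `"mean"` for a
#'   replicate-averaged curve.
#' @param times Numeric vector of sampling times in hours; strictly
#'   increasing and uniformly spaced (relative tolerance 1e-9), length >= 2.
#' @param signals Numeric vector of redox signal intensities, finite, same
#'   length as `times`.
#' @return An object of class `pm_series`.
#' @examples
#' s <- pm_series("S288C", "ctrl30", 1, seq(0, 96, by = 0.25),
#'                seq_len(385) / 10)
#' length(s$times)
#' @export
pm_series <- function(strain_id, condition_id, replicate, times, signals) {
  if (!is.character(strain_id) || length(strain_id) != 1L || !nzchar(strain_id))
    stop("strain_id must be a non-empty string")
  if (!is.character(condition_id) || length(condition_id) != 1L ||
      !nzchar(condition_id))
    stop("condition_id must be a non-empty string")
  if (!(identical(replicate, "mean") ||
        (is.numeric(replicate) && length(replicate) == 1L &&
         replicate >= 1 && replicate == round(replicate))))
    stop("replicate must be a positive integer or \"mean\"")
  times <- as.numeric(times)
  signals <- as.numeric(signals)
  id <- series_label(strain_id, condition_id, replicate)
  if (length(times) < 2L)
    stop("series ", id, ": needs at least 2 time points")
  if (length(signals) != length(times))
    stop("series ", id, ": times and signals differ in length")
  if (!all(is.finite(times)) || !all(is.finite(signals)))
    stop("series ", id, ": times and signals must be finite")
  check_uniform_grid(times, id)
  structure(
    list(strain_id = strain_id, condition_id = condition_id,
         replicate = replicate, times = times, signals = signals),
    class = "pm_series"
  )
}

series_label <- function(strain_id, condition_id, replicate) {
  paste0(strain_id, "/", condition_id, "/rep", replicate)
}

series_key <- function(s) {
  series_label(s$strain_id, s$condition_id, s$replicate)
}

# uniform-grid check; tolerance is relative to the step size
check_uniform_grid <- function(times, id, rtol = 1e-9) {
  d <- diff(times)
  if (any(d <= 0))
    stop("series ", id, ": times must be strictly increasing")
  step <- (times[length(times)] - times[1L]) / (length(times) - 1L)
  if (max(abs(d - step)) > rtol * max(step, 1))
    stop("series ", id, ": non-uniform time grid (expected step ",
         format(step), ")")
  invisible(step)
}

grid_step <- function(s) {
  (s$times[length(s$times)] - s$times[1L]) / (length(s$times) - 1L)
}

#' @export
print.pm_series <- function(x, ...) {
  cat("<pm_series> ", series_key(x), "\n", sep = "")
  cat("  ", length(x$times), " points, t = ", format(x$times[1L]), "..",
      format(x$times[length(x$times)]), " h (step ",
      format(grid_step(x)), " h)\n", sep = "")
  cat("  signal range [", format(min(x$signals)), ", ",
      format(max(x$signals)), "] units\n", sep = "")
  if (!is.null(x$window))
    cat("  smoothed, window ", x$window, "\n", sep = "")
  invisible(x)
}
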