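#' Absolute prediction-error curve
#'
#' `R_abs(t_i) = |Y(t_i) - d*(t_i)|`, the absolute difference between the
#' S-map forecast and the observed value, in target-variable units. Low
#' absolute error signals proximity to an attractor.
#'
#' @param fc a [forecast_series()].
#' @return A data frame of class `error_curve` (columns `time`, `raw`) with
#'   attribute `kind = "absolute"`.
#' @export
absolute_error_curve <- function(fc) {
  stopifnot(inherits(fc, "forecast_series"))
  out <- data.frame(time = fc$time, raw = abs(fc$predicted - fc$actual))
  class(out) <- c("error_curve", "data.frame")
  attr(out, "kind") <- "absolute"
  out
}

#' Relative prediction-error curve
#'
#' `R_rel(t_i) = |(Y(t_i) - d*(t_i)) / d*(t_i)|`, dimensionless. Points whose
#' observed value is below `floor` in magnitude are skipped (not zero-filled),
#' which avoids spurious spikes; the number skipped is recorded in the
#' `n_skipped` attribute.
#'
#' @param fc a [forecast_series()].
#' @param floor smallest |actual| admitted to the ratio.
#' @return A data frame of class `error_curve` with attribute
#'   `kind = "relative"`.
#' @export
relative_error_curve <- function(fc, floor = 1e-8) {
  stopifnot(inherits(fc, "forecast_series"))
  ok <- abs(fc$actual) >= floor
  out <- data.frame(time = fc$time[ok],
                    raw = abs((fc$predicted[ok] - fc$actual[ok]) / fc$actual[ok]))
  class(out) <- c("error_curve", "data.frame")
  attr(out, "kind") <- "relative"
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Gaussian-weighted trailing smoothing
#'
#' Strictly causal smoothing: each smoothed value is the Gaussian-weighted
#' average of up to `window` trailing raw values (including the current one),
#' with kernel `g_m = exp(-m^2 / (2 bandwidth^2))` at lag `m` and weights
#' renormalised over the points actually available.
#'
#' @param curve an `error_curve`.
#' @param window number of trailing points used (>= 1; default 10).
#' @param bandwidth Gaussian kernel width in lag units (default `window/3`).
#' @return The curve with a `smoothed` column added.
#' @export
smooth_curve <- function(curve, window = 10L, bandwidth = window / 3) {
  stopifnot(inherits(curve, "error_curve"), window >= 1, bandwidth > 0)
  g <- exp(-(0:(window - 1L))^2 / (2 * bandwidth^2))
  raw <- curve$raw
  n <- length(raw)
  sm <- numeric(n)
  for (i in seq_len(n)) {
    m <- min(window, i)
    sm[i] <- sum(g[1:m] * raw[i:(i - m + 1L)]) / sum(g[1:m])
  }
  curve$smoothed <- sm
  attr(curve, "window") <- window
  attr(curve, "bandwidth") <- bandwidth
  curve
}

detection_result <- function(t_pred, rule, threshold, index) {
  structure(list(t_pred = t_pred, rule = rule, threshold = threshold,
                 triggered_index = index),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (is.null(x$t_pred)) {
    cat(sprintf("no transient-end prediction (%s rule, threshold %g)\n",
                x$rule, x$threshold))
  } else {
    cat(sprintf("transient end predicted at t = %g (%s rule, threshold %g, index %d)\n",
                x$t_pred, x$rule, x$threshold, x$triggered_index))
  }
  invisible(x)
}

#' Absolute-error transient-end detector
#'
#' Predicts the transient end at the first grid time where the smoothed
#' absolute error drops below the floor `delta_a`: near the equilibrium the
#' S-map forecasts well, so a persistently low absolute error marks the start
#' of the equilibrium phase. Returns "no prediction" when the curve never goes
#' below the floor.
#'
#' @param curve a smoothed `error_curve` (see [smooth_curve()]).
#' @param delta_a positive threshold in target-variable units.
#' @return A `detection_result`; `t_pred` is `NULL` when no point qualifies.
#' @export
detect_absolute <- function(curve, delta_a) {
  stopifnot(inherits(curve, "error_curve"), delta_a > 0,
            !is.null(curve$smoothed), nrow(curve) > 0)
  i <- which(curve$smoothed < delta_a)
  if (!length(i)) return(detection_result(NULL, "absolute", delta_a, NA_integer_))
  detection_result(curve$time[i[1L]], "absolute", delta_a, i[1L])
}

#' Relative-error transient-end detector
#'
#' Predicts the transient end at the first grid time where the smoothed
#' relative error exceeds `delta_r` *and* is a strict local maximum of the
#' smoothed curve: the forecast error spikes when the dynamics leave the
#' transient pseudo-attractor and cross to the equilibrium. A local maximum
#' must exceed both neighbours; an exact-tie plateau resolves to its last
#' point; the first and last points are ineligible (a causal detector confirms
#' a maximum only once the following value is seen — the reported time is that
#' of the maximum itself). Returns "no prediction" when no qualifying spike
#' exists.
#'
#' @param curve a smoothed `error_curve`.
#' @param delta_r positive dimensionless threshold.
#' @return A `detection_result`; `t_pred` is `NULL` when no point qualifies.
#' @export
detect_relative <- function(curve, delta_r) {
  stopifnot(inherits(curve, "error_curve"), delta_r > 0,
            !is.null(curve$smoothed), nrow(curve) > 0)
  s <- curve$smoothed
  n <- length(s)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (s[i] <= delta_r) next
      # resolve plateaus to their last point: the next differing value must
      # be lower, and the previous differing value must be lower
      if (s[i + 1L] >= s[i]) next
      j <- i - 1L
      while (j >= 1L && s[j] == s[i]) j <- j - 1L
      if (j < 1L || s[j] >= s[i]) next
      return(detection_result(curve$time[i], "relative", delta_r, i))
    }
  }
  detection_result(NULL, "relative", delta_r, NA_integer_)
}
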