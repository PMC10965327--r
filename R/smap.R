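#' S-map forecaster configuration
#'
#' The S-map (sequential locally weighted global linear map) forecasts a
#' target variable one grid step ahead from an `E`-dimensional data vector,
#' fitting a local linear map whose training points are weighted by their
#' state-space distance to the query. `theta` controls the weight decay:
#' `theta = 0` is a global linear model, larger values localise the fit.
#'
#' @param theta nonlinearity weighting (>= 0, default 5).
#' @param E embedding dimension (default 4: the four observed state variables).
#' @param h maximum trailing-library size in monitoring mode (>= 2, default 20).
#' @param target index of the forecast variable within the data vector
#'   (default 1, the substrate `S1`).
#' @return An object of class `smap_config`.
#' @export
smap_config <- function(theta = 5, E = 4L, h = 20L, target = 1L) {
  stopifnot(theta >= 0, E >= 1, h >= 2, target >= 1, target <= E)
  structure(list(theta = theta, E = as.integer(E), h = as.integer(h),
                 target = as.integer(target)),
            class = "smap_config")
}

#' Training library of state/next-target pairs
#'
#' @param states numeric matrix, one row per library point `D(t_i)`.
#' @param targets observed target values one grid step after each row of
#'   `states`.
#' @return An object of class `smap_library`.
#' @export
smap_library <- function(states, targets) {
  states <- as.matrix(states)
  if (nrow(states) < 1L) stop("library must contain at least one pair")
  if (nrow(states) != length(targets))
    stop("states and targets must have equal length")
  structure(list(states = unname(states), targets = as.numeric(targets)),
            class = "smap_library")
}

#' Distance-decay weights of the S-map
#'
#' `w_i = exp(-theta * ||D(t_i) - query|| / dbar)` where `dbar` is the mean
#' Euclidean distance from the query to all library states. When the query
#' coincides with every library state (`dbar = 0`) all weights are 1.
#'
#' @param library an [smap_library()].
#' @param query numeric query vector (same dimension as library states).
#' @param theta nonlinearity weighting.
#' @return Numeric weight vector in `(0, 1]`.
#' @export
smap_weights <- function(library, query, theta) {
  stopifnot(inherits(library, "smap_library"))
  if (length(query) != ncol(library$states))
    stop("query dimension ", length(query), " does not match library dimension ",
         ncol(library$states))
  d <- sqrt(rowSums((library$states - rep(query, each = nrow(library$states)))^2))
  dbar <- mean(d)
  if (dbar == 0) return(rep(1, length(d)))
  exp(-theta * d / dbar)
}

# minimum-norm least squares via SVD; singular values below rtol*max dropped
svd_solve <- function(A, b, rtol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d)
  if (!any(keep)) stop("degenerate library: all singular values vanish")
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' One S-map forecast
#'
#' Builds the weighted design `A[i, j] = w_i * d_j(t_i)` and response
#' `B[i] = w_i * d*(t_{i+1})`, solves `B = A C` by singular-value least squares
#' (minimum-norm when rank-deficient; singular values below `1e-10 * max`
#' discarded), and returns the forecast `Y = sum_j C_j * d_j(query)`. There is
#' no intercept term: the map is linear through the origin in the data
#' coordinates.
#'
#' @inheritParams smap_weights
#' @return The forecast value `Y` one grid step after the query.
#' @export
smap_forecast <- function(library, query, theta) {
  w <- smap_weights(library, query, theta)
  A <- library$states * w
  if (all(A == 0)) stop("degenerate library: all weighted states are zero")
  C <- svd_solve(A, w * library$targets)
  sum(C * query)
}

#' Forecast series container
#'
#' @param times grid times at which forecasts are evaluated.
#' @param predicted S-map forecasts at `times`.
#' @param actual observed target values at `times`.
#' @return A data frame of class `forecast_series`.
#' @export
forecast_series <- function(times, predicted, actual) {
  stopifnot(length(times) == length(predicted), length(times) == length(actual))
  out <- data.frame(time = times, predicted = predicted, actual = actual)
  class(out) <- c("forecast_series", "data.frame")
  out
}

# data matrix (rows = D(t_i)) and target column for a series + config
series_design <- function(ts, cfg) {
  D <- ts_states(ts)
  if (cfg$E != ncol(D))
    stop("config E = ", cfg$E, " does not match series dimension ", ncol(D))
  list(D = D, target = D[, cfg$target])
}

#' Monitoring-mode forecasts (trailing library)
#'
#' For each feasible time index `j >= 2`, the library holds the transitions of
#' the trailing `h` points — states `D(t_{j-h}), ..., D(t_{j-1})` paired with
#' their observed next-step targets — all available history when `j <= h`. The
#' query is `D(t_j)` and the forecast targets `t_j + dt`. Forecasts therefore
#' exist for evaluation times `t_3, ..., t_n`.
#'
#' @param ts an [ad_ts()] series.
#' @param cfg an [smap_config()].
#' @return A [forecast_series()].
#' @export
monitoring_forecasts <- function(ts, cfg) {
  stopifnot(inherits(ts, "ad_ts"), inherits(cfg, "smap_config"))
  n <- nrow(ts)
  if (n < 3L) stop("monitoring mode needs a series of length >= 3")
  des <- series_design(ts, cfg)
  js <- 2:(n - 1L)
  pred <- numeric(length(js))
  for (m in seq_along(js)) {
    j <- js[m]
    lo <- max(1L, j - cfg$h)
    lib <- smap_library(des$D[lo:(j - 1L), , drop = FALSE], des$target[(lo + 1L):j])
    pred[m] <- smap_forecast(lib, des$D[j, ], cfg$theta)
  }
  forecast_series(ts$time[js + 1L], pred, des$target[js + 1L])
}

#' Control-mode forecasts (fixed reference library)
#'
#' The library is built once from every consecutive transition of a fully
#' observed control series and reused for every forecast: for each index `j`
#' of the target series, the query is `D(t_j)` and the forecast targets
#' `t_j + dt`.
#'
#' @param control an [ad_ts()] reference series (the training data).
#' @param target_ts an [ad_ts()] series to forecast (same grid spacing).
#' @param cfg an [smap_config()].
#' @return A [forecast_series()].
#' @export
control_forecasts <- function(control, target_ts, cfg) {
  stopifnot(inherits(control, "ad_ts"), inherits(target_ts, "ad_ts"),
            inherits(cfg, "smap_config"))
  if (abs(attr(control, "dt") - attr(target_ts, "dt")) >
      1e-9 * attr(target_ts, "dt"))
    stop("control and target series have different grid spacings")
  if (nrow(control) < 2L) stop("control series needs at least 2 points")
  desc <- series_design(control, cfg)
  nc <- nrow(control)
  lib <- smap_library(desc$D[-nc, , drop = FALSE], desc$target[-1L])
  dest <- series_design(target_ts, cfg)
  nt <- nrow(target_ts)
  js <- 1:(nt - 1L)
  pred <- vapply(js, function(j) smap_forecast(lib, dest$D[j, ], cfg$theta),
                 numeric(1))
  forecast_series(target_ts$time[js + 1L], pred, dest$target[js + 1L])
}
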