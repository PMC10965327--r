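#' Coefficient of determination against the identity line
#'
#' `R^2` computed with respect to the line `y = x` rather than a fitted
#' regression: `1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)`.
#' It equals 1 only for perfect prediction, and — unlike best-fit `R^2` — it
#' penalises systematic bias, going strongly negative for a consistently
#' offset predictor. Reported unclipped.
#'
#' @param predicted predicted transient end times.
#' @param truth ground-truth transient end times (must not be all equal).
#' @return The identity-line `R^2` (<= 1, possibly negative).
#' @export
r2_identity <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop("identity-line R^2 undefined: truth values have zero variance")
  1 - sum((predicted - truth)^2) / ss_tot
}

#' Pearson correlation of predicted and true end times
#'
#' A correlation of 1 means the predictions and the truth are perfectly
#' linearly related but, being shift- and scale-invariant, does not by itself
#' mean the predictions are accurate (a constant over- or under-prediction
#' still correlates perfectly).
#'
#' @inheritParams r2_identity
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_corr <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) > 1)
  if (stats::sd(predicted) == 0 || stats::sd(truth) == 0)
    stop("Pearson correlation undefined: zero variance")
  stats::cor(predicted, truth)
}

#' Proportion of successful predictions
#'
#' @param n_predicted number of series for which the detector produced a
#'   prediction.
#' @param n_attempted number of series attempted (>= 1).
#' @return `n_predicted / n_attempted`.
#' @export
success_rate <- function(n_predicted, n_attempted) {
  stopifnot(n_attempted >= 1, n_predicted >= 0, n_predicted <= n_attempted)
  n_predicted / n_attempted
}

#' Default sweep grids
#'
#' Noise levels: 10 log-spaced points on [5e-4, 5]; detection thresholds: 15
#' log-spaced points on [1e-3, 1e2]; working spacings 0.05-1 d; trailing
#' library sizes 2-20.
#'
#' @return List with elements `sigma`, `delta`, `dt`, `h`.
#' @export
default_grids <- function() {
  list(sigma = exp(seq(log(5e-4), log(5), length.out = 10)),
       delta = exp(seq(log(1e-3), log(1e2), length.out = 15)),
       dt = c(0.05, 0.1, 0.5, 1),
       h = c(2L, 5L, 10L, 20L))
}

# detect on one forecast series; returns t_pred or NA
detect_from_fc <- function(fc, rule, delta, window = 10L) {
  curve <- if (rule == "abs") absolute_error_curve(fc) else relative_error_curve(fc)
  curve <- smooth_curve(curve, window = window)
  det <- if (rule == "abs") detect_absolute(curve, delta) else detect_relative(curve, delta)
  if (is.null(det$t_pred)) NA_real_ else det$t_pred
}

#' Factorial sweep over noise, threshold, spacing and library size
#'
#' For each noise level `sigma`, `n_series` synthetic series (plus one control
#' series in control mode) are generated once and reused across every
#' `(dt, h, delta)` cell: each cell subsamples the series to spacing `dt`,
#' forecasts with the S-map (trailing library of `h` points in monitoring
#' mode, the full control series in control mode), builds the smoothed error
#' curve, applies the detector, and pairs predictions with the ground-truth
#' end times. Pairs without a prediction count only against the success
#' proportion; accuracy scores use predicted pairs alone, and cells with fewer
#' than 2 predictions (or degenerate truth) report `NA` scores.
#'
#' @param grids list with components `sigma`, `delta`, `dt`, `h`
#'   (see [default_grids()]); `h` is ignored in control mode.
#' @param n_series series per noise level (>= 2).
#' @param base_seed integer seed; the sweep is a pure function of
#'   `(grids, n_series, base_seed, ...)`.
#' @param mode `"monitoring"` or `"control"`.
#' @param rule `"rel"` (relative-error spike) or `"abs"` (absolute-error floor).
#' @param params,sim_dt,t_max,theta simulation and forecaster settings.
#' @param window smoothing window (trailing points).
#' @return A data frame of class `sweep_result`, one row per cell, with
#'   columns `sigma`, `dt`, `h`, `delta`, `n_attempted`, `n_predicted`,
#'   `success`, `r2_identity`, `pearson_r`, and a `pairs` attribute (list of
#'   per-cell predicted/true time pairs).
#' @export
run_sweep <- function(grids, n_series, base_seed = 1L,
                      mode = c("monitoring", "control"),
                      rule = c("rel", "abs"),
                      params = ad_params(), sim_dt = 0.01, t_max = 200,
                      theta = 5, window = 10L) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  stopifnot(n_series >= 2, length(grids$sigma) >= 1, length(grids$delta) >= 1,
            length(grids$dt) >= 1)
  h_grid <- if (mode == "control") NA_integer_ else grids$h
  rows <- list()
  pairs <- list()
  set.seed(base_seed)
  sigma_seeds <- sample.int(.Machine$integer.max, length(grids$sigma))
  for (si in seq_along(grids$sigma)) {
    sigma <- grids$sigma[si]
    noise <- noise_model(sigma, sim_dt)
    batch <- generate_batch(n_series, params, noise, t_max,
                            base_seed = sigma_seeds[si])
    control_full <- if (mode == "control") {
      init <- random_init(sigma_seeds[si] %% 100003L + 1L)
      suppressWarnings(simulate_stochastic(params, noise, init, t_max,
                                           seed = sigma_seeds[si] %% 999983L + 1L))
    } else NULL
    for (dt in grids$dt) {
      sub <- lapply(batch$series, subsample, delta_t = dt)
      control_sub <- if (!is.null(control_full)) subsample(control_full, dt)
      for (h in h_grid) {
        fcs <- if (mode == "monitoring") {
          cfg <- smap_config(theta = theta, h = h)
          lapply(sub, monitoring_forecasts, cfg = cfg)
        } else {
          cfg <- smap_config(theta = theta)
          lapply(sub, function(s) control_forecasts(control_sub, s, cfg))
        }
        for (delta in grids$delta) {
          t_pred <- vapply(fcs, detect_from_fc, numeric(1),
                           rule = rule, delta = delta, window = window)
          ok <- !is.na(t_pred) & !is.na(batch$t_end)
          n_att <- length(t_pred)
          n_pred <- sum(!is.na(t_pred))
          r2 <- pr <- NA_real_
          if (sum(ok) >= 2 && stats::var(batch$t_end[ok]) > 0) {
            r2 <- r2_identity(t_pred[ok], batch$t_end[ok])
            if (stats::sd(t_pred[ok]) > 0)
              pr <- pearson_corr(t_pred[ok], batch$t_end[ok])
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sigma = sigma, dt = dt, h = h, delta = delta,
            n_attempted = n_att, n_predicted = n_pred,
            success = n_pred / n_att,
            r2_identity = r2, pearson_r = pr)
          pairs[[length(pairs) + 1L]] <-
            data.frame(predicted = t_pred[ok], truth = batch$t_end[ok])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "pairs") <- pairs
  attr(out, "mode") <- mode
  attr(out, "rule") <- rule
  out
}
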