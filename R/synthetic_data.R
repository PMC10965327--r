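#' Multiplicative noise model for the stochastic chemostat
#'
#' Each state variable receives an independent Gaussian increment with
#' state-dependent variance `sigma^2 * x^2 * dt` (multiplicative noise),
#' truncated so that the state can hit exactly zero but never becomes
#' negative: an increment that would cross zero is replaced by `-x`, which
#' places an atom of probability `pnorm(-1/(sigma*sqrt(dt)))` on extinction.
#'
#' @param sigma noise level (dimensionless, >= 0).
#' @param dt simulation step (d, > 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, dt = 0.01) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(dt), length(dt) == 1L, dt > 0)
  structure(list(sigma = sigma, dt = dt), class = "noise_model")
}

#' Draw truncated multiplicative-noise increments
#'
#' Draws `w ~ Normal(0, sigma^2 x^2 dt)` for each element of `x` from the
#' current RNG stream. Where `x + w < 0` the increment is replaced by `-x`
#' (the next value is exactly zero, the extinction atom). `x = 0` yields 0:
#' extinction is absorbing for the noise term.
#'
#' @param x current non-negative value(s).
#' @param noise a [noise_model()].
#' @return Increment(s), same length as `x`.
#' @export
sample_increment <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"), all(x >= 0))
  if (noise$sigma == 0) return(numeric(length(x)) )
  w <- stats::rnorm(length(x), mean = 0, sd = noise$sigma * x * sqrt(noise$dt))
  pmax(w, -x)
}

#' Uniform random initial condition for synthetic series
#'
#' Draws `S1(0) ~ U(0,1)`, `S2(0) ~ U(0,1)`, `X1(0) ~ U(0,0.5)`,
#' `X2(0) ~ U(0,1)`, independently — initial conditions small and far from the
#' equilibrium so that a nonlinear transient occurs.
#'
#' @param seed optional integer seed; when given the draw is reproducible.
#' @return Named initial state vector.
#' @export
random_init <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(S1 = stats::runif(1), S2 = stats::runif(1),
    X1 = stats::runif(1, 0, 0.5), X2 = stats::runif(1))
}

#' Simulate the stochastic analogue of the AD model
#'
#' Euler scheme for the stochastic chemostat: at each step the state advances
#' by the deterministic drift (the dimensional model right-hand side) times
#' `dt` plus one truncated multiplicative-noise increment per variable (drawn
#' in the fixed order S1, S2, X1, X2). Noise cannot drive a variable negative
#' by construction; a component driven negative by the drift alone is clamped
#' to zero and counted in the `n_clamped` attribute (a warning summarises the
#' count).
#'
#' @param params an [ad_params()] object.
#' @param noise a [noise_model()]; its `dt` is the simulation step.
#' @param init named non-negative initial state `(S1, S2, X1, X2)`.
#' @param t_max simulation horizon (d).
#' @param seed optional integer seed; identical seeds give bit-identical series.
#' @return An [ad_ts()] in the dimensional frame with attribute `n_clamped`.
#' @export
simulate_stochastic <- function(params, noise, init, t_max, seed = NULL) {
  stopifnot(inherits(params, "ad_params"), inherits(noise, "noise_model"),
            t_max > 0)
  init <- check_state(init, "dimensional")
  if (!is.null(seed)) set.seed(seed)
  dt <- noise$dt
  n <- floor(t_max / dt + 1e-9) + 1L
  times <- (seq_len(n) - 1L) * dt
  out <- matrix(NA_real_, n, 4L)
  state <- unname(init)
  out[1L, ] <- state
  # pre-draw standard normals; scaled per step by the current state
  z <- if (noise$sigma > 0) {
    matrix(stats::rnorm(4L * (n - 1L)), n - 1L, 4L, byrow = TRUE)
  } else matrix(0, n - 1L, 4L)
  sig_sqdt <- noise$sigma * sqrt(dt)
  D <- params$D; S0 <- params$S0
  y1 <- params$y1; y2 <- params$y2; y3 <- params$y3
  r1 <- params$D + params$k1; r2 <- params$D + params$k2
  H1 <- params$H1; H2 <- params$H2
  m1 <- params$mu1_max; m2 <- params$mu2_max
  n_clamped <- 0L
  for (i in seq_len(n - 1L)) {
    S1 <- state[1L]; S2 <- state[2L]; X1 <- state[3L]; X2 <- state[4L]
    g1 <- m1 * S1 / (H1 + S1) * X1
    g2 <- m2 * S2 / (H2 + S2) * X2
    drift <- c(D * (S0 - S1) - y1 * g1,
               -D * S2 + y2 * g1 - y3 * g2,
               -r1 * X1 + g1,
               -r2 * X2 + g2)
    w <- pmax(z[i, ] * (sig_sqdt * state), -state)
    state <- state + drift * dt + w
    if (any(state < 0)) {
      n_clamped <- n_clamped + sum(state < 0)
      state <- pmax(state, 0)
    }
    if (any(!is.finite(state)))
      stop("simulation failure: non-finite state at t = ", format(times[i + 1L]))
    out[i + 1L, ] <- state
  }
  if (n_clamped > 0L)
    warning("drift clamped ", n_clamped, " negative component value(s) to zero")
  ts <- ad_ts(times, out, "dimensional")
  attr(ts, "n_clamped") <- n_clamped
  ts
}

#' Subsample a series to a coarser uniform spacing
#'
#' Keeps every `delta_t/dt`-th row starting at the first; `delta_t` must be an
#' integer multiple of the source spacing (relative tolerance 1e-9). This is
#' how working series at spacing `delta_t` are extracted from the densely
#' simulated originals.
#'
#' @param ts an [ad_ts()].
#' @param delta_t target spacing, an integer multiple of `attr(ts, "dt")`.
#' @return The subsampled [ad_ts()].
#' @export
subsample <- function(ts, delta_t) {
  stopifnot(inherits(ts, "ad_ts"))
  dt <- attr(ts, "dt")
  ratio <- delta_t / dt
  stride <- round(ratio)
  if (stride < 1 || abs(ratio - stride) > 1e-9 * ratio)
    stop("delta_t = ", delta_t, " is not an integer multiple of the source spacing ", dt)
  idx <- seq(1L, nrow(ts), by = stride)
  ad_ts(ts$time[idx], ts_states(ts)[idx, , drop = FALSE], attr(ts, "frame"))
}

#' Default equilibrium-proximity tolerance
#'
#' Width of the band around `S1*` that defines the ground-truth transient end;
#' noisier series get a wider band: `max(0.25, 0.5 * sigma)` in `S1` units
#' (g l^-1).
#'
#' @param sigma noise level of the series.
#' @return The tolerance `delta_eq`.
#' @export
default_delta_eq <- function(sigma) max(0.25, 0.5 * sigma)

#' Ground-truth transient end time
#'
#' The transient is declared over at the first grid time where `S1` is within
#' `delta_eq` of the deterministic equilibrium `s1_star`, i.e. the series
#' begins to approach the equilibrium. Because the transient of interest is an
#' overshoot — from small initial conditions `S1` rises straight through the
#' equilibrium band before peaking far above it — the scan starts only once
#' `S1` has first left the band upward (`S1 >= s1_star + delta_eq`); the
#' momentary up-crossing at the start of the run is not the end of the
#' transient. For a series that never leaves the band upward (no overshoot),
#' the scan covers the whole series.
#'
#' @param ts an [ad_ts()] in the dimensional frame.
#' @param s1_star deterministic `S1` equilibrium.
#' @param delta_eq proximity tolerance (> 0), see [default_delta_eq()].
#' @return A list of class `ground_truth` with `t_end`, `index`, `delta_eq`,
#'   `s1_star`, or `NULL` when the series never enters the band.
#' @export
true_end_time <- function(ts, s1_star, delta_eq) {
  stopifnot(inherits(ts, "ad_ts"), delta_eq > 0)
  from <- 1L
  up <- which(ts$S1 >= s1_star + delta_eq)
  if (length(up)) from <- up[1L]
  s1 <- ts$S1[from:nrow(ts)]
  i <- which(abs(s1 - s1_star) < delta_eq)
  if (!length(i)) return(NULL)
  idx <- from + i[1L] - 1L
  structure(list(t_end = ts$time[idx], index = idx,
                 delta_eq = delta_eq, s1_star = s1_star),
            class = "ground_truth")
}

#' Generate a batch of synthetic series with ground truth
#'
#' Draws `n` random initial conditions and simulates `n` independent stochastic
#' series from one base seed (series `k` uses a sub-seed derived from
#' `base_seed`), computing each ground-truth transient end time against the
#' deterministic equilibrium.
#'
#' @param n number of series.
#' @param params an [ad_params()] object.
#' @param noise a [noise_model()].
#' @param t_max horizon per series (d); the default 200 lets low-noise series
#'   reach the equilibrium band.
#' @param base_seed integer seed controlling the whole batch.
#' @param delta_eq equilibrium band width; defaults to
#'   [default_delta_eq()]`(noise$sigma)`.
#' @return List with `series` (list of [ad_ts()]), `t_end` (numeric, `NA` when
#'   undefined), `seeds`, `inits`, `s1_star`, `delta_eq`.
#' @export
generate_batch <- function(n, params = ad_params(), noise = noise_model(0.1),
                           t_max = 200, base_seed = 1L,
                           delta_eq = default_delta_eq(noise$sigma)) {
  stopifnot(n >= 1)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, 2L * n)
  init_seeds <- seeds[seq_len(n)]
  sim_seeds <- seeds[n + seq_len(n)]
  s1_star <- dimensional_equilibrium(params)$state[["S1"]]
  series <- vector("list", n)
  inits <- matrix(NA_real_, n, 4L,
                  dimnames = list(NULL, state_names("dimensional")))
  t_end <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    init <- random_init(init_seeds[k])
    inits[k, ] <- init
    ts <- suppressWarnings(
      simulate_stochastic(params, noise, init, t_max, seed = sim_seeds[k]))
    series[[k]] <- ts
    gt <- true_end_time(ts, s1_star, delta_eq)
    if (!is.null(gt)) t_end[k] <- gt$t_end
  }
  list(series = series, t_end = t_end, seeds = sim_seeds, inits = inits,
       s1_star = s1_star, delta_eq = delta_eq)
}
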