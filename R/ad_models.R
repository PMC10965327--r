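#' Dimensional anaerobic-digestion chemostat parameters
#'
#' Constructs and validates the parameter set of the two-guild anaerobic
#' digestion (AD) chemostat model: acidogens `X1` degrade the simple substrate
#' `S1` into volatile fatty acids `S2`, which methanogens `X2` consume. Both
#' guilds grow with Monod kinetics and are washed out at the dilution rate `D`.
#' Defaults are the synthetic-data parameter set used throughout the package.
#'
#' @param D dilution rate of the chemostat (d^-1).
#' @param S0 inflow concentration of `S1` (g l^-1).
#' @param y1 degradation yield, g of `S1` consumed per g of `X1` produced.
#' @param y2 production yield, mmol of `S2` produced per g of `X1`.
#' @param y3 consumption yield, mmol of `S2` consumed per g of `X2`.
#' @param k1,k2 decay rates of `X1` and `X2` (d^-1).
#' @param H1 half-saturation constant for `S1` degradation (g l^-1).
#' @param H2 half-saturation constant for `S2` consumption (mmol l^-1).
#' @param mu1_max,mu2_max maximal growth rates of `X1` and `X2` (d^-1).
#'
#' @return An object of class `ad_params` (a named list).
#' @export
#' @examples
#' p <- ad_params()
#' dimensional_equilibrium(p)$state[["S1"]]
ad_params <- function(D = 0.055, S0 = 700, y1 = 42.14, y2 = 116.5, y3 = 268,
                      k1 = 0.1, k2 = 0.001, H1 = 10, H2 = 9.28,
                      mu1_max = 0.5, mu2_max = 0.0064) {
  p <- list(D = D, S0 = S0, y1 = y1, y2 = y2, y3 = y3, k1 = k1, k2 = k2,
            H1 = H1, H2 = H2, mu1_max = mu1_max, mu2_max = mu2_max)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all 'ad_params' fields must be finite and strictly positive")
  if (mu1_max <= D + k1)
    stop("mu1_max must exceed D + k1 for a positive acidogen equilibrium (",
         mu1_max, " <= ", D + k1, ")")
  structure(p, class = "ad_params")
}

#' Dimensionless anaerobic-digestion model parameters
#'
#' Parameter groups of the non-dimensionalised AD model in states
#' `(u, v, x, y)` (scaled `S1`, `S2`, `X1`, `X2`). `eps = D/mu1` is the
#' timescale-separation parameter; a warning is issued when it is not small
#' (`eps >= 0.1`). `sigma1 < 1` is required for a positive fast equilibrium.
#'
#' @param eps timescale ratio D/mu1; must be << 1 for the fast-slow reduction.
#' @param alpha scaled substrate inflow S0*D/(H1*mu1).
#' @param beta scaled degradation yield.
#' @param sigma1 scaled acidogen decay k1/mu1.
#' @param sigma2 scaled methanogen decay k2/D.
#' @param omega scaled methanogen growth mu2/D.
#'
#' @return An object of class `dimless_params`.
#' @export
dimless_params <- function(eps = 0.11, alpha = 6, beta = 0.336,
                           sigma1 = 0.1, sigma2 = 0.0667, omega = 4.27) {
  p <- list(eps = eps, alpha = alpha, beta = beta,
            sigma1 = sigma1, sigma2 = sigma2, omega = omega)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all 'dimless_params' fields must be finite and strictly positive")
  if (sigma1 >= 1)
    stop("sigma1 must be < 1 for a positive fast equilibrium")
  if (eps >= 0.1)
    warning("eps = ", eps, " is not small; the fast-slow reduction assumes eps << 1")
  structure(p, class = "dimless_params")
}

#' @export
print.ad_params <- function(x, ...) {
  cat("AD chemostat parameters (dimensional):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.dimless_params <- function(x, ...) {
  cat("AD chemostat parameters (dimensionless):\n")
  print(unlist(x))
  invisible(x)
}

state_names <- function(frame) {
  if (identical(frame, "dimensional")) c("S1", "S2", "X1", "X2") else c("u", "v", "x", "y")
}

check_state <- function(state, frame) {
  nm <- state_names(frame)
  if (is.null(names(state))) names(state) <- nm
  state <- state[nm]
  if (any(is.na(state))) stop("state must have components ", paste(nm, collapse = ", "))
  if (any(state < 0)) stop("negative state component: ",
                           paste(nm[state < 0], collapse = ", "))
  state
}

#' Right-hand side of the dimensional AD model
#'
#' Time derivatives of `(S1, S2, X1, X2)` for the chemostat model with Monod
#' growth `mu_i(S) = mu_i_max * S / (H_i + S)`:
#' substrate inflow/washout at rate `D`, degradation of `S1` by `X1`,
#' production and consumption of `S2`, and first-order decay of both guilds.
#'
#' @param state named non-negative numeric vector `(S1, S2, X1, X2)`.
#' @param params an [ad_params()] object.
#' @return Named numeric vector of derivatives (same order as `state`).
#' @export
dimensional_rhs <- function(state, params) {
  stopifnot(inherits(params, "ad_params"))
  s <- check_state(state, "dimensional")
  S1 <- s[["S1"]]; S2 <- s[["S2"]]; X1 <- s[["X1"]]; X2 <- s[["X2"]]
  mu1 <- params$mu1_max * S1 / (params$H1 + S1)
  mu2 <- params$mu2_max * S2 / (params$H2 + S2)
  c(S1 = params$D * (params$S0 - S1) - params$y1 * mu1 * X1,
    S2 = -params$D * S2 + params$y2 * mu1 * X1 - params$y3 * mu2 * X2,
    X1 = -(params$D + params$k1) * X1 + mu1 * X1,
    X2 = -(params$D + params$k2) * X2 + mu2 * X2)
}

#' Right-hand side of the dimensionless AD model
#'
#' Time derivatives of `(u, v, x, y)` on the fast timescale. Every term of the
#' slow variable `y` carries the factor `eps`, which is what separates the
#' timescales when `eps` is small.
#'
#' @param state named non-negative numeric vector `(u, v, x, y)`.
#' @param params a [dimless_params()] object.
#' @return Named numeric vector of derivatives.
#' @export
dimensionless_rhs <- function(state, params) {
  stopifnot(inherits(params, "dimless_params"))
  s <- check_state(state, "dimensionless")
  u <- s[["u"]]; v <- s[["v"]]; x <- s[["x"]]; y <- s[["y"]]
  fu <- u / (1 + u)
  fv <- v / (1 + v)
  e <- params$eps
  c(u = params$alpha - e * u - params$beta * fu * x,
    v = -e * v + fu * x - fv * y,
    x = -e * x - params$sigma1 * x + fu * x,
    y = -e * (1 + params$sigma2) * y + e * params$omega * fv * y)
}

#' Coexistence-branch equilibrium of the dimensional model
#'
#' Solves the acidogen balance `mu1(S1*) = D + k1` for `S1*` and the substrate
#' balance for `X1*`. If the methanogen cannot grow fast enough
#' (`mu2_max <= D + k2`) it washes out: `X2* = 0` and `S2*` balances VFA
#' production against dilution. Otherwise `S2*` solves `mu2(S2*) = D + k2` and
#' `X2*` balances the `S2` equation.
#'
#' @param params an [ad_params()] object.
#' @return A list with `state` (named equilibrium vector) and `washout`
#'   (`TRUE` when the methanogen equilibrium is extinction).
#' @export
dimensional_equilibrium <- function(params) {
  stopifnot(inherits(params, "ad_params"))
  r1 <- params$D + params$k1
  if (params$mu1_max <= r1)
    stop("no positive equilibrium: mu1_max <= D + k1")
  S1s <- params$H1 * r1 / (params$mu1_max - r1)
  X1s <- params$D * (params$S0 - S1s) / (params$y1 * r1)
  r2 <- params$D + params$k2
  if (params$mu2_max <= r2) {
    washout <- TRUE
    X2s <- 0
    S2s <- params$y2 * r1 * X1s / params$D
  } else {
    washout <- FALSE
    S2s <- params$H2 * r2 / (params$mu2_max - r2)
    # S2 balance: -D*S2s + y2*r1*X1s - y3*r2*X2s = 0
    X2s <- (params$y2 * r1 * X1s - params$D * S2s) / (params$y3 * r2)
  }
  list(state = c(S1 = S1s, S2 = S2s, X1 = X1s, X2 = X2s), washout = washout)
}

#' Uniformly sampled multivariate trajectory
#'
#' Container for a trajectory on a strictly uniform time grid: a data frame
#' with a `time` column and the four state columns of the declared frame
#' (`S1,S2,X1,X2` dimensional or `u,v,x,y` dimensionless).
#'
#' @param times strictly increasing, uniformly spaced numeric vector.
#' @param states numeric matrix (rows match `times`) or data frame of the four
#'   state components.
#' @param frame `"dimensional"` or `"dimensionless"`.
#' @return A data frame of class `ad_ts` with attributes `frame` and `dt`.
#' @export
ad_ts <- function(times, states, frame = c("dimensional", "dimensionless")) {
  frame <- match.arg(frame)
  states <- as.matrix(states)
  if (length(times) != nrow(states)) stop("times and states lengths differ")
  if (length(times) < 2) stop("a time series needs at least 2 points")
  dt <- times[2] - times[1]
  if (dt <= 0) stop("times must be strictly increasing")
  gaps <- diff(times)
  bad <- which(abs(gaps - dt) > 1e-9 * dt)
  if (length(bad))
    stop("non-uniform time grid at row ", bad[1] + 1L,
         " (gap ", format(gaps[bad[1]]), ", expected ", format(dt), ")")
  colnames(states) <- state_names(frame)
  out <- data.frame(time = times, states, check.names = FALSE)
  class(out) <- c("ad_ts", "data.frame")
  attr(out, "frame") <- frame
  attr(out, "dt") <- dt
  out
}

#' @export
print.ad_ts <- function(x, ...) {
  cat(sprintf("<ad_ts> %s frame, %d points, dt = %g, t in [%g, %g]\n",
              attr(x, "frame"), nrow(x), attr(x, "dt"),
              x$time[1], x$time[nrow(x)]))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

ts_states <- function(ts) as.matrix(as.data.frame(ts)[, -1, drop = FALSE])

#' Fixed-step fourth-order Runge-Kutta integration
#'
#' Integrates `rhs(state, params)` on the exactly uniform grid
#' `0, dt, 2*dt, ...` up to `t_max`. The fixed step keeps output grids exactly
#' uniform for downstream stride subsampling. Tiny negative excursions are
#' clipped to zero (concentrations are non-negative by construction of the
#' model); clips beyond round-off (-1e-12) are reported in a warning.
#'
#' @param rhs function of `(state, params)` returning the derivative vector.
#' @param init named non-negative initial state.
#' @param params parameter object passed through to `rhs`.
#' @param t_max integration horizon (> 0).
#' @param dt step size (> 0).
#' @param frame frame tag for the returned series.
#' @return An [ad_ts()] trajectory.
#' @export
integrate_ode <- function(rhs, init, params, t_max, dt = 0.01,
                          frame = c("dimensional", "dimensionless")) {
  frame <- match.arg(frame)
  stopifnot(dt > 0, t_max > 0)
  init <- check_state(init, frame)
  n <- floor(t_max / dt + 1e-9) + 1L
  times <- (seq_len(n) - 1L) * dt
  out <- matrix(NA_real_, n, 4L)
  state <- unname(init)
  nm <- state_names(frame)
  out[1L, ] <- state
  n_clip <- 0L
  for (i in seq_len(n - 1L)) {
    s <- stats::setNames(state, nm)
    k1 <- unname(rhs(s, params))
    k2 <- unname(rhs(stats::setNames(pmax(state + dt / 2 * k1, 0), nm), params))
    k3 <- unname(rhs(stats::setNames(pmax(state + dt / 2 * k2, 0), nm), params))
    k4 <- unname(rhs(stats::setNames(pmax(state + dt * k3, 0), nm), params))
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state)))
      stop("integration failure: non-finite state at t = ", format(times[i + 1L]))
    if (any(state < 0)) {
      if (any(state < -1e-12)) n_clip <- n_clip + 1L
      state <- pmax(state, 0)
    }
    out[i + 1L, ] <- state
  }
  if (n_clip > 0L)
    warning("clipped negative components to zero at ", n_clip, " step(s)")
  ad_ts(times, out, frame)
}
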