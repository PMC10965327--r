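#' Right-hand side of the fast subsystem
#'
#' The dimensionless model in the singular limit `eps -> 0` on the fast
#' timescale: `(u, v, x)` evolve while the slow methanogen variable `y` acts
#' as a constant (its rate is exactly zero).
#'
#' @inheritParams dimensionless_rhs
#' @return Named derivative vector with `y` component exactly 0.
#' @export
fast_rhs <- function(state, params) {
  stopifnot(inherits(params, "dimless_params"))
  s <- check_state(state, "dimensionless")
  u <- s[["u"]]; v <- s[["v"]]; x <- s[["x"]]; y <- s[["y"]]
  fu <- u / (1 + u)
  fv <- v / (1 + v)
  c(u = params$alpha - params$beta * fu * x,
    v = fu * x - fv * y,
    x = -params$sigma1 * x + fu * x,
    y = 0)
}

#' Equilibrium of the fast subsystem
#'
#' The unique positive equilibrium of the fast flow for a frozen slow value
#' `y`: `u* = sigma1/(1-sigma1)`, `v* = alpha/(beta*y - alpha)`,
#' `x* = alpha/(beta*sigma1)`. A positive `v*` requires `beta*y > alpha`.
#'
#' @param params a [dimless_params()] object.
#' @param y frozen slow-variable value.
#' @return Named vector `(u, v, x)`.
#' @export
fast_equilibrium <- function(params, y) {
  stopifnot(inherits(params, "dimless_params"))
  if (params$sigma1 >= 1) stop("sigma1 must be < 1 for a positive fast equilibrium")
  if (params$beta * y <= params$alpha)
    stop("no positive fast equilibrium: beta*y <= alpha (y = ", y, ")")
  c(u = params$sigma1 / (1 - params$sigma1),
    v = params$alpha / (params$beta * y - params$alpha),
    x = params$alpha / (params$beta * params$sigma1))
}

# central-difference Jacobian of the first three fast equations at (u, v, x)
fast_jacobian <- function(params, y, at, h_scale = 1e-6) {
  f <- function(s3) {
    st <- c(s3, y = y)
    names(st) <- c("u", "v", "x", "y")
    unname(fast_rhs(st, params)[1:3])
  }
  J <- matrix(NA_real_, 3L, 3L)
  for (j in 1:3) {
    h <- h_scale * max(1, abs(at[j]))
    ep <- em <- at
    ep[j] <- at[j] + h
    em[j] <- max(at[j] - h, 0)
    J[, j] <- (f(ep) - f(em)) / (ep[j] - em[j])
  }
  J
}

#' Stability of the fast equilibrium
#'
#' Eigenvalues of the numerically differentiated (central differences) 3x3
#' Jacobian of the fast subsystem at its equilibrium, sorted by non-increasing
#' real part (ties broken by non-increasing imaginary part). The equilibrium is
#' stable when all real parts are negative.
#'
#' @inheritParams fast_equilibrium
#' @param h_scale relative step of the central-difference Jacobian.
#' @return List with `values` (complex eigenvalues, sorted) and `stable`.
#' @export
fast_stability <- function(params, y, h_scale = 1e-6) {
  eq <- fast_equilibrium(params, y)
  J <- fast_jacobian(params, y, unname(eq), h_scale)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev <- ev[order(-Re(ev), -Im(ev))]
  list(values = ev, stable = all(Re(ev) < 0))
}

#' Point on the critical manifold
#'
#' Solves the algebraic constraint of the slow differential-algebraic system
#' (the fast equations set to zero) for `(u, v, x)` at a given `y`, by damped
#' Newton iteration with a central-difference Jacobian, initialised from the
#' closed-form fast equilibrium.
#'
#' @inheritParams fast_equilibrium
#' @param tol residual tolerance for convergence.
#' @param max_iter iteration cap.
#' @return Named vector `(u, v, x)` satisfying the constraint to `tol`.
#' @export
slow_manifold_point <- function(y, params, tol = 1e-12, max_iter = 50L) {
  pt <- unname(fast_equilibrium(params, y))
  resid <- function(p) {
    st <- c(p, y)
    names(st) <- c("u", "v", "x", "y")
    unname(fast_rhs(st, params)[1:3])
  }
  r <- resid(pt)
  iter <- 0L
  while (max(abs(r)) > tol && iter < max_iter) {
    J <- fast_jacobian(params, y, pt, 1e-7)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- pmax(pt + lambda * step, 0)
      rc <- resid(cand)
      if (max(abs(rc)) < max(abs(r)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    pt <- pmax(pt + lambda * step, 0)
    r <- resid(pt)
    iter <- iter + 1L
  }
  if (max(abs(r)) > 1e-10)
    stop("critical-manifold solve failed at y = ", y,
         " (residual ", format(max(abs(r))), ")")
  stats::setNames(pt, c("u", "v", "x"))
}

#' Slow flow on the critical manifold
#'
#' Integrates the slow equation `y' = -(1+sigma2)*y + omega*v/(1+v)*y` on the
#' slow timescale `s`, re-solving the algebraic constraint for `(u, v, x)` at
#' every step (index-1 differential-algebraic system solved by alternating a
#' manifold root-solve with an explicit Euler step).
#'
#' @param y0 positive initial slow value.
#' @param params a [dimless_params()] object.
#' @param s_max slow-time horizon.
#' @param ds Euler step in slow time.
#' @return An [ad_ts()] in the dimensionless frame; `time` is slow time `s`.
#' @export
slow_flow <- function(y0, params, s_max, ds = 1e-2) {
  stopifnot(y0 > 0, s_max > 0, ds > 0)
  n <- floor(s_max / ds + 1e-9) + 1L
  times <- (seq_len(n) - 1L) * ds
  out <- matrix(NA_real_, n, 4L)
  y <- y0
  for (i in seq_len(n)) {
    uvx <- tryCatch(slow_manifold_point(y, params), error = function(e) NULL)
    if (is.null(uvx)) {
      if (i == 1L) stop("critical-manifold solve failed at y0 = ", y0)
      warning("manifold solve failed at s = ", format(times[i]),
              "; returning trajectory up to the last valid state")
      out <- out[seq_len(i - 1L), , drop = FALSE]
      times <- times[seq_len(i - 1L)]
      break
    }
    out[i, ] <- c(uvx, y)
    v <- uvx[["v"]]
    dy <- -(1 + params$sigma2) * y + params$omega * v / (1 + v) * y
    y <- y + ds * dy
  }
  ad_ts(times, out, "dimensionless")
}

#' Critical times of the staged transient approximation
#'
#' For small initial conditions the fast transient has three stages. Stage 1 is
#' inflow-dominated (`u` grows linearly at rate `alpha`) and ends at
#' `tau1 = (u_tol - u0)/alpha`, where `u_tol = (1 - eps_tol)/eps_tol` is the
#' value of `u` at which the Monod factor `u/(1+u)` equals `1 - eps_tol`.
#' Stage 2 has saturated uptake and exponential acidogen growth; it ends when
#' `u` stops increasing, at `tau2 = log(alpha/(beta*x0)) + tau1`.
#'
#' @param init named dimensionless initial state `(u, v, x, y)`.
#' @param params a [dimless_params()] object.
#' @param eps_tol tolerance defining saturation of `u/(1+u)` (default 0.05,
#'   i.e. `u_tol = 19`).
#' @return List of class `stage_times`: `tau1`, `tau2`, `u_tol`, `eps_tol`,
#'   and `tau2_degenerate` (`TRUE` when `alpha <= beta*x0` so stage 2 is empty).
#' @export
stage_times <- function(init, params, eps_tol = 0.05) {
  stopifnot(inherits(params, "dimless_params"), eps_tol > 0, eps_tol < 1)
  init <- check_state(init, "dimensionless")
  u0 <- init[["u"]]; x0 <- init[["x"]]
  u_tol <- (1 - eps_tol) / eps_tol
  if (u0 > u_tol * (1 + 1e-12))
    warning("u0 = ", u0, " already exceeds u_tol = ", u_tol,
            "; stage 1 is empty")
  tau1 <- max(u_tol - u0, 0) / params$alpha
  if (x0 == 0) stop("tau2 undefined: x0 = 0 (no acidogens to grow)")
  tau2 <- log(params$alpha / (params$beta * x0)) + tau1
  degenerate <- params$alpha <= params$beta * x0
  if (degenerate)
    warning("alpha <= beta*x0: tau2 <= tau1, staged approximation degenerate")
  structure(list(tau1 = tau1, tau2 = tau2, u_tol = u_tol, eps_tol = eps_tol,
                 tau2_degenerate = degenerate),
            class = "stage_times")
}

#' @export
print.stage_times <- function(x, ...) {
  cat(sprintf("stage times: tau1 = %.4f, tau2 = %.4f (u_tol = %g, eps_tol = %g)\n",
              x$tau1, x$tau2, x$u_tol, x$eps_tol))
  invisible(x)
}

# rhs of the saturated-uptake stage (stage 2): u' = alpha - beta*x,
# v' = x - v/(1+v)*y, x' = (1-sigma1)*x, y' = 0
stage2_rhs <- function(state, params) {
  s <- check_state(state, "dimensionless")
  v <- s[["v"]]; x <- s[["x"]]; y <- s[["y"]]
  c(u = params$alpha - params$beta * x,
    v = x - v / (1 + v) * y,
    x = (1 - params$sigma1) * x,
    y = 0)
}

# single RK4 step of length h
rk4_step <- function(rhs, state, params, h, nm) {
  s <- stats::setNames(state, nm)
  k1 <- unname(rhs(s, params))
  k2 <- unname(rhs(stats::setNames(pmax(state + h / 2 * k1, 0), nm), params))
  k3 <- unname(rhs(stats::setNames(pmax(state + h / 2 * k2, 0), nm), params))
  k4 <- unname(rhs(stats::setNames(pmax(state + h * k3, 0), nm), params))
  pmax(state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
}

#' Piecewise staged approximation of the fast transient
#'
#' Assembles the three-stage approximation of the fast transient on one
#' uniform grid: linear inflow growth of `u` (others frozen) for
#' `tau < tau1`; saturated uptake with exponential acidogen growth for
#' `tau1 <= tau <= tau2`; the full fast subsystem for `tau > tau2`. The state
#' is carried continuously across both hand-offs, and each hand-off occurs at
#' the exact critical time (grid steps straddling `tau1` or `tau2` are split).
#'
#' @inheritParams stage_times
#' @param t_max fast-time horizon.
#' @param dt integration step.
#' @return List with `ts` (the [ad_ts()] trajectory), `stages`
#'   (the [stage_times()] object), and `handoffs` (the carried state at each
#'   critical time falling inside a grid step, named by its time).
#' @export
piecewise_transient <- function(init, params, eps_tol = 0.05, t_max, dt = 0.01) {
  st <- stage_times(init, params, eps_tol)
  init <- check_state(init, "dimensionless")
  n <- floor(t_max / dt + 1e-9) + 1L
  times <- (seq_len(n) - 1L) * dt
  out <- matrix(NA_real_, n, 4L)
  state <- unname(init)
  nm <- state_names("dimensionless")
  out[1L, ] <- state
  stage1_rhs <- function(s, p) c(u = p$alpha, v = 0, x = 0, y = 0)
  rhs_on <- function(tau) {
    if (tau < st$tau1) stage1_rhs else if (tau < st$tau2) stage2_rhs else fast_rhs
  }
  breaks <- sort(c(st$tau1, st$tau2))
  handoffs <- list()
  for (i in seq_len(n - 1L)) {
    t0 <- times[i]; t1 <- times[i + 1L]
    cuts <- breaks[breaks > t0 + 1e-15 & breaks < t1 - 1e-15]
    pts <- c(t0, cuts, t1)
    for (k in seq_len(length(pts) - 1L)) {
      h <- pts[k + 1L] - pts[k]
      state <- rk4_step(rhs_on(pts[k]), state, params, h, nm)
      if (k < length(pts) - 1L)  # state carried across a stage hand-off
        handoffs[[format(pts[k + 1L])]] <- stats::setNames(state, nm)
    }
    if (any(!is.finite(state)))
      stop("integration failure: non-finite state at tau = ", format(t1))
    out[i + 1L, ] <- state
  }
  list(ts = ad_ts(times, out, "dimensionless"), stages = st,
       handoffs = handoffs)
}
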