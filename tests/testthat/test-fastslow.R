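dp2 <- dimless_params(eps = 0.05)

test_that("fast subsystem equals the dimensionless model at eps = 0", {
  # the dimensionless-params validator requires eps > 0; compare term-by-term
  # against the eps -> 0 limit computed by Richardson-style direct evaluation
  set.seed(42)
  for (i in 1:25) {
    s <- c(u = runif(1, 0, 5), v = runif(1, 0, 5),
           x = runif(1, 0, 200), y = runif(1, 0, 50))
    f <- fast_rhs(s, dp2)
    expect_identical(f[["y"]], 0)
    # eps -> 0 limit via tiny eps: terms are linear in eps
    tiny <- dimless_params(eps = 1e-12)
    expect_equal(unname(dimensionless_rhs(s, tiny)), unname(f),
                 tolerance = 1e-9)
  }
  expect_equal(fast_rhs(c(u = 0, v = 0, x = 0, y = 3), dp2),
               c(u = dp2$alpha, v = 0, x = 0, y = 0))
})

test_that("fast equilibrium matches its closed form and is a fixed point", {
  eq <- fast_equilibrium(dp2, y = 30)
  expect_equal(eq[["u"]], 0.1 / 0.9, tolerance = 1e-14)
  expect_equal(eq[["v"]], 6 / (0.336 * 30 - 6), tolerance = 1e-14)
  expect_equal(eq[["x"]], 6 / 0.0336, tolerance = 1e-12)
  r <- fast_rhs(c(eq, y = 30), dp2)
  expect_lt(max(abs(r[1:3])), 1e-10)
  expect_error(fast_equilibrium(dp2, y = 10), "beta\\*y <= alpha")
})

test_that("fast equilibrium is stable and eigenvalues are ordered and step-robust", {
  st <- fast_stability(dp2, y = 30)
  expect_true(st$stable)
  expect_true(all(diff(Re(st$values)) <= 1e-12))
  st2 <- fast_stability(dp2, y = 30, h_scale = 5e-7)
  expect_lt(max(Mod(st$values - st2$values)) / max(Mod(st$values)), 1e-6)
  # long fast-subsystem integration converges to the equilibrium
  eq <- fast_equilibrium(dp2, y = 30)
  ts <- integrate_ode(fast_rhs, c(u = 1, v = 1, x = 50, y = 30), dp2,
                      t_max = 150, dt = 0.01, frame = "dimensionless")
  last <- unlist(as.data.frame(ts)[nrow(ts), c("u", "v", "x")])
  expect_equal(unname(last), unname(eq), tolerance = 1e-4)
})

test_that("fast equilibrium is stable across the sampled parameter box", {
  for (alpha in c(0.5, 2, 6)) for (y in c(alpha / 0.336 + 0.1, 30, 100)) {
    p <- dimless_params(eps = 0.05, alpha = alpha)
    expect_true(fast_stability(p, y)$stable)
  }
})

test_that("critical-manifold points satisfy the algebraic constraint and closed forms", {
  for (y in c(20, 30, 80)) {
    pt <- slow_manifold_point(y, dp2)
    r <- fast_rhs(c(pt, y = y), dp2)
    expect_lt(max(abs(r[1:3])), 1e-10)
    eq <- fast_equilibrium(dp2, y)
    expect_equal(pt[["u"]], eq[["u"]], tolerance = 1e-10)
    expect_equal(pt[["x"]], eq[["x"]], tolerance = 1e-8)
    expect_equal(pt[["v"]], dp2$alpha / (dp2$beta * y - dp2$alpha),
                 tolerance = 1e-8)
  }
})

test_that("slow flow is stationary at the full equilibrium and positive", {
  # slow equation fixed point: omega*v/(1+v) = 1 + sigma2 => v*,
  # then y* from the manifold relation v* = alpha/(beta*y - alpha)
  vstar <- (1 + dp2$sigma2) / (dp2$omega - (1 + dp2$sigma2))
  ystar <- (dp2$alpha / vstar + dp2$alpha) / dp2$beta
  fl <- slow_flow(ystar, dp2, s_max = 1, ds = 1e-2)
  expect_lt(max(abs(fl$y - ystar)), 1e-6)
  fl2 <- slow_flow(40, dp2, s_max = 5, ds = 1e-2)
  expect_true(all(fl2$y > 0))
})

test_that("slow flow is the eps -> 0 limit of the full model's y component", {
  eps <- 1e-3
  p <- dimless_params(eps = eps)
  y0 <- 40
  init <- c(fast_equilibrium(p, y0), y = y0)
  # fast time tau = s/eps: integrate the full model on tau, compare y(s)
  s_max <- 2
  full <- integrate_ode(dimensionless_rhs, init, p, t_max = s_max / eps,
                        dt = 0.05, frame = "dimensionless")
  slow <- slow_flow(y0, p, s_max = s_max, ds = 1e-3)
  for (s in c(0.5, 1, 2)) {
    y_full <- full$y[which.min(abs(full$time - s / eps))]
    y_slow <- slow$y[which.min(abs(slow$time - s))]
    expect_lt(abs(y_full - y_slow), 20 * eps * y0)
  }
})

test_that("stage times match their closed forms", {
  init <- c(u = 0, v = 0, x = 0.05, y = 30)
  st <- stage_times(init, dp2, eps_tol = 0.05)
  expect_equal(st$u_tol, 19)
  expect_equal(st$tau1, 19 / 6, tolerance = 1e-14)
  expect_equal(st$tau2, log(6 / (0.336 * 0.05)) + 19 / 6, tolerance = 1e-12)
  # u0 at u_tol: stage 1 is empty
  st2 <- stage_times(c(u = 19, v = 0, x = 0.05, y = 30), dp2, 0.05)
  expect_equal(st2$tau1, 0)
  # tau1 scales as 1/alpha
  pa <- dimless_params(eps = 0.05, alpha = 12)
  expect_equal(stage_times(init, pa, 0.05)$tau1, st$tau1 / 2)
  expect_error(stage_times(c(u = 0, v = 0, x = 0, y = 30), dp2), "x0 = 0")
  expect_warning(stage_times(c(u = 0, v = 0, x = 30, y = 30), dp2),
                 "degenerate")
})

test_that("staged approximation is exact in stage 1 and exponential in stage 2", {
  init <- c(u = 0, v = 0, x = 0.05, y = 30)
  pw <- piecewise_transient(init, dp2, eps_tol = 0.05, t_max = 15, dt = 0.01)
  st <- pw$stages
  ts <- pw$ts
  i1 <- ts$time < st$tau1
  expect_lt(max(abs(ts$u[i1] - dp2$alpha * ts$time[i1])), 1e-10)
  expect_true(all(ts$v[i1] == 0) && all(ts$x[i1] == init[["x"]]))
  i2 <- ts$time >= st$tau1 & ts$time <= st$tau2
  x_exact <- init[["x"]] * exp((1 - dp2$sigma1) * (ts$time[i2] - st$tau1))
  expect_lt(max(abs(ts$x[i2] - x_exact) / x_exact), 1e-6)
})

test_that("full fast transient peaks between tau1 and 1.5 tau2", {
  init <- c(u = 0, v = 0, x = 0.05, y = 30)
  st <- stage_times(init, dp2, eps_tol = 0.05)
  full <- integrate_ode(fast_rhs, init, dp2, t_max = 20, dt = 0.005,
                        frame = "dimensionless")
  t_peak <- full$time[which.max(full$u)]
  expect_gte(t_peak, st$tau1)
  expect_lte(t_peak, 1.5 * st$tau2)
})
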