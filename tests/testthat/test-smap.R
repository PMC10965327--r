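# geometric series in which every component follows d(t+1) = rho * d(t);
# linear dynamics like this are inside the S-map's hypothesis class
geometric_ts <- function(n, rho = 0.9, start = c(1, 2, 0.5, 1.5), dt = 1) {
  states <- t(vapply(seq_len(n) - 1L, function(i) start * rho^i,
                     numeric(4)))
  ad_ts((seq_len(n) - 1L) * dt, states, "dimensional")
}

# stable diagonal linear map with distinct rates: its trajectory spans all
# four coordinates, so a full library identifies the map exactly
diagonal_ts <- function(n, rates = c(0.9, 0.8, 0.7, 0.6),
                        start = c(1, 2, 0.5, 1.5), dt = 1) {
  states <- t(vapply(seq_len(n) - 1L, function(i) start * rates^i,
                     numeric(4)))
  ad_ts((seq_len(n) - 1L) * dt, states, "dimensional")
}

test_that("weights follow the exponential distance kernel", {
  lib <- smap_library(rbind(c(0, 0), c(1, 0), c(0, 1)), c(0, 1, 1))
  w <- smap_weights(lib, c(0, 0), theta = 5)
  # distances (0, 1, 1), mean 2/3 -> weights (1, e^-7.5, e^-7.5)
  expect_equal(w, c(1, exp(-7.5), exp(-7.5)), tolerance = 1e-12)
  expect_equal(smap_weights(lib, c(0, 0), theta = 0), rep(1, 3))
  # exact match keeps weight 1 for any theta
  expect_equal(smap_weights(lib, c(1, 0), theta = 50)[2], 1)
  expect_true(all(w > 0 & w <= 1))
  expect_error(smap_weights(lib, c(0, 0, 0), 5), "dimension")
})

test_that("one-pair library gives the exact proportional forecast", {
  lib <- smap_library(matrix(2), 6)
  for (q in c(-1, 0.5, 10))
    expect_equal(smap_forecast(lib, q, theta = 5), 3 * q, tolerance = 1e-12)
})

test_that("forecasts are exact for scalar linear dynamics at any theta", {
  set.seed(8)
  for (theta in c(0, 5)) {
    states <- matrix(runif(12, 0.1, 2), 12, 1)
    targets <- 0.7 * states[, 1]
    lib <- smap_library(states, targets)
    q <- runif(1, 0.1, 2)
    expect_equal(smap_forecast(lib, q, theta), 0.7 * q, tolerance = 1e-10)
  }
})

test_that("forecast agrees with a brute-force weighted least-squares oracle", {
  set.seed(99)
  for (rep in 1:100) {
    E <- sample(1:4, 1)
    k <- sample(E:10, 1)  # full column rank almost surely
    states <- matrix(rnorm(k * E), k, E)
    targets <- rnorm(k)
    q <- rnorm(E)
    theta <- runif(1, 0, 8)
    lib <- smap_library(states, targets)
    w <- smap_weights(lib, q, theta)
    # oracle: normal equations of min ||diag(w) (S C - y)||^2
    A <- states * w
    C <- solve(crossprod(A), crossprod(A, w * targets))
    expect_equal(smap_forecast(lib, q, theta), sum(C * q), tolerance = 1e-10)
  }
})

test_that("forecast is invariant to rescaling all weights", {
  # scale cancels in the least-squares solve: theta = 0 vs a query equidistant
  # from all library points (all weights equal but < 1) must agree
  states <- rbind(c(1, 1), c(-1, 1))  # equidistant from the query (0, 1)
  lib <- smap_library(states, c(2, -1))
  q <- c(0, 1)
  expect_equal(smap_forecast(lib, q, theta = 7), 0.5, tolerance = 1e-12)
  expect_equal(smap_forecast(lib, q, theta = 0),
               smap_forecast(lib, q, theta = 7), tolerance = 1e-12)
})

test_that("monitoring forecasts are exact on geometric series for any h", {
  ts <- geometric_ts(30)
  for (h in c(2, 5, 20, 1000)) {
    cfg <- smap_config(theta = 5, h = h)
    fc <- monitoring_forecasts(ts, cfg)
    expect_lt(max(abs(fc$predicted - fc$actual)), 1e-10)
  }
  # h saturating at the series length equals whole-history library
  f1 <- monitoring_forecasts(ts, smap_config(h = 500))
  f2 <- monitoring_forecasts(ts, smap_config(h = 1000))
  expect_identical(f1, f2)
  expect_error(monitoring_forecasts(geometric_ts(2), smap_config()),
               "length >= 3")
})

test_that("monitoring library bookkeeping matches the hand-built oracle", {
  # 6-point series, h = 3, forecasting from j = 5: the library must hold the
  # pairs D(t2)->d*(t3), D(t3)->d*(t4), D(t4)->d*(t5), query D(t5)
  set.seed(21)
  states <- matrix(runif(24), 6, 4)
  ts <- ad_ts(0:5, states, "dimensional")
  cfg <- smap_config(theta = 5, h = 3)
  fc <- monitoring_forecasts(ts, cfg)
  lib <- smap_library(states[2:4, ], states[3:5, 1])
  by_hand <- smap_forecast(lib, states[5, ], theta = 5)
  expect_equal(fc$predicted[fc$time == 5], by_hand, tolerance = 1e-12)
  expect_equal(fc$actual[fc$time == 5], states[6, 1])
})

test_that("control forecasts reuse one library, deterministically", {
  ctrl <- diagonal_ts(25)
  set.seed(4)
  target <- ad_ts(0:19, matrix(runif(80, 0.1, 2), 20, 4), "dimensional")
  cfg <- smap_config(theta = 5)
  f1 <- control_forecasts(ctrl, target, cfg)
  f2 <- control_forecasts(ctrl, target, cfg)
  expect_identical(f1, f2)
  # a control generated by a linear rule forecasts any target exactly
  expect_lt(max(abs(f1$predicted - 0.9 * target$S1[-nrow(target)])), 1e-8)
  bad <- ad_ts(c(0, 0.5, 1), matrix(1, 3, 4), "dimensional")
  expect_error(control_forecasts(ctrl, bad, cfg), "spacing")
})

test_that("control forecasts on linear series are exact in both roles", {
  ctrl <- diagonal_ts(25)
  tgt <- diagonal_ts(15, start = c(3, 1, 2, 0.2))
  fc <- control_forecasts(ctrl, tgt, smap_config(theta = 5))
  expect_lt(max(abs(fc$predicted - fc$actual)), 1e-8)
})
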