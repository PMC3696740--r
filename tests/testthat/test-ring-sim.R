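test_that("winner-take-all bump is stationary in the noise-free field", {
  p <- ring_params(I0 = 0.6, beta = 0, eps = 0, n_grid = 256,
                   dt = 1e-3, t_total = 100)
  s <- simulate_ring(p)
  a <- wta_half_width(0.6, 0, 0.5, 0)
  x <- s$final$x
  u0 <- sin(2 * a) * sin(2 * x) - 0.6 * cos(4 * x)
  # drift away from the analytic profile is limited by grid resolution
  expect_lt(max(abs(s$final$u - u0)), 3 * pi / 256)
  # suppressed side stays subthreshold: exactly one censored record
  expect_equal(nrow(s$records), 1L)
  expect_equal(s$records$percept, "R")
  expect_true(s$records$censored)
})

test_that("rivalrous oscillations alternate with equal noise-free durations", {
  p <- ring_params(I0 = 0.84, beta = 1, tau = 50, eps = 0, n_grid = 256,
                   dt = 1e-3, t_total = 600)
  s <- simulate_ring(p)
  rec <- s$records[!s$records$censored, ]
  expect_gte(nrow(rec), 8)
  expect_true(all(rec$percept[-1] != rec$percept[-nrow(rec)]))
  d <- tail(rec$duration, 6)
  expect_lt(max(d) / min(d) - 1, 0.01)
})

test_that("the fusion state persists from a fusion initial condition", {
  p <- ring_params(I0 = 1, beta = 1, tau = 50, eps = 0, n_grid = 256,
                   dt = 1e-3, t_total = 200)
  s <- simulate_ring(p, init = "fusion")
  # both bumps stay up for the whole run: no dominance is ever assigned
  # (exact tie), and both peaks remain superthreshold
  expect_equal(nrow(s$records), 0L)
  expect_gt(min(s$peaks$peak_R), 0.5)
  expect_gt(min(s$peaks$peak_L), 0.5)
})

test_that("synaptic resources stay in (0, 1] with floor 1/(1+beta)", {
  p <- ring_params(I0 = 0.84, beta = 1, tau = 50, eps = 0, n_grid = 128,
                   dt = 1e-3, t_total = 400)
  s <- simulate_ring(p)
  expect_true(all(s$final$q > 0 & s$final$q <= 1))
  expect_gte(min(s$final$q), 1 / (1 + 1) - 0.02)
})

test_that("noise-free dynamics are deterministic and independent of the seed", {
  p1 <- ring_params(I0 = 0.84, beta = 1, eps = 0, n_grid = 128,
                    dt = 1e-3, t_total = 150, seed = 1)
  p2 <- p1; p2$seed <- 999
  s1 <- simulate_ring(p1); s2 <- simulate_ring(p2)
  expect_identical(s1$peaks, s2$peaks)
})

test_that("halving the timestep leaves noise-free dominance times unchanged", {
  T1 <- ring_period_sim(0.84, n_grid = 256, dt = 1e-3, t_total = 500)
  T2 <- ring_period_sim(0.84, n_grid = 256, dt = 5e-4, t_total = 500)
  expect_lt(abs(T2 / T1 - 1), 0.005)
})

test_that("depression-free noisy field switches dominance stochastically", {
  p <- ring_params(I0 = 0.9, beta = 0, eps = 0.04, n_grid = 256,
                   dt = 1e-3, t_total = 1500, seed = 42)
  s <- simulate_ring(p)
  rec <- s$records[!s$records$censored, ]
  expect_gte(nrow(rec), 2)
  expect_true(all(c("R", "L") %in% c(rec$percept, s$records$percept)))
  # durations vary (exponential-like spread), unlike the clockwork
  # depression-driven case
  expect_gt(stats::sd(rec$duration) / mean(rec$duration), 0.2)
})

test_that("diverging integration aborts with a diagnostic", {
  p <- ring_params(I0 = 0.9, beta = 0, eps = 0, n_grid = 64,
                   dt = 50, t_total = 1e5)
  expect_error(simulate_ring(p), "non-finite")
  expect_error(simulate_ring(ring_params(n_grid = 64),
                             init = list(u = rep(0, 32), q = rep(1, 64))))
})

test_that("snapshots carry the full field at the requested cadence", {
  p <- ring_params(I0 = 0.6, beta = 0, eps = 0, n_grid = 64, dt = 1e-3,
                   t_total = 10)
  s <- simulate_ring(p, snapshot_dt = 5)
  expect_equal(unique(s$snapshots$t), c(0, 5, 10))
  u0 <- s$snapshots$u[s$snapshots$t == 0]
  a <- wta_half_width(0.6, 0, 0.5, 0)
  expect_equal(u0, sin(2 * a) * sin(2 * ring_grid(64)) -
                     0.6 * cos(4 * ring_grid(64)), tolerance = 1e-12)
})
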