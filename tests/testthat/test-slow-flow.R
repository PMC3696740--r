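# Fast-slow (adiabatic) dominance-time theory against noise-free
# simulation.  The theory is leading order in tau_m/tau: agreement
# tightens as tau grows.

test_that("symmetric inputs give exactly equal dominance times, linear in tau", {
  a <- dominance_time_ring(0.84, 0, 0.5, 1, tau = 50)
  expect_true(a$exists)
  expect_identical(a$T_R, a$T_L)
  b <- dominance_time_ring(0.84, 0, 0.5, 1, tau = 100)
  expect_equal(b$T_R / a$T_R, 2, tolerance = 1e-10)
  r50 <- dominance_time_reduced(0.6, 0.6, 1, 50)
  r100 <- dominance_time_reduced(0.6, 0.6, 1, 100)
  expect_equal(r100$T_R / r50$T_R, 2, tolerance = 1e-10)
  t50 <- dominance_time_tristable(0.6, 1, 50)
  t100 <- dominance_time_tristable(0.6, 1, 100)
  expect_equal(t100$T / t50$T, 2, tolerance = 1e-10)
})

test_that("asymmetric formulas reduce continuously to the symmetric case", {
  s <- dominance_time_ring(0.84, 0, 0.5, 1, 50)
  a <- dominance_time_ring(0.84, 1e-9, 0.5, 1, 50)
  expect_equal(a$T_R, s$T_R, tolerance = 1e-5)
  expect_equal(a$T_L, s$T_L, tolerance = 1e-5)
  rs <- dominance_time_reduced(0.6, 0.6, 1, 50)
  ra <- dominance_time_reduced(0.6 + 1e-9, 0.6 - 1e-9, 1, 50)
  expect_equal(ra$T_R, rs$T_R, tolerance = 1e-5)
})

test_that("reduced-network theory converges to simulation as tau grows", {
  sim_T <- function(tau) {
    p <- reduced_params(IR = 0.6, IL = 0.6, beta = 1, tau = tau, eps = 0,
                        t_total = 12 * tau, dt = 1e-4)
    s <- simulate_reduced(p, init = list(u = c(1, 0), q = c(0.7, 0.9)))
    mean(tail(s$records$duration[!s$records$censored], 4))
  }
  th_T <- function(tau) dominance_time_reduced(0.6, 0.6, 1, tau)$T_R
  rel <- vapply(c(50, 200, 400), function(tau) th_T(tau) / sim_T(tau) - 1, 0)
  expect_lt(abs(rel[3]), 0.02)             # tight by tau = 400
  expect_true(all(diff(abs(rel)) < 0))     # error shrinks with tau
})

test_that("ring theory converges to simulation as tau grows", {
  th50 <- dominance_time_ring(0.84, 0, 0.5, 1, 50)$T_R
  th200 <- dominance_time_ring(0.84, 0, 0.5, 1, 200)$T_R
  s50 <- ring_period_sim(0.84, tau = 50, t_total = 700)
  s200 <- ring_period_sim(0.84, tau = 200, t_total = 2200)
  rel50 <- th50 / s50 - 1
  rel200 <- th200 / s200 - 1
  expect_lt(abs(rel50), 0.10)
  expect_lt(abs(rel200), 0.03)
  expect_lt(abs(rel200), abs(rel50))
})

test_that("tristable theory tracks simulation and decreases with input", {
  th <- dominance_time_tristable(0.6, 1, 50)
  p <- tristable_params(I = 0.6, beta = 1, tau = 50, eps = 0,
                        t_total = 1200, dt = 1e-4)
  s <- simulate_tristable(p, init = list(u = c(1, 0, 0), q = c(0.6, 0.8, 1)))
  Ts <- mean(tail(s$records$duration[!s$records$censored], 4))
  expect_lt(abs(th$T / Ts - 1), 0.05)
  Tv <- vapply(c(0.55, 0.6, 0.65, 0.7),
               function(I) dominance_time_tristable(I, 1, 50)$T, 0)
  expect_true(all(diff(Tv) < 0))
})

test_that("Levelt's second proposition: the contralateral time moves most", {
  # ring: raise I_R holding I_L fixed (inside the narrow asymmetric
  # rivalry window at beta = 1)
  IL <- 0.81
  T1 <- dominance_time_ring(I0 = (0.83 + IL) / 2, Ia = (0.83 - IL) / 2,
                            kappa = 0.5, beta = 1, tau = 50)
  T2 <- dominance_time_ring(I0 = (0.85 + IL) / 2, Ia = (0.85 - IL) / 2,
                            kappa = 0.5, beta = 1, tau = 50)
  expect_true(T1$exists && T2$exists)
  dTL <- abs(T2$T_L - T1$T_L)
  dTR <- abs(T2$T_R - T1$T_R)
  expect_gt(dTL, 3 * dTR)
})

test_that("reduced Levelt monotonicity: T_L strictly falls as I_R rises", {
  IL <- 0.58
  IR <- seq(0.55, 0.64, by = 0.01)
  out <- purrr::map_dfr(IR, function(i) dominance_time_reduced(i, IL, 1, 50))
  ok <- out$exists
  expect_gte(sum(ok), 5)
  expect_true(all(diff(out$T_L[ok]) < 0))
})

test_that("out-of-regime points are reported, not fabricated", {
  expect_false(dominance_time_reduced(0.8, 0.8, 1, 50)$exists)  # fusion only
  expect_false(dominance_time_reduced(0.4, 0.4, 1, 50)$exists)  # WTA regime
  expect_false(dominance_time_ring(1.1, 0, 0.5, 1, 50)$exists)
})
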