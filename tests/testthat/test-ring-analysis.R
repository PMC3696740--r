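test_that("root-found bump half-width matches the explicit symmetric formula", {
  withr::with_seed(11, {
    n_ok <- 0
    for (i in 1:100) {
      kap <- runif(1, 0.2, 0.8)
      I0 <- runif(1, kap + 0.05, 1.2)
      beta <- runif(1, 0, 2)
      a_root <- wta_half_width(I0, 0, kap, beta)
      disc <- 1 + 4 * (1 + beta)^2 * (I0^2 - kap^2)
      a_expl <- 0.5 * atan((1 + sqrt(disc)) / (2 * (1 + beta) * (I0 + kap)))
      if (!is.na(a_root)) {
        n_ok <- n_ok + 1
        expect_equal(a_root, a_expl, tolerance = 1e-10)
      }
    }
    expect_gte(n_ok, 80)
  })
})

test_that("half-width satisfies the threshold condition to 1e-10", {
  a <- wta_half_width(0.6, 0, kappa = 0.5, beta = 1)
  resid <- sin(4 * a) / 4 + 0.6 * cos(4 * a) - 0.5
  expect_lt(abs(resid), 1e-10)
})

test_that("no bump is reported when the discriminant is negative", {
  # I0 < kappa with 1 + 4(1+beta)^2 (I0^2 - kappa^2) < 0
  expect_true(is.na(wta_half_width(0.3, 0, kappa = 0.5, beta = 2)))
  expect_false(wta_exists(0.3, 0, kappa = 0.5, beta = 2)$exists)
})

test_that("winner-take-all existence flips between the regime anchors", {
  w1 <- wta_exists(0.6, 0, kappa = 0.5, beta = 1)
  w2 <- wta_exists(0.84, 0, kappa = 0.5, beta = 1)
  expect_true(w1$exists); expect_gt(w1$margin, 0)
  expect_false(w2$exists); expect_lt(w2$margin, 0)
})

test_that("fusion half-widths: symmetric closed form and Newton agree with a grid oracle", {
  fh <- fusion_half_widths(1, 0, kappa = 0.5, beta = 1)
  expect_true(fh$exists)
  expect_equal(fh$a, fh$b)
  expect_equal(fh$a, acos(0.5) / 4, tolerance = 1e-12)
  expect_lt(max(abs(c(fh$residual_a, fh$residual_b))), 1e-10)

  fh2 <- fusion_half_widths(1, 0.03, kappa = 0.5, beta = 1)
  expect_true(fh2$exists)
  expect_lt(max(abs(c(fh2$residual_a, fh2$residual_b))), 1e-9)
  # brute-force 2-D grid oracle
  Fab <- function(a, b) {
    D <- (sin(2 * a) - sin(2 * b)) / 2 + 0.03
    abs(D * cos(2 * a) + cos(4 * a) - 0.5) +
      abs(-D * cos(2 * b) + cos(4 * b) - 0.5)
  }
  g <- seq(0.05, pi / 4 - 0.05, length.out = 300)
  val <- outer(g, g, Fab)
  i <- which(val == min(val), arr.ind = TRUE)[1, ]
  expect_lt(abs(g[i[1]] - fh2$a), 5e-3)
  expect_lt(abs(g[i[2]] - fh2$b), 5e-3)
})

test_that("pre-switch resources match the defining threshold/escape system", {
  withr::with_seed(21, {
    n_ok <- 0
    for (i in 1:40) {
      kap <- runif(1, 0.3, 0.6)
      I0 <- runif(1, kap + 0.1, 1.1)
      Ia <- runif(1, 0, 0.04)
      ps <- pre_switch_resources(I0, Ia, kap)
      # right bump at its suppression (left escapes): side input -Ia
      or_R <- pre_switch_oracle(I0, Ia, kap)
      or_L <- pre_switch_oracle(I0, -Ia, kap)
      if (is.null(or_R) || is.null(or_L)) next
      n_ok <- n_ok + 1
      expect_equal(ps$qR, or_R$q, tolerance = 1e-8)
      expect_equal(ps$qL, or_L$q, tolerance = 1e-8)
      expect_equal(ps$a0, or_R$a, tolerance = 1e-8)
    }
    expect_gte(n_ok, 25)
  })
})

test_that("pre-switch resources: symmetric reduction and rivalry bounds", {
  ps <- pre_switch_resources(0.84, 0, 0.5)
  expect_equal(ps$qR, ps$q0)
  expect_equal(ps$qL, ps$q0)
  # q0 within (1/(1+beta), 1) at the rivalry anchor point, beta = 1
  expect_gt(ps$q0, 0.5)
  expect_lt(ps$q0, 1)
})

test_that("regime partition reproduces the three anchor behaviors", {
  g <- regime_partition(beta = 1, I0 = c(0.6, 0.84, 1.0), kappa = 0.5)
  expect_equal(g$label, c("winner_take_all", "rivalry", "fusion"))
  # a quiescent point below threshold
  g0 <- regime_partition(beta = 1, I0 = 0.2, kappa = 0.5)
  expect_equal(g0$label, "no_active_state")
})

test_that("rivalry band widens and winner-take-all narrows with stronger depression", {
  I0 <- seq(0.5, 1.1, by = 0.02)
  g_lo <- regime_partition(beta = 0.5, I0 = I0, kappa = 0.5)
  g_hi <- regime_partition(beta = 1.0, I0 = I0, kappa = 0.5)
  expect_gt(sum(g_hi$label == "rivalry"), sum(g_lo$label == "rivalry"))
  expect_lt(sum(g_hi$label == "winner_take_all"),
            sum(g_lo$label == "winner_take_all"))
})
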