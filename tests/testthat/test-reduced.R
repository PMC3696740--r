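test_that("symmetric noise-free network alternates with equal durations", {
  p <- reduced_params(IR = 0.6, IL = 0.6, beta = 1, tau = 50, eps = 0,
                      t_total = 600)
  s <- simulate_reduced(p, init = list(u = c(1, 0), q = c(0.7, 0.9)))
  rec <- s$records[!s$records$censored, ]
  expect_gte(nrow(rec), 8)
  expect_true(all(rec$percept[-1] != rec$percept[-nrow(rec)]))
  d <- tail(rec$duration, 6)
  expect_lt(max(d) / min(d) - 1, 0.01)
})

test_that("weak contralateral input gives winner-take-all", {
  # I_L < 1/(1+beta) = 0.5 cannot escape
  p <- reduced_params(IR = 0.6, IL = 0.3, beta = 1, tau = 50, eps = 0,
                      t_total = 400)
  s <- simulate_reduced(p, init = list(u = c(1, 0), q = c(0.8, 1)))
  expect_equal(unique(s$records$percept), "R")
  expect_gt(tail(s$trajectory$uR, 1), 0.95)
  expect_lt(tail(s$trajectory$uL, 1), 0.05)
})

test_that("depression + noise: stronger input dominates longer on average", {
  p <- reduced_params(IR = 0.82, IL = 0.78, beta = 0.2, tau = 50,
                      eps = 0.036, t_total = 6000, seed = 3)
  s <- simulate_reduced(p)
  rec <- s$records[!s$records$censored, ]
  expect_gte(nrow(rec), 40)
  expect_gt(mean(rec$duration[rec$percept == "R"]),
            mean(rec$duration[rec$percept == "L"]))
})

test_that("symmetric stochastic runs balance within Monte-Carlo error", {
  p <- reduced_params(IR = 0.6, IL = 0.6, beta = 1, tau = 50,
                      eps = 0.02, t_total = 8000, seed = 4)
  s <- simulate_reduced(p)
  rec <- s$records[!s$records$censored, ]
  dR <- rec$duration[rec$percept == "R"]
  dL <- rec$duration[rec$percept == "L"]
  se <- sqrt(stats::var(dR) / length(dR) + stats::var(dL) / length(dL))
  expect_lt(abs(mean(dR) - mean(dL)), 3 * se)
})

test_that("fixed-point regime labels follow the Heaviside inequalities", {
  expect_equal(fixed_point_regimes(0.6, 0.3, beta = 1)$label,
               "winner_take_all")
  expect_true(fixed_point_regimes(0.6, 0.3, beta = 1)$wta_right)
  expect_equal(fixed_point_regimes(0.8, 0.8, beta = 1)$label, "fusion_only")
  r <- fixed_point_regimes(0.6, 0.6, beta = 1)
  expect_equal(r$label, "rivalry")
  expect_true(r$fusion_fp)   # fusion fixed point coexists
  # oscillation boundary: present at 0.63, gone by 0.70 (= past 2/(2+beta))
  expect_true(fixed_point_regimes(0.63, 0.63, beta = 1)$oscillation)
  expect_false(fixed_point_regimes(0.70, 0.70, beta = 1)$oscillation)
  expect_equal(fixed_point_regimes(-0.1, -0.1, beta = 1)$label, "quiescent")
})

test_that("energy and gaps match hand-evaluated cases", {
  # right-dominant with suppressed left: E = -I_R q_L
  e <- energy(uR = 1, uL = 0, qR = 0.9, qL = 0.8, IR = 0.82, IL = 0.78)
  expect_equal(e$E, -0.82 * 0.8)
  expect_equal(e$dE_R, 1 - 0.78 * 0.9)
  expect_equal(energy(1, 0, qR = 1, qL = 1, IR = 0.9, IL = 0.78)$dE_R, 0.22)
  # beta = 0 limit (q = 1) reduces to the depression-free energy
  u <- c(0.2, 0.9)
  e0 <- energy(u[1], u[2], 1, 1, IR = 0.7, IL = 0.6)
  H <- function(z) as.numeric(z >= 0)
  E_ref <- H(0.6 - u[1]) * H(0.7 - u[2]) -
    0.6 * H(0.6 - u[1]) - 0.7 * H(0.7 - u[2])
  expect_equal(e0$E, E_ref)
  # gap falls as the opposing input rises
  g <- energy(1, 0, 0.9, 0.9, IR = 0.8, IL = c(0.6, 0.7, 0.8))
  expect_true(all(diff(g$dE_R) < 0))
})
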