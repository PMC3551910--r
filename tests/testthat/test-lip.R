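test_that("the LIP rate is anchored at the bound and clamped at the floor", {
  lip <- lip_params(bound_rate = 70, gain = 100, floor = 0)
  expect_equal(lip_rate(0.8, 0.8, lip), 70)        # at threshold: bound rate
  expect_equal(lip_rate(0.9, 0.8, lip), 80)
  expect_equal(lip_rate(0.5, 0.9, lip), 30)
  lip0 <- lip_params(bound_rate = 70, gain = 0)
  expect_equal(lip_rate(c(0.1, 0.5, 0.9), rep(0.7, 3), lip0), rep(70, 3))
  lipf <- lip_params(bound_rate = 70, gain = 100, floor = 25)
  expect_equal(lip_rate(0.5, 1.0, lipf), 25)       # clamped
  expect_error(lip_rate(0.6, NA_real_, lip), "finite")
})

test_that("the urgency signal is the image of the collapsing boundary", {
  sol <- default_test_policy()
  lip <- lip_params()
  u <- urgency_signal(sol, lip)
  # algebraic identity: rate - B = gain * (1/2 - theta_R)
  expect_equal(u$signal$rate - lip$bound_rate,
               lip$gain * (0.5 - u$signal$theta_right), tolerance = 1e-12)
  # urgency is non-decreasing wherever the lattice boundary is non-increasing,
  # and stays below the bound until the boundary fully collapses
  falling <- diff(u$signal$theta_right) <= 0
  expect_true(all(diff(u$signal$rate)[falling] >= 0))
  expect_true(all(u$signal$rate <= lip$bound_rate))
  expect_false(u$degenerate)
})

test_that("urgency fitting recovers a synthetically imposed hyperbolic boundary", {
  fake <- synthetic_hyperbolic_solution(a = 0.4, tau = 30)
  lip <- lip_params()
  u <- urgency_signal(fake, lip)
  expect_equal(u$fit$half_time, 30, tolerance = 0.01)
  expect_equal(u$fit$amplitude_rate, lip$gain * 0.4, tolerance = 0.01 * 40)
  # fully collapsed boundary: urgency equals the bound, fit flagged degenerate
  flat <- synthetic_hyperbolic_solution(a = 0, tau = 30)
  uf <- urgency_signal(flat, lip)
  expect_true(all(uf$signal$rate == lip$bound_rate))
  expect_true(uf$degenerate)
})

test_that("LIP bound crossing is the policy's rightward decision, bit-exactly", {
  sol <- default_test_policy()
  mt <- mt_params()
  lip <- lip_params()
  seeds <- trial_seeds(2024, 300)
  cohs <- rep(c(0, 0.064, 0.256), each = 100)
  for (i in seq_along(seeds)) {
    tr <- simulate_trial(cohs[i], "right", sol, mt, seed = seeds[i])
    rates <- trial_lip_rates(tr, sol, lip)
    hit <- which(rates$rate_right >= lip$bound_rate)[1]
    if (tr$choice == "right" && !tr$truncated) {
      expect_identical(hit, tr$decision_step)
    } else {
      expect_true(is.na(hit) || hit > tr$decision_step)
    }
    if (tr$choice == "left" && !tr$truncated) {
      hit_l <- which(rates$rate_left >= lip$bound_rate)[1]
      expect_identical(hit_l, tr$decision_step)
    }
  }
})

test_that("buildup slope extraction recovers constructed linear trajectories", {
  # constructed trajectories with known slopes 1, 2, 3 per unit coherence
  steps <- 5:22
  cohs <- c(0.1, 0.2, 0.3)
  profiles <- lapply(1:3, function(k) 20 + k * (steps - steps[1]))
  reg <- buildup_regression(profiles, cohs, steps)
  expect_equal(reg$slopes, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(reg$slope_per_pct, 1 / 10, tolerance = 0.02 / 10)
})

test_that("buildup rates reduce to the urgency signal and to zero gain", {
  sol <- default_test_policy()
  mt <- mt_params()
  # zero gain: every trajectory is flat at the bound rate
  b0 <- buildup_rates(sol, mt, lip_params(gain = 0), coherences = c(0, 0.256),
                      n_trials = 200, seed = 3)
  expect_equal(b0$slopes$slope, c(0, 0), tolerance = 1e-12)
  # with a gain that never engages the rate floor, the exact
  # survivor-conditioned buildup at c = 0 equals the urgency slope: the
  # surviving evidence distribution is symmetric, so its mean ratio is 1/2
  lip <- lip_params(gain = 60)
  ba <- buildup_rates(sol, mt, lip, coherences = c(0, 0.128, 0.512),
                      method = "analytic")
  u <- urgency_signal(sol, lip)
  window <- ba$window_steps
  urate <- u$signal$rate[match(window, u$signal$t)]
  uslope <- unname(coef(lm(urate ~ window))[2])
  expect_equal(ba$slopes$slope[1], uslope, tolerance = 1e-10)
  # every early trajectory rises (urgency dominates the read-out early on)
  expect_true(all(ba$slopes$slope > 0))
  expect_true(is.finite(ba$regression$slope_per_pct))
})

test_that("simulated buildup converges to the analytic profile", {
  sol <- default_test_policy()
  mt <- mt_params()
  lip <- lip_params(gain = 60)
  bs <- buildup_rates(sol, mt, lip, coherences = c(0, 0.256),
                      n_trials = 4000, seed = 17, method = "simulation")
  ba <- buildup_rates(sol, mt, lip, coherences = c(0, 0.256),
                      method = "analytic")
  expect_equal(bs$slopes$slope, ba$slopes$slope, tolerance = 0.15)
})
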