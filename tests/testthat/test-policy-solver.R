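test_that("predictive observation probabilities are beta-binomial", {
  expect_equal(predictive_obs_prob(belief_state(1, 1), 1, 1), 0.5)
  expect_equal(predictive_obs_prob(belief_state(2, 1), 1, 1), 2 / 3)
  expect_equal(predictive_obs_prob(belief_state(1, 1), 0:2, 2), rep(1 / 3, 3))
  for (ab in list(c(3, 2), c(10, 4)))
    expect_equal(sum(predictive_obs_prob(belief_state(ab[1], ab[2]), 0:5, 5)),
                 1, tolerance = 1e-12)
  expect_error(predictive_obs_prob(belief_state(1, 1), 3, 2), "z")
})

test_that("expected rewards follow the belief and the reward structure", {
  r <- reward_params(-0.01, 10, -10)
  expect_equal(expected_reward(belief_state(1, 1), "right", r), 0)
  expect_equal(expected_reward(belief_state(2, 1), "right",
                               reward_params(-1, 1, 0)), 0.75)
  expect_equal(expected_reward(belief_state(5, 2), "sample", r, N = 1), -0.01)
  expect_equal(expected_reward(belief_state(5, 2), "sample", r, N = 4), -0.04)
  # right and left values are complementary in the posterior
  b <- belief_state(7, 3)
  expect_equal(expected_reward(b, "right", r) + expected_reward(b, "left", r),
               r$reward_correct + r$reward_error, tolerance = 1e-12)
  expect_error(expected_reward(b, "up", r), "action")
})

test_that("belief transitions: sampling branches, terminal actions absorb", {
  tr <- belief_transition(belief_state(1, 1), "sample", N = 1)
  expect_false(tr$absorbing)
  expect_equal(tr$prob, c(0.5, 0.5))
  expect_equal(tr$alpha, c(1, 2))
  expect_equal(tr$beta, c(2, 1))
  expect_true(belief_transition(belief_state(3, 2), "right")$absorbing)
  expect_true(belief_transition(belief_state(3, 2), "left")$absorbing)
  # composition: one N = 2 step equals two chained N = 1 steps marginalized
  b <- belief_state(3, 2)
  one <- belief_transition(b, "sample", N = 2)
  two <- numeric(3)  # probability of ending at alpha + z for z = 0, 1, 2
  first <- belief_transition(b, "sample", N = 1)
  for (i in 1:2) {
    second <- belief_transition(belief_state(first$alpha[i], first$beta[i]),
                                "sample", N = 1)
    for (j in 1:2) {
      z_tot <- (i - 1) + (j - 1)
      two[z_tot + 1] <- two[z_tot + 1] + first$prob[i] * second$prob[j]
    }
  }
  expect_equal(one$prob, two, tolerance = 1e-14)
})

test_that("backward induction matches exhaustive tree enumeration", {
  for (rw in list(reward_params(-1, 20, -20), reward_params(-0.5, 8, -2))) {
    horizon <- 3L
    sol <- solve_policy(rw, horizon = horizon, check_stationarity = FALSE)
    for (t in 0:horizon) {
      for (n in 0:t) {
        o <- oracle_node(t, n, horizon, rw)
        expect_equal(sol$value[[t + 1]][n + 1], o$value, tolerance = 1e-12)
        expect_true(policy_action(sol, t, n) %in% o$optimal)
      }
    }
  }
})

test_that("a prohibitive sampling cost makes the policy decide immediately", {
  # sampling can never pay when its cost exceeds the best possible gain
  rw <- reward_params(-25, 10, -10)
  sol <- solve_policy(rw, horizon = 3)
  expect_equal(policy_action(sol, 0, 0), "right")  # tie broken right
  expect_equal(sol$theta_right[1], 0.5)
  o <- oracle_node(0, 0, 3, rw)
  expect_equal(sol$value[[1]][1], o$value, tolerance = 1e-12)
  expect_false("sample" %in% o$optimal)
  fp <- first_passage(sol, 0.7)
  expect_equal(fp$h_right[1], 1)
  expect_equal(fp$mean_rt_right, 0)
})

test_that("symmetric rewards give a mirror-symmetric value table and boundaries", {
  sol <- default_test_policy()
  for (t in c(0, 1, 7, 50, 200, 400)) {
    v <- sol$value[[t + 1]]
    expect_equal(v, rev(v), tolerance = 1e-12)
  }
  # boundary mirror, within the certified stationary range (rows beyond it
  # are shaped by the horizon truncation, where the sampling region vanishes
  # and the midline tie shifts the split by one cell)
  def <- which(!is.na(sol$k_right) & !is.na(sol$k_left)) - 1L
  def <- def[def >= 1L & def <= sol$certified_t]
  t_def <- def
  i <- def + 1L
  expect_identical(sol$k_left[i], sol$N * t_def - sol$k_right[i])
  expect_equal(sol$theta_left[i], 1 - sol$theta_right[i], tolerance = 1e-12)
})

test_that("the default decision boundary collapses and the regions are contiguous", {
  sol <- default_test_policy()
  expect_true(sol$converged)
  t_def <- which(!is.na(sol$theta_right)) - 1L
  t_def <- t_def[t_def >= 1L & t_def <= sol$certified_t]
  th <- sol$theta_right[t_def + 1L]
  k <- sol$k_right[t_def + 1L]
  expect_true(all(th > 0.5))
  # the count threshold never decreases, so the exact ratio boundary k/t can
  # tick up by at most one lattice cell, (t - k)/(t (t + 1)), when k increments
  expect_true(all(diff(k) >= 0))
  up <- diff(th)
  bound <- (t_def - k) / (t_def * (t_def + 1))
  expect_true(all(up <= bound[-length(bound)] + 1e-15))
  # the boundary collapses: its lower envelope falls monotonically to ~1/2
  env <- cummin(th)
  expect_lt(env[length(env)], 0.51)
  expect_gt(th[1], 0.9)
  # each lattice row is left-region, then sampling, then right-region
  for (t in c(3, 10, 60, 250)) {
    a <- vapply(0:t, function(n) policy_action(sol, t, n), character(1))
    code <- c(left = 1L, sample = 2L, right = 3L)[a]
    expect_true(all(diff(code) >= 0))
  }
})

test_that("policies are invariant to the overall reward scale", {
  base <- solve_policy(reward_params(-1, 200, -200), horizon = 200,
                       check_stationarity = FALSE)
  for (lam in c(0.1, 10)) {
    scaled <- solve_policy(reward_params(-1 * lam, 200 * lam, -200 * lam),
                           horizon = 200, check_stationarity = FALSE)
    expect_identical(scaled$action, base$action)
    for (t in c(0, 50, 150))
      expect_equal(scaled$value[[t + 1]], lam * base$value[[t + 1]],
                   tolerance = 1e-10)
  }
})

test_that("richer rewards never shrink the sampling region", {
  lo <- solve_policy(reward_params(-1, 100, -100), horizon = 200,
                     check_stationarity = FALSE)
  hi <- solve_policy(reward_params(-1, 300, -300), horizon = 200,
                     check_stationarity = FALSE)
  for (t in 1:160) {
    k_lo <- lo$k_right[t + 1]
    k_hi <- hi$k_right[t + 1]
    if (!is.na(k_hi)) {
      expect_false(is.na(k_lo))
      expect_gte(k_hi, k_lo)
    }
    l_lo <- lo$k_left[t + 1]
    l_hi <- hi$k_left[t + 1]
    if (!is.na(l_hi)) expect_lte(l_hi, l_lo)
  }
})

test_that("coarser observation granularity approximates but does not equal N = 1", {
  # the belief transition composes exactly across granularities (see the
  # composition test), but the coarse agent has fewer stopping opportunities:
  # its value is dominated by the fine agent's and its actions differ only
  # in cells adjacent to the decision boundary
  s1 <- solve_policy(reward_params(-1, 200, -200), N = 1, horizon = 250,
                     check_stationarity = FALSE)
  s5 <- solve_policy(reward_params(-1, 200, -200), N = 5, horizon = 50,
                     check_stationarity = FALSE)
  worst_gap <- 0
  for (t in 0:40) {
    v5 <- s5$value[[t + 1]]
    v1 <- s1$value[[5 * t + 1]]
    a5 <- s5$action[[t + 1]]
    a1 <- s1$action[[5 * t + 1]]
    expect_true(all(v5 <= v1 + 1e-9))  # dominance
    mm <- which(a5 != a1) - 1L
    if (length(mm)) {
      k_r <- s1$k_right[5 * t + 1]
      k_l <- s1$k_left[5 * t + 1]
      near <- (!is.na(k_r) & abs(mm - k_r) <= 5) |
        (!is.na(k_l) & abs(mm - k_l) <= 5)
      expect_true(all(near))
    }
    worst_gap <- max(worst_gap, max(v1 - v5))
  }
  expect_gt(worst_gap, 0)  # strictly coarser: mid-block stops have value
})

test_that("an insufficient horizon is reported, not thrown", {
  sol <- solve_policy(reward_params(-1, 200, -200), horizon = 40)
  expect_false(sol$converged)
  expect_error(first_passage(sol, 0.5), "not certified")
})

test_that("hyperbolic boundary fits round-trip and flag degeneracy", {
  t <- 5:150
  for (par in list(c(0.4, 30), c(0.25, 80))) {
    theta <- 0.5 + par[1] * par[2] / (t + par[2])
    fit <- fit_hyperbolic_boundary(theta, t)
    expect_false(fit$degenerate)
    expect_equal(fit$amplitude, par[1], tolerance = 0.01)
    expect_equal(fit$half_time, par[2], tolerance = 0.01)
    expect_lt(fit$residual, 1e-6)
  }
  flat <- fit_hyperbolic_boundary(rep(0.5, 20), 1:20)
  expect_true(flat$degenerate)
  expect_error(fit_hyperbolic_boundary(c(0.9, 0.8, 0.7), 1:3), "at least 5")
})

test_that("boundary half-time grows with the reward ratio", {
  horizons <- c(`100` = 400L, `200` = 500L, `400` = 1000L)
  taus <- vapply(c(100, 200, 400), function(R) {
    sol <- solve_policy(reward_params(-1, R, -R),
                        horizon = horizons[[as.character(R)]])
    expect_true(sol$converged)
    b <- extract_boundaries(sol)
    fit_hyperbolic_boundary(b$theta_right, b$t)$half_time
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})
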