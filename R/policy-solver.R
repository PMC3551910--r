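# Action codes used throughout the solver and simulator:
# 1 = sample (wait for one more observation), 2 = go right, 3 = go left.
ACTIONS <- c("sample", "right", "left")

#' Predictive distribution of the next observation
#'
#' The probability of observing z rightward spikes out of the next N, given
#' the current beta belief: the beta-binomial predictive, i.e. the binomial
#' likelihood averaged over the posterior. It is stationary (depends on the
#' belief only, not on elapsed time). Computed in log space via `lbeta`.
#'
#' @param b A [belief_state()].
#' @param z Integer count(s) in \[0, N\].
#' @param N Total spikes in the step.
#' @return Predictive probability (vectorized over `z`).
#' @examples
#' predictive_obs_prob(belief_state(1, 1), 0:2, 2)  # uniform: 1/3 each
#' @export
predictive_obs_prob <- function(b, z, N) {
  stopifnot(inherits(b, "belief_state"))
  N <- as.integer(N)
  if (any(z != floor(z)) || any(z < 0L) || any(z > N))
    stop("`z` must be integer(s) in [0, N]", call. = FALSE)
  beta_binom_pmf(z, N, b$alpha, b$beta)
}

# internal vectorized beta-binomial pmf
beta_binom_pmf <- function(z, N, alpha, beta) {
  exp(lchoose(N, z) + lbeta(alpha + z, beta + N - z) - lbeta(alpha, beta))
}

#' Expected immediate reward of an action at a belief
#'
#' Sampling costs `N * sample_cost` regardless of the belief. Choosing right
#' earns `reward_correct` with probability P(p > 1/2 | b) and `reward_error`
#' otherwise; choosing left is the mirror image.
#'
#' @param b A [belief_state()].
#' @param action One of `"sample"`, `"right"`, `"left"`.
#' @param reward A [reward_params()] object.
#' @param N Spikes per step (scales the sampling cost).
#' @return Expected immediate reward.
#' @export
expected_reward <- function(b, action, reward, N = 1L) {
  stopifnot(inherits(b, "belief_state"), inherits(reward, "reward_params"))
  if (!is.character(action) || length(action) != 1L || !action %in% ACTIONS)
    stop('`action` must be one of "sample", "right", "left"', call. = FALSE)
  if (action == "sample") return(as.integer(N) * reward$sample_cost)
  pr <- prob_direction_right(b)
  if (action == "right")
    reward$reward_correct * pr + reward$reward_error * (1 - pr)
  else
    reward$reward_correct * (1 - pr) + reward$reward_error * pr
}

#' Belief-MDP transition distribution
#'
#' Under the sampling action the belief moves to one of the N + 1 conjugate
#' updates, weighted by the beta-binomial predictive probability of the
#' corresponding observation. Under either terminal action the process moves
#' to the absorbing (end-of-trial) state with probability 1.
#'
#' @inheritParams expected_reward
#' @param N Spikes per step.
#' @return A list with `action`, `absorbing` (logical), and for sampling
#'   transitions vectors `z`, `alpha`, `beta`, `prob` describing the
#'   successor beliefs.
#' @export
belief_transition <- function(b, action, N = 1L) {
  stopifnot(inherits(b, "belief_state"))
  if (!is.character(action) || length(action) != 1L || !action %in% ACTIONS)
    stop('`action` must be one of "sample", "right", "left"', call. = FALSE)
  N <- as.integer(N)
  if (action != "sample")
    return(list(action = action, absorbing = TRUE, prob = 1))
  z <- 0:N
  list(action = "sample", absorbing = FALSE, z = z,
       alpha = b$alpha + z, beta = b$beta + (N - z),
       prob = beta_binom_pmf(z, N, b$alpha, b$beta))
}

# internal: one backward-induction pass over the (t, n_right) lattice.
# Returns ragged value/action tables (lists indexed t + 1, vectors over
# n_right = 0..N*t) and integer count thresholds k_right/k_left per step.
#
# For a symmetric prior, P(rightward | n) is computed as the mirrored left
# tail pbeta(1/2, beta, alpha) evaluated once per row and reversed, which
# makes the terminal reward rows bitwise mirror-symmetric.
solve_backward <- function(reward, prior, N, horizon) {
  Tmax <- horizon
  a0 <- prior$alpha0
  b0 <- prior$beta0
  Rp <- reward$reward_correct
  Rm <- reward$reward_error
  cs <- reward$sample_cost
  value <- vector("list", Tmax + 1L)
  action <- vector("list", Tmax + 1L)
  k_right <- rep(NA_integer_, Tmax + 1L)
  k_left <- rep(NA_integer_, Tmax + 1L)
  for (t in Tmax:0) {
    n <- 0:(N * t)
    alpha <- a0 + n
    beta <- b0 + (N * t - n)
    low <- stats::pbeta(0.5, alpha, beta)     # P(p < 1/2 | n)
    pr <- if (a0 == b0) rev(low) else 1 - low # P(p > 1/2 | n)
    r_right <- Rp * pr + Rm * (1 - pr)
    r_left <- Rp * (1 - pr) + Rm * pr
    r_term <- pmax(r_right, r_left)
    if (t < Tmax) {
      v_next <- value[[t + 2L]]
      if (N == 1L) {
        w1 <- alpha / (alpha + beta)
        q <- cs + (1 - w1) * v_next[n + 1L] + w1 * v_next[n + 2L]
      } else {
        q <- rep(N * cs, length(n))
        lb0 <- lbeta(alpha, beta)
        for (z in 0:N) {
          w <- exp(lchoose(N, z) + lbeta(alpha + z, beta + N - z) - lb0)
          q <- q + w * v_next[n + z + 1L]
        }
      }
      # tie-breaks: sample over terminal, right over left
      a <- ifelse(q >= r_term, 1L, ifelse(r_right >= r_left, 2L, 3L))
      v <- pmax(q, r_term)
    } else {
      a <- ifelse(r_right >= r_left, 2L, 3L)
      v <- r_term
    }
    if (any(!is.finite(v)))
      stop("non-finite value encountered in backward induction", call. = FALSE)
    value[[t + 1L]] <- v
    action[[t + 1L]] <- a
    i_r <- which(a == 2L)
    i_l <- which(a == 3L)
    k_right[t + 1L] <- if (length(i_r)) min(i_r) - 1L else NA_integer_
    k_left[t + 1L] <- if (length(i_l)) max(i_l) - 1L else NA_integer_
  }
  list(value = value, action = action, k_right = k_right, k_left = k_left)
}

#' Solve the belief MDP by backward induction
#'
#' Converts the task POMDP into a Markov decision process on the exact integer
#' evidence lattice (t, n_right) — the beta family is closed under binomial
#' observations, so the lattice is exhaustive and there is no discretization
#' error — and solves Bellman's equation by backward induction from a finite
#' horizon. At the horizon sampling is disallowed and the value is the best
#' terminal reward.
#'
#' The stationary infinite-horizon solution is approximated controllably:
#' when `check_stationarity = TRUE` the problem is re-solved at horizon
#' `ceiling(1.25 * horizon)` and the policy is certified as converged if the
#' decision boundaries for `t <= 0.8 * horizon` agree exactly (integer lattice
#' thresholds, no epsilon). Value ties are broken deterministically: sampling
#' over stopping (except at the horizon), right over left.
#'
#' @param reward A [reward_params()] object.
#' @param prior A [prior_params()] object; the task model assumes a symmetric
#'   prior.
#' @param N Spikes per step (observation granularity).
#' @param horizon Maximum number of steps T_max.
#' @param check_stationarity Certify boundary stationarity by re-solving at a
#'   25% longer horizon (doubles the solve cost).
#' @return An object of class `policy_solution` with ragged `value` and
#'   `action` tables (lists indexed by `t + 1`), integer count thresholds
#'   `k_right`/`k_left`, ratio boundaries `theta_right`/`theta_left`,
#'   `converged`, and `certified_t` (the step up to which stationarity was
#'   certified).
#' @examples
#' sol <- solve_policy(reward_params(-1, 200, -200), horizon = 200)
#' sol$converged
#' head(extract_boundaries(sol))
#' @export
solve_policy <- function(reward, prior = prior_params(), N = 1L,
                         horizon = 500L, check_stationarity = TRUE) {
  stopifnot(inherits(reward, "reward_params"), inherits(prior, "prior_params"))
  N <- as.integer(N)
  horizon <- as.integer(horizon)
  if (is.na(N) || N < 1L) stop("`N` must be an integer >= 1", call. = FALSE)
  if (is.na(horizon) || horizon < 1L)
    stop("`horizon` must be an integer >= 1", call. = FALSE)
  base <- solve_backward(reward, prior, N, horizon)
  converged <- NA
  certified_t <- NA_integer_
  if (check_stationarity) {
    certified_t <- as.integer(floor(0.8 * horizon))
    longer <- solve_backward(reward, prior, N,
                             as.integer(ceiling(1.25 * horizon)))
    idx <- seq_len(certified_t + 1L)
    converged <- identical(base$k_right[idx], longer$k_right[idx]) &&
      identical(base$k_left[idx], longer$k_left[idx])
  }
  t_all <- 0:horizon
  denom <- pmax(1L, N * t_all)
  theta_right <- ifelse(is.na(base$k_right), NA_real_, base$k_right / denom)
  theta_left <- ifelse(is.na(base$k_left), NA_real_, base$k_left / denom)
  # at t = 0 the point estimate is 1/2 by convention
  if (!is.na(base$k_right[1L])) theta_right[1L] <- 0.5
  if (!is.na(base$k_left[1L])) theta_left[1L] <- 0.5
  structure(list(horizon = horizon, N = N, reward = reward, prior = prior,
                 value = base$value, action = base$action,
                 k_right = base$k_right, k_left = base$k_left,
                 theta_right = theta_right, theta_left = theta_left,
                 converged = converged, certified_t = certified_t),
            class = "policy_solution")
}

#' @export
print.policy_solution <- function(x, ...) {
  cat("Belief-MDP policy solution\n")
  cat(sprintf("  horizon  : %d steps, N = %d spike(s)/step\n", x$horizon, x$N))
  cat(sprintf("  rewards  : c_s = %g/spike, R+ = %g, R- = %g\n",
              x$reward$sample_cost, x$reward$reward_correct,
              x$reward$reward_error))
  t_def <- which(!is.na(x$theta_right)) - 1L
  if (length(t_def)) {
    cat(sprintf("  boundary : theta_R defined for t in [%d, %d], from %.3f down to %.3f\n",
                min(t_def), max(t_def),
                max(x$theta_right, na.rm = TRUE),
                x$theta_right[max(t_def) + 1L]))
  } else cat("  boundary : no terminal region (policy always samples)\n")
  conv <- if (isTRUE(x$converged)) sprintf("yes (certified for t <= %d)", x$certified_t)
          else if (identical(x$converged, FALSE)) "NO (horizon too small)"
          else "not checked"
  cat(sprintf("  converged: %s\n", conv))
  invisible(x)
}

#' Action prescribed by a solved policy at a lattice point
#'
#' @param sol A [solve_policy()] solution.
#' @param t Step index, 0 <= t <= horizon.
#' @param n_right Rightward spike count, 0 <= n_right <= N * t.
#' @return One of `"sample"`, `"right"`, `"left"`.
#' @export
policy_action <- function(sol, t, n_right) {
  stopifnot(inherits(sol, "policy_solution"))
  if (t < 0 || t > sol$horizon) stop("`t` out of range", call. = FALSE)
  if (n_right < 0 || n_right > sol$N * t)
    stop("`n_right` out of range", call. = FALSE)
  ACTIONS[sol$action[[t + 1L]][n_right + 1L]]
}

#' Extract the collapsing decision boundaries
#'
#' The rightward boundary at step t is the smallest count ratio
#' `n_right / (N t)` whose prescribed action is "right"; the leftward boundary
#' is the largest ratio prescribing "left". Both are undefined (NA) at steps
#' where the policy samples for every evidence value.
#'
#' @param sol A [solve_policy()] solution.
#' @return A data frame with columns `t`, `theta_right`, `theta_left`.
#' @export
extract_boundaries <- function(sol) {
  stopifnot(inherits(sol, "policy_solution"))
  data.frame(t = 0:sol$horizon, theta_right = sol$theta_right,
             theta_left = sol$theta_left)
}

#' Fit a hyperbolic curve to a decision boundary
#'
#' Least-squares fit of `theta(t) = 1/2 + a * tau / (t + tau)`: `a` is the
#' boundary's excess over 1/2 at t = 0 and `tau` (the half-time) is the step
#' at which that excess has halved. Fitted by minimizing the sum of squared
#' errors over log-transformed positive parameters with several starting
#' values (Nelder-Mead); a constant boundary is flagged as degenerate rather
#' than fitted.
#'
#' @param theta Numeric boundary values (NAs allowed; dropped).
#' @param t Step indices matching `theta`; defaults to `seq_along(theta) - 1`.
#' @return An object of class `hyperbolic_fit`: `amplitude`, `half_time`,
#'   `residual` (root-mean-square error), `fitted`, `t`, `theta`,
#'   `degenerate`.
#' @examples
#' t <- 5:120
#' fit <- fit_hyperbolic_boundary(0.5 + 0.4 * 30 / (t + 30), t)
#' c(fit$amplitude, fit$half_time)
#' @export
fit_hyperbolic_boundary <- function(theta, t = seq_along(theta) - 1) {
  stopifnot(is.numeric(theta), is.numeric(t), length(theta) == length(t))
  keep <- is.finite(theta) & is.finite(t)
  theta <- theta[keep]
  t <- t[keep]
  if (length(theta) < 5L)
    stop("need at least 5 defined boundary points", call. = FALSE)
  if (diff(range(theta)) < 1e-8) {
    return(structure(list(amplitude = NA_real_, half_time = NA_real_,
                          residual = NA_real_, fitted = rep(NA_real_, length(t)),
                          t = t, theta = theta, degenerate = TRUE),
                     class = "hyperbolic_fit"))
  }
  sse <- function(par) {
    a <- exp(par[1L]); tau <- exp(par[2L])
    sum((theta - (0.5 + a * tau / (t + tau)))^2)
  }
  a_init <- max(max(theta) - 0.5, 1e-3)
  excess <- theta - 0.5
  half_idx <- which(excess <= a_init / 2)
  tau_guess <- if (length(half_idx)) max(t[half_idx[1L]], 1) else stats::median(t)
  starts <- unique(pmax(c(tau_guess, 5, 30, 200), 1))
  best <- NULL
  for (tau0 in starts) {
    opt <- stats::optim(log(c(a_init, tau0)), sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  a <- exp(best$par[1L])
  tau <- exp(best$par[2L])
  fitted <- 0.5 + a * tau / (t + tau)
  structure(list(amplitude = a, half_time = tau,
                 residual = sqrt(best$value / length(t)), fitted = fitted,
                 t = t, theta = theta, degenerate = FALSE),
            class = "hyperbolic_fit")
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Hyperbolic boundary fit: degenerate (constant boundary), not fitted\n")
  } else {
    cat(sprintf("Hyperbolic boundary fit: theta(t) = 1/2 + %.4f * %.2f / (t + %.2f)\n",
                x$amplitude, x$half_time, x$half_time))
    cat(sprintf("  half-time tau = %.2f steps, RMS residual = %.2e (%d points)\n",
                x$half_time, x$residual, length(x$t)))
  }
  invisible(x)
}
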