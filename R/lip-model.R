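#' LIP firing rate for a belief relative to the boundary
#'
#' The read-out maps the distance between the belief point estimate and the
#' rightward decision boundary onto a firing rate:
#' `rate = max(floor, bound_rate + gain * (p_hat - theta_R))`. The rate
#' reaches `bound_rate` exactly when the point estimate reaches the boundary,
#' i.e. at the moment the policy selects the rightward action, so the read-out
#' is a re-coordinatization of the boundary, not a new decision rule. The
#' leftward-preferring population is the mirror image (use `1 - p_hat` and
#' the mirrored boundary).
#'
#' @param p_hat Belief point estimate(s) in \[0, 1\].
#' @param theta_r Rightward boundary value(s) at the matching step(s); must be
#'   defined (non-NA).
#' @param lip An [lip_params()] object.
#' @return Firing rate(s), spikes/s.
#' @export
lip_rate <- function(p_hat, theta_r, lip = lip_params()) {
  stopifnot(inherits(lip, "lip_params"))
  if (any(!is.finite(p_hat)) || any(!is.finite(theta_r)))
    stop("`p_hat` and `theta_r` must be finite (boundary undefined at this step?)",
         call. = FALSE)
  pmax(lip$floor, lip$bound_rate + lip$gain * (p_hat - theta_r))
}

#' Urgency signal: expected LIP rate at zero coherence
#'
#' At zero coherence the expected point estimate among still-sampling trials
#' is 1/2 (by the mirror symmetry of the policy and the stimulus), so the
#' expected rate is `bound_rate + gain * (1/2 - theta_R(t))`: a rising,
#' stimulus-independent image of the collapsing boundary. The boundary over
#' its defined range is also fitted with the hyperbolic form of
#' [fit_hyperbolic_boundary()], giving the urgency half-time.
#'
#' @param sol A [solve_policy()] solution with a symmetric prior.
#' @param lip An [lip_params()] object.
#' @return An object of class `urgency_signal`: data frame `signal` with
#'   columns `t`, `theta_right`, `rate`; `fit` (the boundary fit, with
#'   `half_time` in steps and rate-scale `amplitude_rate = gain * amplitude`);
#'   `degenerate` flag.
#' @export
urgency_signal <- function(sol, lip = lip_params()) {
  stopifnot(inherits(sol, "policy_solution"), inherits(lip, "lip_params"))
  t_all <- 0:sol$horizon
  def <- which(!is.na(sol$theta_right) & t_all >= 1L)
  if (length(def) < 2L)
    stop("the policy has no defined rightward boundary to read out",
         call. = FALSE)
  t_def <- t_all[def]
  theta <- sol$theta_right[def]
  rate <- lip_rate(rep(0.5, length(theta)), theta, lip)
  fit <- tryCatch(fit_hyperbolic_boundary(theta, t_def),
                  error = function(e) NULL)
  degenerate <- is.null(fit) || isTRUE(fit$degenerate)
  if (!degenerate) fit$amplitude_rate <- lip$gain * fit$amplitude
  structure(list(signal = data.frame(t = t_def, theta_right = theta,
                                     rate = rate),
                 fit = fit, degenerate = degenerate, lip = lip),
            class = "urgency_signal")
}

#' @export
print.urgency_signal <- function(x, ...) {
  cat(sprintf("Urgency signal over t in [%d, %d]: rate %.1f -> %.1f spikes/s\n",
              min(x$signal$t), max(x$signal$t),
              x$signal$rate[1L], x$signal$rate[nrow(x$signal)]))
  if (x$degenerate) cat("  hyperbolic fit: degenerate boundary, not fitted\n")
  else cat(sprintf("  hyperbolic fit: half-time %.1f steps, amplitude %.1f spikes/s\n",
                   x$fit$half_time, x$fit$amplitude_rate))
  invisible(x)
}

# internal: per-trial LIP rate path for the rightward-preferring population.
# n_right is the cumulative right-spike count over steps 1..length(n_right).
# At steps where the rightward boundary is undefined (the policy samples for
# every evidence value, so no decision is possible) the rate is the floor.
lip_rate_path <- function(sol, lip, n_right) {
  t <- seq_along(n_right)
  theta <- sol$theta_right[t + 1L]
  p_hat <- n_right / (sol$N * t)
  rate <- rep(lip$floor, length(t))
  def <- !is.na(theta)
  if (any(def)) rate[def] <- lip_rate(p_hat[def], theta[def], lip)
  rate
}

#' LIP rate trajectories of a simulated trial
#'
#' Computes the per-step firing rates of the rightward- and leftward-
#' preferring LIP populations along a simulated trial's evidence path. The
#' leftward population is the mirror construction: it reads `1 - p_hat`
#' against the mirrored boundary `1 - theta_L(t)`. Steps before the boundary
#' exists (where the policy samples regardless of evidence) are reported at
#' the rate floor. The rightward rate first reaches `bound_rate` exactly at
#' the step where the policy selects the rightward action.
#'
#' @param trial A [simulate_trial()] record.
#' @param sol The [solve_policy()] solution that generated the trial.
#' @param lip An [lip_params()] object.
#' @return Data frame with columns `t`, `p_hat`, `rate_right`, `rate_left`.
#' @export
trial_lip_rates <- function(trial, sol, lip = lip_params()) {
  stopifnot(inherits(trial, "trial_record"), inherits(sol, "policy_solution"),
            inherits(lip, "lip_params"))
  n_right <- trial$n_right
  t <- seq_along(n_right)
  rate_r <- lip_rate_path(sol, lip, n_right)
  # mirror: the leftward population reads the left-spike ratio against the
  # mirrored count threshold; both are ratios over the same denominator N*t,
  # so the bound is reached exactly when n_right <= k_left
  k_l <- sol$k_left[t + 1L]
  p_hat_l <- (sol$N * t - n_right) / (sol$N * t)
  rate_l <- rep(lip$floor, length(t))
  def <- !is.na(k_l) & t >= 1L
  if (any(def)) {
    theta_mirror <- (sol$N * t[def] - k_l[def]) / (sol$N * t[def])
    rate_l[def] <- lip_rate(p_hat_l[def], theta_mirror, lip)
  }
  data.frame(t = t, p_hat = n_right / (sol$N * t),
             rate_right = rate_r, rate_left = rate_l)
}

# internal: exact survivor-conditioned mean LIP rate per step, from the
# forward lattice mass. Returns NA at steps with no surviving mass or an
# undefined boundary.
survivor_rate_profile <- function(sol, p_true, lip, steps) {
  N <- sol$N
  w <- stats::dbinom(0:N, N, p_true)
  mass <- 1
  out <- rep(NA_real_, length(steps))
  max_t <- max(steps)
  if (sol$action[[1L]][1L] != 1L) return(out)
  for (t in 1:max_t) {
    new_mass <- numeric(N * t + 1L)
    for (z in 0:N) {
      idx <- seq_along(mass) + z
      new_mass[idx] <- new_mass[idx] + mass * w[z + 1L]
    }
    a <- sol$action[[t + 1L]]
    new_mass[a != 1L] <- 0
    mass <- new_mass
    k <- match(t, steps)
    if (!is.na(k) && sum(mass) > 0 && !is.na(sol$theta_right[t + 1L])) {
      p_hat <- (0:(N * t)) / (N * t)
      rates <- lip_rate(p_hat, sol$theta_right[t + 1L], lip)
      out[k] <- sum(rates * mass) / sum(mass)
    }
  }
  out
}

#' Buildup rates of the LIP read-out across coherences
#'
#' Estimates the early slope of the trial-averaged LIP rate at each coherence,
#' then regresses those slopes on coherence (in percent). Averages are
#' conditioned on trials still sampling at each step (survivor conditioning,
#' as in the experimental analyses this mirrors), over a window of
#' `lip$buildup_window` steps starting at the first step where the rightward
#' boundary is defined. With `method = "simulation"` the average is over
#' `n_trials` seeded Monte Carlo trials per coherence; with
#' `method = "analytic"` it is the exact survivor-conditioned expectation from
#' the forward lattice mass.
#'
#' @param sol A converged [solve_policy()] solution.
#' @param mt An [mt_params()] object.
#' @param lip An [lip_params()] object.
#' @param coherences Coherence levels.
#' @param n_trials Trials per coherence (simulation method).
#' @param seed Integer seed for the simulation stream.
#' @param method `"simulation"` or `"analytic"`.
#' @param direction True motion direction.
#' @return An object of class `buildup_analysis`: data frame `slopes`
#'   (`coherence`, `slope`, in spikes/s per step), `regression` (list with
#'   `slope_per_pct`, `intercept`, from the least-squares line of slope vs
#'   coherence in percent), and the per-step mean-rate `profiles`.
#' @export
buildup_rates <- function(sol, mt = mt_params(), lip = lip_params(),
                          coherences = c(0, 0.032, 0.064, 0.128, 0.256, 0.512),
                          n_trials = 2000L, seed = 1L,
                          method = c("simulation", "analytic"),
                          direction = "right") {
  stopifnot(inherits(sol, "policy_solution"), inherits(mt, "mt_params"),
            inherits(lip, "lip_params"))
  method <- match.arg(method)
  check_direction(direction)
  t_all <- 0:sol$horizon
  def <- which(!is.na(sol$theta_right) & t_all >= 1L)
  if (!length(def)) stop("no defined boundary: nothing to read out", call. = FALSE)
  t0 <- t_all[def[1L]]
  window <- lip$buildup_window
  if (t0 + window - 1L > sol$horizon - 1L) {
    warning("buildup window extends past the horizon; truncating", call. = FALSE)
    window <- sol$horizon - t0
  }
  steps <- t0:(t0 + window - 1L)
  if (method == "simulation") set.seed(as.integer(seed))
  profiles <- vector("list", length(coherences))
  slopes <- numeric(length(coherences))
  for (i in seq_along(coherences)) {
    p <- success_prob(coherences[i], direction, mt)
    if (method == "analytic") {
      rate_t <- survivor_rate_profile(sol, p, lip, steps)
    } else {
      rate_t <- simulate_rate_profile(sol, lip, p, n_trials, steps)
    }
    ok <- is.finite(rate_t)
    if (sum(ok) < 2L)
      stop(sprintf("fewer than 2 usable steps in the buildup window at coherence %g",
                   coherences[i]), call. = FALSE)
    fit <- stats::lm(rate_t[ok] ~ steps[ok])
    slopes[i] <- unname(stats::coef(fit)[2L])
    profiles[[i]] <- data.frame(coherence = coherences[i], t = steps,
                                rate = rate_t)
  }
  coh_pct <- coherences * 100
  reg <- stats::lm(slopes ~ coh_pct)
  structure(list(slopes = data.frame(coherence = coherences, slope = slopes),
                 regression = list(slope_per_pct = unname(stats::coef(reg)[2L]),
                                   intercept = unname(stats::coef(reg)[1L])),
                 profiles = do.call(rbind, profiles),
                 window_steps = steps, method = method),
            class = "buildup_analysis")
}

# internal: Monte Carlo survivor-conditioned mean rate per step. Uses the
# current RNG stream (caller seeds it once per analysis).
simulate_rate_profile <- function(sol, lip, p_true, n_trials, steps) {
  N <- sol$N
  max_t <- max(steps)
  kr <- sol$k_right[2:(max_t + 1L)]   # count thresholds at t = 1..max_t
  kl <- sol$k_left[2:(max_t + 1L)]
  sums <- counts <- numeric(length(steps))
  for (i in seq_len(n_trials)) {
    z <- stats::rbinom(max_t, N, p_true)
    n_right <- cumsum(z)
    crossed <- (!is.na(kr) & n_right >= kr) | (!is.na(kl) & n_right <= kl)
    stop_t <- which(crossed)[1L]               # NA if survives past max_t
    alive_until <- if (is.na(stop_t)) max_t else stop_t - 1L
    live <- steps <= alive_until
    if (!any(live)) next
    rates <- lip_rate_path(sol, lip, n_right)[steps[live]]
    sums[live] <- sums[live] + rates
    counts[live] <- counts[live] + 1
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

#' Regression of buildup slopes on coherence
#'
#' Helper shared by [buildup_rates()] and usable on externally constructed
#' trajectories: fits a per-trajectory early slope by least squares and then
#' the line of slope versus coherence (in percent).
#'
#' @param profiles A list of numeric mean-rate vectors, one per coherence,
#'   all evaluated at the steps in `steps`.
#' @param coherences Coherence levels matching `profiles`.
#' @param steps Step indices of the trajectory samples.
#' @return List with `slopes` (per coherence, spikes/s per step),
#'   `slope_per_pct` and `intercept` of the slope-vs-coherence line.
#' @export
buildup_regression <- function(profiles, coherences, steps) {
  stopifnot(length(profiles) == length(coherences))
  slopes <- vapply(profiles, function(r) {
    ok <- is.finite(r)
    unname(stats::coef(stats::lm(r[ok] ~ steps[ok]))[2L])
  }, numeric(1))
  coh_pct <- coherences * 100
  reg <- stats::lm(slopes ~ coh_pct)
  list(slopes = slopes, slope_per_pct = unname(stats::coef(reg)[2L]),
       intercept = unname(stats::coef(reg)[1L]))
}

#' @export
print.buildup_analysis <- function(x, ...) {
  cat(sprintf("LIP buildup analysis (%s, window t = %d..%d)\n", x$method,
              min(x$window_steps), max(x$window_steps)))
  for (i in seq_len(nrow(x$slopes)))
    cat(sprintf("  c = %5.1f%% : slope %.3f spikes/s per step\n",
                100 * x$slopes$coherence[i], x$slopes$slope[i]))
  cat(sprintf("  slope vs coherence: %.4f spikes/s/step per %% coherence\n",
              x$regression$slope_per_pct))
  invisible(x)
}
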