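#' Exact first-passage analysis of a solved policy
#'
#' Propagates the full probability mass of the evidence process forward over
#' the lattice under a true success probability `p_true`, restricted to the
#' sampling region of the policy. The mass entering the "right"/"left" regions
#' at step t is the crossing distribution h_R(t)/h_L(t); the mass still
#' sampling after step t is the survival g(t). Mass that reaches the horizon
#' row without having crossed is reported as leak `g(T_max)` and never
#' classified as a choice (stops forced by the finite horizon are truncation
#' artifacts, and a converged policy leaves negligible mass there).
#'
#' Conservation holds by construction:
#' `sum(h_right) + sum(h_left) + leak == 1`.
#'
#' @param sol A converged [solve_policy()] solution.
#' @param p_true True spike-success probability of the stimulus, in \[0, 1\]
#'   (see [success_prob()]).
#' @return An object of class `behavior_prediction`: vectors `t`, `survival`,
#'   `h_right`, `h_left` over steps 0..T_max; choice probabilities `p_right`,
#'   `p_left`; `leak`; conditional mean crossing steps `mean_rt_right`,
#'   `mean_rt_left` (NA, with `rt_right_defined`/`rt_left_defined` flags, when
#'   the corresponding choice has probability 0).
#' @examples
#' sol <- solve_policy(reward_params(-1, 200, -200), horizon = 500)
#' fp <- first_passage(sol, success_prob(0.128, "right"))
#' c(fp$p_right, fp$mean_rt_right)
#' @export
first_passage <- function(sol, p_true) {
  stopifnot(inherits(sol, "policy_solution"))
  if (!isTRUE(sol$converged))
    stop("policy is not certified stationary (converged = ",
         deparse(sol$converged), "); re-solve with a larger `horizon` ",
         "or with `check_stationarity = TRUE`", call. = FALSE)
  if (!is.numeric(p_true) || length(p_true) != 1L || is.na(p_true) ||
      p_true < 0 || p_true > 1)
    stop("`p_true` must be a single probability in [0, 1]", call. = FALSE)
  Tmax <- sol$horizon
  N <- sol$N
  h_right <- h_left <- survival <- numeric(Tmax + 1L)
  leak <- 0
  root <- sol$action[[1L]][1L]
  if (root != 1L) {
    # immediate-decision policy: all mass stops at t = 0
    if (root == 2L) h_right[1L] <- 1 else h_left[1L] <- 1
  } else {
    survival[1L] <- 1
    w <- stats::dbinom(0:N, N, p_true)
    mass <- 1
    for (t in 1:Tmax) {
      # binomial convolution: lattice row t-1 (length N(t-1)+1) -> row t
      new_mass <- numeric(N * t + 1L)
      for (z in 0:N) {
        idx <- seq_along(mass) + z
        new_mass[idx] <- new_mass[idx] + mass * w[z + 1L]
      }
      if (t < Tmax) {
        a <- sol$action[[t + 1L]]
        cross_r <- a == 2L
        cross_l <- a == 3L
        h_right[t + 1L] <- sum(new_mass[cross_r])
        h_left[t + 1L] <- sum(new_mass[cross_l])
        new_mass[cross_r | cross_l] <- 0
        mass <- new_mass
        survival[t + 1L] <- sum(mass)
      } else {
        leak <- sum(new_mass)
        survival[t + 1L] <- leak
      }
    }
  }
  p_right <- sum(h_right)
  p_left <- sum(h_left)
  steps <- 0:Tmax
  rt_r_def <- p_right > 0
  rt_l_def <- p_left > 0
  structure(list(p_true = p_true, t = steps, survival = survival,
                 h_right = h_right, h_left = h_left,
                 p_right = p_right, p_left = p_left, leak = leak,
                 mean_rt_right = if (rt_r_def) sum(steps * h_right) / p_right else NA_real_,
                 mean_rt_left = if (rt_l_def) sum(steps * h_left) / p_left else NA_real_,
                 rt_right_defined = rt_r_def, rt_left_defined = rt_l_def),
            class = "behavior_prediction")
}

#' @export
print.behavior_prediction <- function(x, ...) {
  cat(sprintf("First-passage prediction at p_true = %.4f\n", x$p_true))
  cat(sprintf("  P(right) = %.4f, P(left) = %.4f, horizon leak = %.2e\n",
              x$p_right, x$p_left, x$leak))
  cat(sprintf("  mean crossing step: right %.2f, left %.2f\n",
              x$mean_rt_right, x$mean_rt_left))
  invisible(x)
}

#' Choice probabilities and conditional mean reaction times
#'
#' Marginal choice probabilities (crossing masses summed over time) and mean
#' crossing steps under the choice-conditioned crossing distributions. A
#' zero-probability choice yields an NA mean with its `*_defined` flag FALSE
#' rather than an error.
#'
#' @param pred A [first_passage()] prediction.
#' @return List with `p_right`, `p_left`, `mean_rt_right`, `mean_rt_left`,
#'   `rt_right_defined`, `rt_left_defined`.
#' @export
choice_and_rt <- function(pred) {
  stopifnot(inherits(pred, "behavior_prediction"))
  pred[c("p_right", "p_left", "mean_rt_right", "mean_rt_left",
         "rt_right_defined", "rt_left_defined")]
}

#' Psychometric and chronometric predictions across coherences
#'
#' Runs the exact first-passage analysis at each coherence (with the given
#' true direction) and tabulates accuracy and mean reaction times in steps.
#' Accuracy is the probability of a correct choice conditioned on a decision
#' being made, `P_correct / (P_right + P_left)`, matching the experimental
#' convention of scoring completed trials; the unconditional masses and the
#' horizon leak are also reported.
#'
#' @param sol A converged [solve_policy()] solution.
#' @param mt An [mt_params()] object mapping coherence to success probability.
#' @param coherences Coherence levels in \[0, 1\].
#' @param direction True motion direction for all trials.
#' @return A data frame with one row per coherence: `coherence`, `p_success`,
#'   `p_right`, `p_left`, `leak`, `accuracy`, `mean_rt_correct_steps`,
#'   `mean_rt_error_steps`.
#' @export
psychometric_chronometric <- function(sol, mt = mt_params(),
                                      coherences = c(0, 0.032, 0.064, 0.128,
                                                     0.256, 0.512),
                                      direction = "right") {
  stopifnot(inherits(sol, "policy_solution"), inherits(mt, "mt_params"))
  check_direction(direction)
  if (any(coherences < 0) || any(coherences > 1))
    stop("`coherences` must lie in [0, 1]", call. = FALSE)
  rows <- lapply(coherences, function(co) {
    p <- success_prob(co, direction, mt)
    fp <- first_passage(sol, p)
    correct <- if (direction == "right")
      c(fp$p_right, fp$mean_rt_right, fp$mean_rt_left)
    else
      c(fp$p_left, fp$mean_rt_left, fp$mean_rt_right)
    decided <- fp$p_right + fp$p_left
    data.frame(coherence = co, p_success = p,
               p_right = fp$p_right, p_left = fp$p_left, leak = fp$leak,
               accuracy = correct[1L] / decided,
               mean_rt_correct_steps = correct[2L],
               mean_rt_error_steps = correct[3L])
  })
  do.call(rbind, rows)
}

#' Calibrate POMDP steps to milliseconds
#'
#' Ordinary least-squares regression of observed mean reaction times (ms) on
#' model-predicted mean decision steps:
#' `RT_ms = ms_per_step * steps + residual_ms`. The slope is the real duration
#' of one POMDP step and the intercept is the non-decision residual time. The
#' two coefficients live outside the POMDP model; they only translate steps
#' into seconds for comparison with data.
#'
#' @param expected_steps Model mean decision steps, one per condition.
#' @param observed_rt_ms Observed mean reaction times in ms, same length.
#' @return An object of class `time_calibration`: `ms_per_step`,
#'   `residual_ms`, `rmse_ms`, `fitted_ms`, `n`.
#' @examples
#' calibrate_time(c(10, 20), c(400, 600))  # 20 ms/step, 200 ms residual
#' @export
calibrate_time <- function(expected_steps, observed_rt_ms) {
  stopifnot(is.numeric(expected_steps), is.numeric(observed_rt_ms))
  if (length(expected_steps) != length(observed_rt_ms))
    stop("`expected_steps` and `observed_rt_ms` must have equal length",
         call. = FALSE)
  keep <- is.finite(expected_steps) & is.finite(observed_rt_ms)
  expected_steps <- expected_steps[keep]
  observed_rt_ms <- observed_rt_ms[keep]
  if (length(expected_steps) < 2L || length(unique(expected_steps)) < 2L)
    stop("calibration is underdetermined: need at least 2 distinct ",
         "expected-step values", call. = FALSE)
  fit <- stats::lm(observed_rt_ms ~ expected_steps)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0)
    warning("fitted ms/step is not positive; observed RTs do not increase ",
            "with predicted decision steps", call. = FALSE)
  if (intercept < 0)
    warning("fitted non-decision residual time is negative", call. = FALSE)
  structure(list(ms_per_step = slope, residual_ms = intercept,
                 rmse_ms = sqrt(mean(stats::residuals(fit)^2)),
                 fitted_ms = unname(stats::fitted(fit)),
                 n = length(expected_steps)),
            class = "time_calibration")
}

#' @export
print.time_calibration <- function(x, ...) {
  cat(sprintf("Step-to-time calibration (OLS over %d conditions)\n", x$n))
  cat(sprintf("  ms per step       : %.3f\n", x$ms_per_step))
  cat(sprintf("  non-decision time : %.1f ms\n", x$residual_ms))
  cat(sprintf("  RMS residual      : %.2f ms\n", x$rmse_ms))
  invisible(x)
}
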